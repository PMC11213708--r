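make_annot_field <- function(taus, labels_per_px, H = 6, W = 6) {
  # one row per pixel spec: lifetime value + label
  lt <- matrix(0, H, W)
  mk <- matrix(0L, H, W)
  lt[seq_along(taus)] <- taus
  mk[seq_along(labels_per_px)] <- labels_per_px
  list(field = flim_field(matrix(100, H, W), lt, 1),
       annot = cell_annotation(mk, data.frame(
         label = sort(unique(labels_per_px[labels_per_px > 0])),
         cell_type = paste0("t", sort(unique(labels_per_px[labels_per_px > 0]))))))
}

test_that("cell histograms tally pixel lifetimes into centred bins", {
  fx <- make_annot_field(rep(2, 10), rep(1L, 10))
  h <- cell_histogram(fx$field, fx$annot, 1)
  expect_equal(sum(h$counts), 10)
  expect_equal(h$centres[which(h$counts > 0)], 2)
  expect_equal(max(h$counts), 10)
  # two-valued region tallies each value at its own centre
  fx2 <- make_annot_field(c(rep(1, 5), rep(3, 3)), rep(1L, 8))
  h2 <- cell_histogram(fx2$field, fx2$annot, 1)
  expect_equal(h2$counts[h2$centres == 1], 5)
  expect_equal(h2$counts[h2$centres == 3], 3)
  expect_error(cell_histogram(fx$field, fx$annot, 99), "unknown")
})

test_that("histogram mass is conserved under any bin width", {
  fld <- fixture_field(6, 128)
  annot <- fixture_phantom(6, 128)$annot
  lab <- annot$labels$label[1]
  n_px <- sum(annot$mask == lab)
  for (w in c(0.01, 0.05, 0.2, 1)) {
    h <- cell_histogram(fld, annot, lab, bin_width = w)
    expect_equal(sum(h$counts), n_px)
  }
})

test_that("signatures report modal peak and weighted mean with low-tie rule", {
  fx <- make_annot_field(c(rep(1, 5), rep(3, 3)), rep(1L, 8))
  s <- signature_from_histogram(cell_histogram(fx$field, fx$annot, 1), "t1")
  expect_equal(s$peak_lifetime, 1)
  expect_equal(s$mean_lifetime, (5 * 1 + 3 * 3) / 8)
  expect_equal(s$n_pixels, 8)
  # delta distribution: peak and mean coincide
  fxd <- make_annot_field(rep(2, 10), rep(1L, 10))
  sd_ <- signature_from_histogram(cell_histogram(fxd$field, fxd$annot, 1))
  expect_equal(sd_$peak_lifetime, 2)
  expect_equal(sd_$mean_lifetime, 2)
  # tie breaks toward the lower lifetime
  fxt <- make_annot_field(c(rep(1, 4), rep(3, 4)), rep(1L, 8))
  st <- signature_from_histogram(cell_histogram(fxt$field, fxt$annot, 1))
  expect_equal(st$peak_lifetime, 1)
  empty <- structure(list(counts = rep(0L, 5), centres = 1:5 / 2,
                          bin_width = 0.5), class = "lifetime_histogram")
  expect_error(signature_from_histogram(empty), "empty")
})

test_that("per-type summaries pool pixel-weighted and sort by mean", {
  # two cells of one type plus one of another
  lt <- c(rep(1, 4), rep(2, 4), rep(0.5, 4))
  mk <- c(rep(1L, 4), rep(2L, 4), rep(3L, 4))
  fld <- flim_field(matrix(100, 4, 3), matrix(lt, 4, 3), 1)
  annot <- cell_annotation(matrix(mk, 4, 3),
                           data.frame(label = 1:3,
                                      cell_type = c("a", "a", "b")))
  out <- summarise_cell_types(fld, annot)
  expect_equal(out$cell_type, c("b", "a"))   # ascending mean
  expect_equal(out$mean_lifetime[out$cell_type == "a"], 1.5)
  # pooled mean equals the pixel-weighted mean of per-cell means
  cells <- attr(out, "cells")
  a_cells <- cells[vapply(cells, `[[`, "", "cell_type") == "a"]
  pooled <- sum(vapply(a_cells, function(s) s$mean_lifetime * s$n_pixels,
                       numeric(1))) / sum(vapply(a_cells, `[[`, 0, "n_pixels"))
  expect_equal(out$mean_lifetime[out$cell_type == "a"], pooled)
  expect_error(summarise_cell_types(fld,
    cell_annotation(matrix(0L, 4, 3),
                    data.frame(label = integer(), cell_type = character()))),
    "no annotated")
})

test_that("phantom cell-type ordering and means are recovered", {
  ph <- fixture_phantom(12, 256)
  out <- summarise_cell_types(clamp_flim(ph$flim), ph$annot)
  truth <- default_cell_types()
  truth <- truth[order(truth$mean_lifetime), ]
  expect_equal(out$cell_type, truth$name)
  big <- out$n_pixels >= 200
  expect_true(any(big))
  expect_lt(max(abs(out$mean_lifetime[big] -
                      truth$mean_lifetime[match(out$cell_type, truth$name)][big])),
            0.05)
})

test_that("annotation masks round-trip through 16-bit TIFF plus JSON", {
  ph <- fixture_phantom(6, 128)
  td <- withr::local_tempdir()
  write_phantom(ph, td)
  id <- ph$flim$field_id
  annot <- read_cell_annotation(file.path(td, paste0(id, "_annot.tif")),
                                file.path(td, paste0(id, "_labels.json")))
  expect_equal(annot$mask, ph$annot$mask)
  expect_equal(annot$labels$cell_type, ph$annot$labels$cell_type)
  # mask with an unmapped label is rejected
  expect_error(cell_annotation(matrix(c(0L, 7L), 1),
                               data.frame(label = 1L, cell_type = "x")),
               "without a label-map entry")
})
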