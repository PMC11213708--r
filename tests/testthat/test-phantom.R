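test_that("phantom specs validate their parameters", {
  expect_error(phantom_spec(cell_types = data.frame(name = "x")), "columns")
  ct <- default_cell_types()
  ct$mean_lifetime[1] <- 6
  expect_error(phantom_spec(cell_types = ct), "\\(0, 5\\)")
  ct <- default_cell_types(); ct$density[1] <- -1
  expect_error(phantom_spec(cell_types = ct), ">= 0")
  # packing beyond what rejection sampling can place fails loudly
  ct <- default_cell_types(); ct$density <- ct$density * 100
  expect_error(generate_phantom(phantom_spec(image_size = c(64, 64),
                                             cell_types = ct)),
               "density too high")
})

test_that("phantoms are bit-identical under a fixed seed", {
  sp <- phantom_spec(image_size = c(96, 96), seed = 77)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$flim$intensity, b$flim$intensity)
  expect_identical(a$flim$lifetime, b$flim$lifetime)
  expect_identical(a$he, b$he)
  expect_identical(a$annot$mask, b$annot$mask)
  # a different seed gives a different tissue
  c2 <- generate_phantom(phantom_spec(image_size = c(96, 96), seed = 78))
  expect_false(identical(a$annot$mask, c2$annot$mask))
  # the generator must not disturb the caller's RNG stream
  withr::local_seed(5)
  r1 <- runif(1)
  withr::local_seed(5)
  invisible(generate_phantom(sp))
  expect_identical(runif(1), r1)
})

test_that("an all-zero density spec is an empty slide region", {
  ct <- default_cell_types()
  ct$density <- 0
  ph <- generate_phantom(phantom_spec(image_size = c(64, 64),
                                      cell_types = ct, seed = 3))
  expect_true(all(ph$he == 1))                  # blank white H&E
  expect_true(all(ph$annot$mask == 0L))
  # intensity is pure background noise at the stated Poisson mean
  expect_lt(abs(mean(ph$flim$intensity) - 20), 1)
  expect_true(all(ph$flim$lifetime == 0))
})

test_that("per-type lifetime statistics converge to the spec values", {
  ph <- fixture_phantom(30, 256)
  ct <- default_cell_types()
  for (t in seq_len(nrow(ct))) {
    labs <- ph$annot$labels$label[ph$annot$labels$cell_type == ct$name[t]]
    px <- ph$flim$lifetime[ph$annot$mask %in% labs]
    se <- ct$lifetime_sd[t] / sqrt(length(px))
    expect_lt(abs(mean(px) - ct$mean_lifetime[t]), 3 * se + 1e-9)
  }
})

test_that("photon counts behave like Poisson draws (mean ~ variance)", {
  ph <- fixture_phantom(31, 256)
  core_px <- ph$annot$mask == 0 & ph$flim$lifetime > 0   # stroma
  x <- ph$flim$intensity[core_px]
  expect_gt(length(x), 1e4)
  expect_lt(abs(mean(x) - 150) / 150, 0.05)
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
  # background outside the core
  bg <- ph$flim$intensity[ph$flim$lifetime == 0]
  expect_lt(abs(mean(bg) - 20) / 20, 0.1)
})

test_that("H&E rendering is geometry-driven Beer-Lambert with white background", {
  ph <- fixture_phantom(32, 128)
  # background is exactly white
  bg <- ph$flim$lifetime == 0
  for (k in 1:3) expect_true(all(ph$he[, , k][bg] == 1))
  # nuclei are darker and bluer than stroma
  nuc_px <- ph$annot$mask > 0
  expect_lt(mean(ph$he[, , 3][nuc_px]), 1)
  expect_gt(min(ph$he), 0.2)
  # the rendering never saw lifetime values: rescaling lifetimes leaves
  # the H&E untouched
  sp <- phantom_spec(image_size = c(128, 128), seed = 32)
  sp2 <- sp
  sp2$cell_types$mean_lifetime <- pmin(sp$cell_types$mean_lifetime * 1.5, 4.9)
  ph2 <- generate_phantom(sp2)
  expect_identical(ph$he, ph2$he)
})

test_that("degrade_pair warps by the stated transform and adds known noise", {
  ph <- fixture_phantom(33, 128)
  same <- degrade_pair(ph, affine_identity(), 0)
  expect_identical(same$he, ph$he)
  tr <- affine_from_params(tx = 7, ty = -3)
  warped <- degrade_pair(ph, tr, 0)
  expect_identical(warped$true_affine$m, tr$m)
  # content moved by the transform: compare against a direct warp
  expect_identical(warped$he, apply_affine(ph$he, tr, fill = 1))
  # additive Gaussian noise at sd 0.05 lands near its closed-form PSNR
  noisy <- withr::with_seed(9, degrade_pair(ph, affine_identity(), 0.05))
  expect_equal(psnr(ph$he, noisy$he), 10 * log10(1 / 0.05^2), tolerance = 1)
})

test_that("phantom patch pairs come filtered, shaped and in all formats", {
  pairs <- phantom_patch_pairs(2, c(128, 128), patch = 32, seed = 50)
  expect_gt(length(pairs), 4)
  p <- pairs[[1]]
  expect_equal(dim(p$input_patch), c(32, 32, 3))
  expect_equal(dim(p$target_patch), c(32, 32, 3))
  expect_lte(p$background_fraction, 0.75)
  one <- phantom_patch_pairs(1, c(64, 64), patch = 32, seed = 50,
                             format_tag = "INTENSITY", max_background = 1)
  expect_equal(dim(one[[1]]$input_patch)[3], 1)
  four <- phantom_patch_pairs(1, c(64, 64), patch = 32, seed = 50,
                              format_tag = "ALPHA_FLIM", max_background = 1)
  expect_equal(dim(four[[1]]$input_patch)[3], 4)
})
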