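test_that("H&E preparation stretches the 1-99 percentile range to [0, 1]", {
  withr::local_seed(1)
  # a narrow-range image fills [0, 1] after the stretch
  g <- matrix(runif(100 * 100, 0.4, 0.6), 100)
  he <- array(rep(g, 3), c(100, 100, 3))
  s <- prepare_he_for_registration(he)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  q <- quantile(g, c(0.01, 0.99), names = FALSE)
  mid <- g[50, 50]
  expect_equal(s[50, 50], (mid - q[1]) / (q[2] - q[1]), tolerance = 1e-12)
  # a full-range image is nearly unchanged away from the clipped tails
  g2 <- matrix(seq(0, 1, length.out = 10000), 100)
  s2 <- prepare_he_for_registration(array(rep(g2, 3), c(100, 100, 3)))
  expect_lt(max(abs(s2[, 50] - g2[, 50])), 0.025)
  expect_error(prepare_he_for_registration(array(0.5, c(10, 10, 3))),
               "dynamic range")
})

test_that("bicubic downsampling maps pixel sizes and preserves constants", {
  he <- array(0.7, c(64, 64, 3))
  out <- downsample_he(he, 0.22, 0.455)
  expect_equal(dim(out)[1:2], round(c(64, 64) * 0.22 / 0.455))
  expect_equal(max(abs(out - 0.7)), 0, tolerance = 1e-12)
  expect_identical(downsample_he(he, 0.4, 0.4), he)
  expect_error(downsample_he(he, -1, 2), "positive")
  # the reference scan geometry: 1024 px at 0.22 um -> 495 px at 0.455 um
  expect_equal(round(1024 * 0.22 / 0.455), 495)
})

test_that("affine transforms compose, invert and serialise", {
  a <- affine_from_params(tx = 3, ty = -2, angle = 10, sx = 1.05)
  expect_error(affine_transform(matrix(c(1, 2, 2, 4, 0, 0), 2)), "singular")
  ident <- affine_compose(a, affine_invert(a))
  expect_equal(ident$m, affine_identity()$m, tolerance = 1e-12)
  td <- withr::local_tempdir()
  p <- file.path(td, "t.json")
  write_affine_json(a, p)
  expect_equal(read_affine_json(p)$m, a$m, tolerance = 1e-12)
})

test_that("apply_affine inverse-warps with exact identity and inverse", {
  img <- fixture_rgb(1, 32)
  expect_equal(apply_affine(img, affine_identity()), img)
  # integer shift: bilinear sampling lands on grid points, so the
  # composition with its inverse is exact in the interior
  t <- affine_from_params(tx = 5, ty = -3)
  there <- apply_affine(img, t)
  back <- apply_affine(there, affine_invert(t))
  interior <- back[12:22, 12:22, ]
  expect_equal(interior, img[12:22, 12:22, ], tolerance = 1e-6)
})

test_that("a 90-degree rotation moves a marker to the computed location", {
  img <- matrix(0, 9, 9)
  img[2, 5] <- 1  # asymmetric marker above centre
  t <- affine_from_params(angle = 90, centre = c(4, 4))
  out <- apply_affine(img, t)
  # row/col coords (1, 4) (0-based) map under +90 deg about (4,4):
  # offset (-3, 0) -> rotated (0, -3) -> (4, 1) 0-based = [5, 2] 1-based
  expect_equal(out[5, 2], 1)
  expect_equal(sum(out), 1)
})

test_that("patch extraction matches a brute-force scan with the strict filter", {
  fld <- fixture_field(5, 128)
  si <- make_iw_flim(fld)
  bg <- background_mask(fld)
  he <- fixture_phantom(5, 128)$he
  patches <- extract_patches(si, he, bg, patch = 32, stride = 16)
  # independent brute-force enumeration of the same grid + filter
  count <- 0
  for (r in seq(1, 128 - 32 + 1, 16)) for (c in seq(1, 128 - 32 + 1, 16)) {
    if (mean(bg[r:(r + 31), c:(c + 31)]) <= 0.75) count <- count + 1
  }
  expect_equal(length(patches), count)
  expect_gt(attr(patches, "n_dropped"), 0)
  # provenance: crops are exact sub-arrays at their stated origin
  p <- patches[[3]]
  r0 <- p$origin[["row"]] + 1; c0 <- p$origin[["col"]] + 1
  expect_identical(p$input_patch,
                   si$pixels[r0:(r0 + 31), c0:(c0 + 31), , drop = FALSE])
  expect_identical(p$target_patch,
                   he[r0:(r0 + 31), c0:(c0 + 31), , drop = FALSE])
  expect_error(extract_patches(si, he, bg, patch = 256), "exceeds")
})

test_that("the background filter drops strictly above 75%", {
  # constructed field: four 4x4 patches with background fractions
  # 0.50, 0.75, 0.76 (12.25/16 -> use 13/16 = 0.8125), 1.00
  bg <- matrix(FALSE, 4, 16)
  bg[, 1:4][1:8] <- TRUE                      # 0.50
  bg[, 5:8][1:12] <- TRUE                     # 0.75
  bg[, 9:12][1:13] <- TRUE                    # 0.8125 > 0.75
  bg[, 13:16] <- TRUE                         # 1.00
  img <- array(0.5, c(4, 16, 3))
  kept <- extract_patches(img, img, bg, patch = 4, stride = 4)
  expect_equal(length(kept), 2)
  expect_equal(vapply(kept, `[[`, 0, "background_fraction"), c(0.5, 0.75))
})

test_that("mutual-information registration recovers synthetic warps", {
  ph <- fixture_phantom(21, 256)
  fixh <- prepare_he_for_registration(ph$he)
  # exact self-registration
  self <- estimate_affine(fixh, fixh, levels = 2)
  expect_lt(corner_error(self, affine_identity(), dim(fixh)), 0.1)
  # translation recovery on a clean synthetic shift (noisy recovery at
  # its own tolerance is exercised by the acceptance suite)
  tr <- affine_from_params(tx = 7, ty = -3)
  mov <- prepare_he_for_registration(degrade_pair(ph, tr, 0)$he)
  est <- estimate_affine(mov, fixh)
  expect_lt(corner_error(est, affine_invert(tr), dim(mov)), 0.5)
  # rotation recovery: the estimated angle is within half a degree
  ctr <- (dim(fixh) - 1) / 2
  rot <- affine_from_params(angle = 10, centre = ctr)
  mov2 <- prepare_he_for_registration(degrade_pair(ph, rot, 0)$he)
  est2 <- estimate_affine(mov2, fixh)
  ang <- atan2(est2$m[2, 1], est2$m[1, 1]) * 180 / pi
  expect_lt(abs(ang - (-10)), 0.5)
})

test_that("control-point registration fits the least-squares affine", {
  withr::local_seed(2)
  pts <- cbind(runif(6, 0, 100), runif(6, 0, 100))
  truth <- affine_from_params(tx = 4, ty = -2, angle = 7, sx = 1.02)
  mapped <- pts %*% t(truth$m[, 1:2]) + rep(1, 6) %o% truth$m[, 3]
  est <- estimate_affine(method = "points",
                         points = list(moving = pts, fixed = mapped))
  expect_equal(est$m, truth$m, tolerance = 1e-9)
})
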