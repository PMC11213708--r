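# Windowed brute-force SSIM oracle: explicit loops over all interior
# 11x11 windows with Gaussian weights.
oracle_mssim_channel <- function(x, y, window = 11, sigma = 1.5) {
  r <- (window - 1) / 2
  g <- exp(-(seq(-r, r)^2) / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  C1 <- 0.01^2; C2 <- 0.03^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in seq_len(H - window + 1)) for (j in seq_len(W - window + 1)) {
    wx <- x[i:(i + window - 1), j:(j + window - 1)]
    wy <- y[i:(i + window - 1), j:(j + window - 1)]
    mx <- sum(w * wx); my <- sum(w * wy)
    sxx <- sum(w * wx^2) - mx^2
    syy <- sum(w * wy^2) - my^2
    sxy <- sum(w * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
  }
  mean(vals)
}

test_that("nrmse is the reference-normalised Euclidean error", {
  x <- fixture_rgb(1, 16)
  expect_equal(nrmse(x, x), 0)
  expect_equal(nrmse(x, x * 0), 1)
  expect_equal(nrmse(array(c(1, 1, 1, 1), c(2, 2)),
                     array(c(1, 1, 1, 0), c(2, 2))), 0.5)
  expect_error(nrmse(x * 0, x), "all-zero")
  expect_error(nrmse(x, x[1:8, , ]), "shape")
})

test_that("nmi is 2 for identical images and ~1 for independent noise", {
  x <- fixture_rgb(2, 32)
  expect_equal(nmi(x, x), 2, tolerance = 1e-12)
  # permuting both images identically leaves the histograms unchanged
  y <- fixture_rgb(3, 32)
  perm <- withr::with_seed(4, sample(32 * 32))
  gx <- flimstain:::luminance(x); gy <- flimstain:::luminance(y)
  px <- matrix(gx[perm], 32); py <- matrix(gy[perm], 32)
  expect_equal(nmi(gx, gy), nmi(px, py), tolerance = 1e-12)
  # independence limit on a large sample
  withr::local_seed(5)
  a <- matrix(runif(1e6), 1000)
  b <- matrix(runif(1e6), 1000)
  expect_lt(abs(nmi(a, b) - 1), 0.01)
  expect_error(nmi(matrix(0.5, 8, 8), matrix(0.5, 8, 8)), "constant")
})

test_that("psnr has its closed forms and logarithm law", {
  x <- fixture_rgb(6, 16)
  expect_identical(psnr(x, x), Inf)
  # constant offset of 16/255 on the unit scale
  off <- array(16 / 255, dim(x))
  expect_equal(psnr(x, x + off), 10 * log10(1 / (16 / 255)^2),
               tolerance = 1e-9)
  expect_equal(10 * log10(1 / (16 / 255)^2), 24.0482, tolerance = 1e-3)
  # halving the MSE raises PSNR by 10 log10 2
  half <- array(16 / 255 / sqrt(2), dim(x))
  expect_equal(psnr(x, x + half) - psnr(x, x + off), 10 * log10(2),
               tolerance = 1e-9)
})

test_that("mssim matches the windowed brute-force oracle", {
  withr::local_seed(7)
  x <- matrix(runif(16 * 16), 16)
  y <- matrix(runif(16 * 16), 16)
  expect_equal(mssim(x, y), oracle_mssim_channel(x, y), tolerance = 1e-10)
  expect_equal(mssim(x, x), 1)
  expect_equal(mssim(x, y), mssim(y, x))
  # anti-correlated structure about mid-grey scores negative
  z <- 0.5 + 0.4 * sin(outer(1:32, 1:32, function(i, j) i / 2 + j / 3))
  expect_lt(mssim(z, 1 - z), 0)
  expect_equal(mssim(z, 1 - z), oracle_mssim_channel(z, 1 - z),
               tolerance = 1e-10)
  expect_error(mssim(x[1:8, 1:8], y[1:8, 1:8]), "window")
  # RGB is averaged over per-channel scores
  xr <- fixture_rgb(8, 16); yr <- fixture_rgb(9, 16)
  expect_equal(mssim(xr, yr),
               mean(sapply(1:3, function(k) mssim(xr[, , k], yr[, , k]))))
})

test_that("nrmse and psnr order a noise ladder in exactly opposite ways", {
  ref <- fixture_phantom(3, 64)$he
  lvls <- c(0.01, 0.03, 0.07, 0.12, 0.2)
  tests <- withr::with_seed(10, lapply(lvls, function(s)
    pmin(pmax(ref + array(rnorm(length(ref), 0, s), dim(ref)), 0), 1)))
  nr <- vapply(tests, function(t) nrmse(ref, t), numeric(1))
  ps <- vapply(tests, function(t) psnr(ref, t), numeric(1))
  expect_equal(order(nr), rev(order(ps)))
  expect_equal(order(nr), seq_along(lvls))
})

test_that("metric reports aggregate per field and formats are ranked", {
  he1 <- fixture_phantom(4, 64)$he
  he2 <- fixture_phantom(5, 64)$he
  noisy <- function(x, s, seed) withr::with_seed(seed,
    pmin(pmax(x + array(rnorm(length(x), 0, s), dim(x)), 0), 1))
  good <- metric_report(list(noisy(he1, 0.02, 1), noisy(he2, 0.02, 2)),
                        list(he1, he2), "IW_FLIM", c("f1", "f2"))
  bad <- metric_report(list(noisy(he1, 0.1, 3), noisy(he2, 0.1, 4)),
                       list(he1, he2), "INTENSITY", c("f1", "f2"))
  expect_equal(nrow(good$per_field), 2)
  expect_true(all(c("nrmse", "nmi", "psnr", "mssim") %in%
                    names(good$aggregate)))
  tab <- compare_formats(list(good, bad))
  # the dominant format wins every metric
  expect_true(all(tab$format_tag[tab$best] == "IW_FLIM"))
  expect_false(any(tab$tie))
  # identical reports tie everywhere; single report ranks first trivially
  tie <- compare_formats(list(good, good))
  expect_true(all(tie$tie))
  single <- compare_formats(list(good))
  expect_true(all(single$rank == 1))
  bad2 <- bad; bad2$field_ids <- c("f1", "f9")
  expect_error(compare_formats(list(good, bad2)), "field sets")
})
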