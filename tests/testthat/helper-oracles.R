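# Independent brute-force oracle for DISTS with the tiny fixed
# extractor: stage-0 maps are the three channels; stage-1 maps are the
# two 2x2-mean combinations, all terms computed directly from global
# means, variances and covariances with uniform normalised weights.
oracle_dists <- function(r, s, c1 = 1e-6, c2 = 1e-6) {
  pool_mean <- function(img) {
    n <- nrow(img) / 2
    o <- matrix(0, n, n)
    for (a in seq_len(n)) for (b in seq_len(n))
      o[a, b] <- mean(img[(2 * a - 1):(2 * a), (2 * b - 1):(2 * b)])
    o
  }
  maps <- function(x) list(
    x[, , 1], x[, , 2], x[, , 3],
    pool_mean((x[, , 1] + x[, , 2] + x[, , 3]) / 3),
    pool_mean((x[, , 1] - x[, , 3]) / 2))
  mr <- maps(r); ms <- maps(s)
  tt <- function(a, b) {
    (2 * mean(a) * mean(b) + c1) / (mean(a)^2 + mean(b)^2 + c1)
  }
  ss <- function(a, b) {
    srs <- mean(a * b) - mean(a) * mean(b)
    (2 * srs + c2) /
      ((mean(a^2) - mean(a)^2) + (mean(b^2) - mean(b)^2) + c2)
  }
  1 - sum(vapply(1:5, function(j)
    (tt(mr[[j]], ms[[j]]) + ss(mr[[j]], ms[[j]])) / 10, numeric(1)))
}
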