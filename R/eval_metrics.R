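# Similarity metrics between virtual and true H&E.
#
# Four full-reference metrics with pinned conventions:
#   NRMSE - Euclidean error normalised by the reference norm (lower
#           better);
#   NMI   - (H1 + H2) / H12 over 256-bin histograms of the greyscale
#           images, in [1, 2] (higher better);
#   PSNR  - 10 log10(peak^2 / MSE) in dB, peak 1 on normalised images
#           (higher better; +Inf for identical images);
#   MSSIM - mean SSIM over 11x11 Gaussian windows (sigma 1.5,
#           K1 = 0.01, K2 = 0.03, data range 1), channels averaged
#           (higher better).

#' Normalised root-mean-squared error
#'
#' `||ref - test||_2 / ||ref||_2` over all pixels and channels.
#'
#' @param ref,test Equal-shaped rasters in `[0, 1]`.
#' @return Non-negative scalar; 0 iff identical.
#' @export
nrmse <- function(ref, test) {
  if (!all(dim(ref) == dim(test))) stop("nrmse: shape mismatch")
  den <- sqrt(sum(ref^2))
  if (den == 0) stop("nrmse undefined for an all-zero reference")
  sqrt(sum((ref - test)^2)) / den
}

#' Normalised mutual information
#'
#' `(H(ref) + H(test)) / H(ref, test)` from a `bins` x `bins` joint
#' histogram of the greyscale images; 1 for independent, 2 for
#' identical images.
#'
#' @param ref,test Equal-shaped rasters in `[0, 1]` (RGB is converted
#'   to luminance first).
#' @param bins Histogram bins per axis (default 256).
#' @return Scalar in `[1, 2]`.
#' @export
nmi <- function(ref, test, bins = 256) {
  if (!all(dim(ref) == dim(test))) stop("nmi: shape mismatch")
  if (length(dim(ref)) == 3) { ref <- luminance(ref); test <- luminance(test) }
  if (max(ref) - min(ref) < 1e-12 || max(test) - min(test) < 1e-12)
    stop("nmi undefined for constant images")
  v <- nmi_pair(ref, test, bins)
  if (!is.finite(v)) stop("nmi undefined (degenerate histogram)")
  v
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB; identical images return `Inf`.
#'
#' @param ref,test Equal-shaped rasters.
#' @param peak Peak signal value (1 on normalised images).
#' @return Scalar in dB (possibly `Inf`).
#' @export
psnr <- function(ref, test, peak = 1.0) {
  if (!all(dim(ref) == dim(test))) stop("psnr: shape mismatch")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

gaussian_window <- function(size = 11, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

ssim_channel <- function(x, y, w, C1, C2) {
  size <- as.integer(sqrt(length(w)))
  d <- dim(x)
  cx <- im2col_c(array(x, c(d, 1, 1)), d[1], d[2], 1L, 1L, size, 1L, 0L)
  cy <- im2col_c(array(y, c(d, 1, 1)), d[1], d[2], 1L, 1L, size, 1L, 0L)
  wv <- as.vector(w)
  mx <- cx %*% wv; my <- cy %*% wv
  sxx <- cx^2 %*% wv - mx^2
  syy <- cy^2 %*% wv - my^2
  sxy <- (cx * cy) %*% wv - mx * my
  mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
         ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
}

#' Mean structural similarity index
#'
#' SSIM averaged over all fully interior 11x11 Gaussian-weighted
#' windows (sigma 1.5), `K1 = 0.01`, `K2 = 0.03`, data range 1; RGB
#' channels scored separately and averaged.
#'
#' @param ref,test Equal-shaped rasters in `[0, 1]`, at least 11x11.
#' @param window,sigma Window size and Gaussian width.
#' @param K1,K2 Stability fractions of the data range.
#' @return Scalar in `[-1, 1]`; 1 iff identical.
#' @export
mssim <- function(ref, test, window = 11, sigma = 1.5,
                  K1 = 0.01, K2 = 0.03) {
  if (!all(dim(ref) == dim(test))) stop("mssim: shape mismatch")
  if (any(dim(ref)[1:2] < window))
    stop("image smaller than the ", window, "x", window, " SSIM window")
  C1 <- K1^2; C2 <- K2^2
  w <- gaussian_window(window, sigma)
  if (is.matrix(ref)) return(ssim_channel(ref, test, w, C1, C2))
  mean(vapply(seq_len(dim(ref)[3]), function(k)
    ssim_channel(ref[, , k], test[, , k], w, C1, C2), numeric(1)))
}

#' Metric report for one input format
#'
#' Computes all four metrics per field and their aggregate means.
#'
#' @param virtual,true Lists of equal-shaped rasters (one per field).
#' @param format_tag Label of the input format evaluated.
#' @param field_ids Field identifiers (defaults to list names or
#'   indices).
#' @return An object of class `metric_report`: `per_field` data.frame
#'   and `aggregate` named vector.
#' @export
metric_report <- function(virtual, true, format_tag = "IW_FLIM",
                          field_ids = NULL) {
  stopifnot(length(virtual) == length(true), length(virtual) >= 1)
  field_ids <- field_ids %||% names(virtual) %||%
    as.character(seq_along(virtual))
  per <- do.call(rbind, lapply(seq_along(virtual), function(i)
    data.frame(field_id = field_ids[i],
               nrmse = nrmse(true[[i]], virtual[[i]]),
               nmi = nmi(true[[i]], virtual[[i]]),
               psnr = psnr(true[[i]], virtual[[i]]),
               mssim = mssim(true[[i]], virtual[[i]]),
               stringsAsFactors = FALSE)))
  structure(list(per_field = per,
                 aggregate = colMeans(per[, -1]),
                 format_tag = format_tag,
                 field_ids = field_ids), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report %s, %d field(s)>\n", x$format_tag,
              nrow(x$per_field)))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Rank input formats across metrics
#'
#' Lower is better for NRMSE; higher is better for NMI, PSNR and
#' MSSIM. All reports must cover the same fields. Ties on a metric are
#' flagged.
#'
#' @param reports List of [metric_report()] objects (>= 1).
#' @return data.frame with one row per metric x format, columns
#'   `metric`, `format_tag`, `value`, `rank`, `best`, `tie`.
#' @export
compare_formats <- function(reports) {
  stopifnot(length(reports) >= 1)
  ids <- lapply(reports, function(r) sort(r$field_ids))
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("metric reports cover different field sets")
  metrics <- c("nrmse", "nmi", "psnr", "mssim")
  lower_better <- c(nrmse = TRUE, nmi = FALSE, psnr = FALSE, mssim = FALSE)
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) unname(r$aggregate[m]), numeric(1))
    o <- if (lower_better[m]) rank(v, ties.method = "min")
         else rank(-v, ties.method = "min")
    data.frame(metric = m,
               format_tag = vapply(reports, `[[`, "", "format_tag"),
               value = v, rank = o, best = o == 1,
               tie = duplicated(v) | duplicated(v, fromLast = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a metric report as TSV (per field) and JSON (aggregate)
#'
#' @param report A [metric_report()].
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @export
write_metric_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(report$per_field, tsv_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(format_tag = report$format_tag,
                              aggregate = as.list(report$aggregate)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
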