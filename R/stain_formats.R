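# Network-input formats.
#
# Three candidate representations of a FLIM field are compared as inputs
# to the stain-translation network:
#   INTENSITY  - inverted normalised photon counts, 1 channel (tissue dark
#                on a white background, matching bright-field contrast);
#   ALPHA_FLIM - false-colour lifetime RGB with normalised intensity
#                appended as a 4th (alpha) channel;
#   IW_FLIM    - false-colour lifetime RGB multiplied pixelwise by
#                normalised intensity ("intensity-weighted").
# Lifetimes are colour-mapped over the fixed display range [1, 5] ns;
# values outside the range saturate at the map ends.

FORMAT_CHANNELS <- c(INTENSITY = 1L, ALPHA_FLIM = 4L, IW_FLIM = 3L)

#' Default false-colour lifetime map
#'
#' A perceptually ordered blue-to-green-to-red lookup table with `n`
#' entries, generated from fixed anchor colours so outputs are identical
#' on every platform. Any 256x3 table in `[0, 1]` may be substituted.
#'
#' @param n Number of entries (default 256).
#' @return `n` x 3 numeric matrix of RGB values in `[0, 1]`.
#' @export
flim_colormap <- function(n = 256) {
  anchors <- matrix(c(
    0.050, 0.030, 0.530,   # deep blue   (short lifetime)
    0.000, 0.420, 0.880,   # azure
    0.000, 0.740, 0.610,   # teal
    0.350, 0.870, 0.200,   # green
    0.900, 0.880, 0.080,   # yellow
    0.980, 0.550, 0.040,   # orange
    0.850, 0.080, 0.060),  # red         (long lifetime)
    ncol = 3, byrow = TRUE)
  pos <- seq(0, 1, length.out = nrow(anchors))
  u <- seq(0, 1, length.out = n)
  cm <- sapply(1:3, function(k) stats::approx(pos, anchors[, k], xout = u)$y)
  dimnames(cm) <- NULL
  cm
}

#' Read / write a colour table as 256-row CSV
#'
#' @param path CSV file with three unnamed columns R,G,B in `[0, 1]`.
#' @return For the reader, an n x 3 matrix.
#' @export
read_colormap_csv <- function(path) {
  cm <- as.matrix(read.csv(path, header = FALSE))
  dimnames(cm) <- NULL
  if (ncol(cm) != 3 || any(cm < 0) || any(cm > 1))
    stop("colour table must have 3 columns with values in [0, 1]")
  cm
}

#' @rdname read_colormap_csv
#' @param colormap Matrix to write.
#' @export
write_colormap_csv <- function(colormap, path) {
  write.table(colormap, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map lifetimes to false colour
#'
#' Positions `u = clip((tau - lo) / (hi - lo), 0, 1)` index the colour
#' table with linear interpolation between entries; `u = 0` returns the
#' first entry and `u = 1` the last. The default display range is the
#' fixed `[1, 5]` ns window; sub-range lifetimes saturate at `u = 0`.
#'
#' @param lifetime 2-D lifetime raster in ns (clamped to `[0, 5]`).
#' @param colormap n x 3 lookup table, default [flim_colormap()].
#' @param lifetime_range `(lo, hi)` display window in ns, `lo < hi`.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
lifetime_to_rgb <- function(lifetime, colormap = flim_colormap(),
                            lifetime_range = c(1, 5)) {
  lifetime <- as_raster2d(lifetime, "lifetime")
  lo <- lifetime_range[1]; hi <- lifetime_range[2]
  if (!(lo < hi)) stop("lifetime_range must satisfy lo < hi")
  n <- nrow(colormap)
  u <- clip01((lifetime - lo) / (hi - lo))
  pos <- u * (n - 1)
  i0 <- pmin(floor(pos), n - 2)
  frac <- pos - i0
  out <- array(0, c(dim(lifetime), 3))
  for (k in 1:3)
    out[, , k] <- (1 - frac) * colormap[i0 + 1, k] + frac * colormap[i0 + 2, k]
  out
}

#' Construct a network-input raster
#'
#' @param pixels H x W x C array in `[0, 1]`.
#' @param format_tag One of `"INTENSITY"`, `"ALPHA_FLIM"`, `"IW_FLIM"`.
#' @param colormap_name Identifier of the colour table used.
#' @param lifetime_range Display window `(lo, hi)` in ns.
#' @return An object of class `stain_input`.
#' @export
stain_input <- function(pixels, format_tag, colormap_name = "flim_default",
                        lifetime_range = c(1, 5)) {
  format_tag <- match.arg(format_tag, names(FORMAT_CHANNELS))
  if (length(dim(pixels)) == 2) dim(pixels) <- c(dim(pixels), 1L)
  if (dim(pixels)[3] != FORMAT_CHANNELS[[format_tag]])
    stop(format_tag, " requires ", FORMAT_CHANNELS[[format_tag]],
         " channels, got ", dim(pixels)[3])
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("stain input channels must lie in [0, 1]")
  if (!(lifetime_range[1] < lifetime_range[2]))
    stop("lifetime_range must satisfy lo < hi")
  structure(list(pixels = pixels, format_tag = format_tag,
                 colormap_name = colormap_name,
                 lifetime_range = lifetime_range), class = "stain_input")
}

#' @export
print.stain_input <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stain_input %s %dx%dx%d, range [%.3f, %.3f]>\n", x$format_tag,
              d[1], d[2], d[3], min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Greyscale intensity input
#'
#' Inverted normalised intensity (`1 - I_norm`), so tissue appears dark
#' on a white background as in bright-field H&E.
#'
#' @param field A clamped [flim_field()].
#' @param ctx A [norm_ctx()].
#' @return A single-channel [stain_input()].
#' @export
make_intensity_input <- function(field, ctx = norm_ctx()) {
  stain_input(1 - normalise_intensity(field, ctx), "INTENSITY")
}

#' Alpha-FLIM input
#'
#' False-colour lifetime RGB with normalised (non-inverted) intensity as
#' the alpha channel: `[R, G, B, alpha]`.
#'
#' @inheritParams make_intensity_input
#' @param colormap Colour table for [lifetime_to_rgb()].
#' @param lifetime_range Display window in ns.
#' @return A 4-channel [stain_input()].
#' @export
make_alpha_flim <- function(field, ctx = norm_ctx(),
                            colormap = flim_colormap(),
                            lifetime_range = c(1, 5)) {
  rgb <- lifetime_to_rgb(field$lifetime, colormap, lifetime_range)
  px <- array(0, c(dim(field$lifetime), 4))
  px[, , 1:3] <- rgb
  px[, , 4] <- normalise_intensity(field, ctx)
  stain_input(px, "ALPHA_FLIM", lifetime_range = lifetime_range)
}

#' Intensity-weighted FLIM input
#'
#' Each false-colour channel is multiplied pixelwise by normalised
#' intensity used as a soft weight, so signal-free pixels are black.
#'
#' @inheritParams make_alpha_flim
#' @return A 3-channel [stain_input()].
#' @export
make_iw_flim <- function(field, ctx = norm_ctx(), colormap = flim_colormap(),
                         lifetime_range = c(1, 5)) {
  rgb <- lifetime_to_rgb(field$lifetime, colormap, lifetime_range)
  w <- normalise_intensity(field, ctx)
  for (k in 1:3) rgb[, , k] <- rgb[, , k] * w
  stain_input(rgb, "IW_FLIM", lifetime_range = lifetime_range)
}

#' Save a stain input as an 8-bit PNG for inspection
#'
#' `ALPHA_FLIM` is written as RGBA, `IW_FLIM` as RGB and `INTENSITY` as
#' greyscale. Training uses the float arrays directly; the PNG is a
#' quantised view.
#'
#' @param x A [stain_input()].
#' @param path Output PNG path.
#' @export
write_stain_png <- function(x, path) {
  stopifnot(inherits(x, "stain_input"))
  px <- x$pixels
  if (dim(px)[3] == 1) px <- array(px, dim(px)[1:2])
  png::writePNG(px, path)
  invisible(path)
}
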