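# Co-registration of H&E targets to the FLIM grid and patch extraction.
#
# The H&E bright-field image is converted to a contrast-stretched
# greyscale, resampled to the FLIM pixel size with bicubic interpolation,
# and registered to the inverted FLIM intensity with a 6-parameter affine
# transform maximising normalised mutual information over a
# multi-resolution pyramid. Co-registered pairs are then cut into fixed
# patches; patches dominated by background are discarded.

#' Affine transform between pixel grids
#'
#' A 2x3 matrix `[L | t]` mapping moving-image `(row, col)` 0-based pixel
#' coordinates to fixed-image coordinates. The linear part must be
#' invertible.
#'
#' @param m 2x3 numeric matrix (or 6-vector, row-major).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(m) {
  if (is.numeric(m) && length(m) == 6 && is.null(dim(m)))
    m <- matrix(m, 2, 3, byrow = TRUE)
  stopifnot(is.matrix(m), all(dim(m) == c(2, 3)))
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(det) || abs(det) < 1e-12)
    stop("affine transform is singular (determinant ~ 0)")
  structure(list(m = m), class = "affine_transform")
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform(cbind(diag(2), c(0, 0)))

#' Invert / compose affine transforms
#'
#' `affine_compose(a, b)` returns the transform applying `b` first, then
#' `a`.
#'
#' @param a,b [affine_transform()] objects.
#' @return An [affine_transform()].
#' @export
affine_invert <- function(a) {
  L <- a$m[, 1:2]; t <- a$m[, 3]
  Li <- solve(L)
  affine_transform(cbind(Li, -Li %*% t))
}

#' @rdname affine_invert
#' @export
affine_compose <- function(a, b) {
  La <- a$m[, 1:2]; Lb <- b$m[, 1:2]
  affine_transform(cbind(La %*% Lb, La %*% b$m[, 3] + a$m[, 3]))
}

#' Build an affine transform from pose parameters
#'
#' Rotation (degrees), anisotropic scale, shear and translation (pixels)
#' about a given centre, in the order scale/shear, then rotation, then
#' translation.
#'
#' @param tx,ty Translation in pixels (row, col).
#' @param angle Rotation in degrees (counter-clockwise in row/col space).
#' @param sx,sy Scale factors.
#' @param shear Shear coefficient.
#' @param centre `(row, col)` rotation centre, 0-based.
#' @return An [affine_transform()].
#' @export
affine_from_params <- function(tx = 0, ty = 0, angle = 0, sx = 1, sy = 1,
                               shear = 0, centre = c(0, 0)) {
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(sx, 0, shear, sy), 2, 2)
  L <- R %*% S
  t <- c(tx, ty) + centre - L %*% centre
  affine_transform(cbind(L, t))
}

#' Serialise an affine transform to / from a 6-number JSON array
#'
#' Row-major 2x3 layout.
#'
#' @param a An [affine_transform()]; `path` a JSON file path.
#' @export
write_affine_json <- function(a, path) {
  jsonlite::write_json(as.vector(t(a$m)), path, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  affine_transform(unlist(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' Mean corner displacement between two transforms
#'
#' Average distance (pixels) between the images of the four corners of a
#' `shape`-sized image under `a` and `b`; the registration-accuracy
#' score.
#'
#' @param a,b [affine_transform()] objects.
#' @param shape `(H, W)` of the image the transforms act on.
#' @return Mean corner error in pixels.
#' @export
corner_error <- function(a, b, shape) {
  H <- shape[1]; W <- shape[2]
  corners <- rbind(c(0, 0), c(0, W - 1), c(H - 1, 0), c(H - 1, W - 1))
  pa <- corners %*% t(a$m[, 1:2]) + rep(1, 4) %o% a$m[, 3]
  pb <- corners %*% t(b$m[, 1:2]) + rep(1, 4) %o% b$m[, 3]
  mean(sqrt(rowSums((pa - pb)^2)))
}

#' Resample an image through an affine transform
#'
#' Inverse-warps `image` (the moving image) onto the fixed grid: output
#' pixel `p` samples the moving image at `t^{-1}(p)` with bilinear
#' interpolation. Out-of-domain pixels take `fill` (1 = white for H&E,
#' 0 for intensity, `NA` to mark invalid).
#'
#' @param image 2-D matrix or H x W x C array.
#' @param t An [affine_transform()] mapping moving to fixed coordinates.
#' @param out_shape `(H, W)` of the output grid.
#' @param fill Fill value for pixels mapping outside the image.
#' @return Array of shape `out_shape` (x C).
#' @export
apply_affine <- function(image, t, out_shape = dim(image)[1:2], fill = 0) {
  stopifnot(inherits(t, "affine_transform"))
  was_2d <- is.matrix(image)
  if (was_2d) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  Ainv <- affine_invert(t)$m
  out <- warp_affine_c(image, d[1], d[2], d[3], Ainv,
                       as.integer(out_shape[1]), as.integer(out_shape[2]),
                       as.double(fill))
  if (was_2d) dim(out) <- out_shape[1:2]
  out
}

#' Prepare an H&E image for registration
#'
#' Luminance greyscale, linearly stretched so the 1st and 99th intensity
#' percentiles map to 0 and 1 (1% saturation at both tails).
#'
#' @param he_rgb H x W x 3 array in `[0, 1]`.
#' @return 2-D matrix in `[0, 1]`.
#' @export
prepare_he_for_registration <- function(he_rgb) {
  g <- if (is.matrix(he_rgb)) he_rgb else luminance(he_rgb)
  q <- quantile(g, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] < 1e-12)
    stop("H&E image has no dynamic range (constant after greyscale)")
  clip01((g - q[1]) / (q[2] - q[1]))
}

#' Downsample H&E to the FLIM pixel grid
#'
#' Bicubic resampling from the scanner pixel size to the (coarser) FLIM
#' pixel size, e.g. 0.22 to 0.455 micrometres.
#'
#' @param he_rgb H x W x 3 (or 2-D) raster in `[0, 1]`.
#' @param src_pixel_size,dst_pixel_size Pixel edges in micrometres;
#'   `dst >= src > 0`.
#' @return Resampled raster, clipped to `[0, 1]`.
#' @export
downsample_he <- function(he_rgb, src_pixel_size, dst_pixel_size) {
  if (src_pixel_size <= 0 || dst_pixel_size <= 0)
    stop("pixel sizes must be positive")
  if (src_pixel_size == dst_pixel_size) return(he_rgb)
  was_2d <- is.matrix(he_rgb)
  if (was_2d) dim(he_rgb) <- c(dim(he_rgb), 1L)
  d <- dim(he_rgb)
  outH <- max(1L, round(d[1] * src_pixel_size / dst_pixel_size))
  outW <- max(1L, round(d[2] * src_pixel_size / dst_pixel_size))
  out <- clip01(resize_bicubic_c(he_rgb, d[1], d[2], d[3],
                                 as.integer(outH), as.integer(outW)))
  if (was_2d) dim(out) <- dim(out)[1:2]
  out
}

box_down2 <- function(x) {
  d <- dim(x)
  i <- seq(1, d[1] - d[1] %% 2, 2); j <- seq(1, d[2] - d[2] %% 2, 2)
  (x[i, j, drop = FALSE] + x[i + 1, j, drop = FALSE] +
     x[i, j + 1, drop = FALSE] + x[i + 1, j + 1, drop = FALSE]) / 4
}

# Normalised mutual information (H1 + H2) / H12 between two rasters;
# NA pixels (outside the warp domain) are ignored.
nmi_pair <- function(a, b, bins = 32) {
  h <- joint_hist_c(as.vector(a), as.vector(b), as.integer(bins))
  n <- sum(h)
  if (n == 0) return(NA_real_)
  p <- h / n
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  h12 <- ent(p)
  if (h12 == 0) return(NA_real_)
  (ent(px) + ent(py)) / h12
}

params_to_affine <- function(p, centre) {
  affine_from_params(tx = p[1], ty = p[2], angle = p[3],
                     sx = exp(p[4]), sy = exp(p[5]), shear = p[6],
                     centre = centre)
}

# Rescale a moving->fixed transform to a pyramid level (factor f <= 1).
scale_affine <- function(a, f) {
  m <- a$m
  affine_transform(cbind(m[, 1:2], m[, 3] * f))
}

#' Estimate the affine registration between two rasters
#'
#' Maximises normalised mutual information between the warped moving
#' image and the fixed image over a multi-resolution pyramid (default 3
#' levels). At the coarsest level a deterministic grid search over
#' translations and rotations seeds a Nelder-Mead refinement of the full
#' 6-parameter pose (translation, rotation, log-scales, shear), which is
#' then propagated down the pyramid. Both images should be preprocessed
#' to comparable contrast (inverted normalised intensity vs. stretched
#' greyscale H&E) and share the same pixel spacing.
#'
#' Alternatively, `method = "points"` fits the least-squares affine
#' through matched control points.
#'
#' @param moving,fixed 2-D rasters in `[0, 1]`.
#' @param init Optional [affine_transform()] initial guess (skips the
#'   coarse search).
#' @param method `"mi"` (default) or `"points"`.
#' @param points For `"points"`: list with `moving` and `fixed`, each an
#'   n x 2 matrix of `(row, col)` coordinates, n >= 3.
#' @param levels Pyramid depth.
#' @param bins Joint-histogram bins for the similarity.
#' @param max_shift,max_angle Search radius of the coarse initialisation
#'   (pixels at full resolution / degrees).
#' @return An [affine_transform()] mapping moving to fixed coordinates,
#'   with the final similarity in `attr(, "similarity")`.
#' @export
estimate_affine <- function(moving, fixed, init = NULL,
                            method = c("mi", "points"), points = NULL,
                            levels = 3, bins = 32,
                            max_shift = 24, max_angle = 15) {
  method <- match.arg(method)
  if (method == "points") {
    stopifnot(!is.null(points), nrow(points$moving) >= 3)
    X <- cbind(points$moving, 1)
    fit <- qr.solve(X, points$fixed)      # 3x2: rows (row,col,1) -> fixed
    return(affine_transform(rbind(c(fit[1, 1], fit[2, 1], fit[3, 1]),
                                  c(fit[1, 2], fit[2, 2], fit[3, 2]))))
  }
  stopifnot(is.matrix(moving), is.matrix(fixed))
  pyr_m <- list(moving); pyr_f <- list(fixed)
  for (l in seq_len(levels - 1)) {
    pyr_m[[l + 1]] <- box_down2(pyr_m[[l]])
    pyr_f[[l + 1]] <- box_down2(pyr_f[[l]])
  }
  centre <- (dim(fixed) - 1) / 2
  obj <- function(p, mov, fix, ctr) {
    t <- tryCatch(params_to_affine(p, ctr), error = function(e) NULL)
    if (is.null(t)) return(1e6)
    w <- apply_affine(mov, t, dim(fix), fill = NA)
    v <- nmi_pair(w, fix, bins)
    if (!is.finite(v)) 1e6 else -v
  }
  # Parameters live at full-resolution scale; divide lengths per level.
  p <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init)) {
    m <- init$m
    p[1:2] <- m[, 3] + (m[, 1:2] %*% centre - centre)  # approx: translation at centre
    p[3] <- atan2(m[2, 1], m[1, 1]) * 180 / pi
  } else {
    lv <- levels
    f <- 1 / 2^(lv - 1)
    ctr <- (dim(pyr_f[[lv]]) - 1) / 2
    shifts <- seq(-ceiling(max_shift * f) - 2, ceiling(max_shift * f) + 2, 1)
    angles <- seq(-max_angle, max_angle, by = 5)
    best <- c(Inf, 0, 0, 0)
    for (ang in angles) for (dy in shifts) for (dx in shifts) {
      v <- obj(c(dy, dx, ang, 0, 0, 0), pyr_m[[lv]], pyr_f[[lv]], ctr)
      if (v < best[1]) best <- c(v, dy, dx, ang)
    }
    p <- c(best[2] / f, best[3] / f, best[4], 0, 0, 0)
  }
  val <- NA_real_
  for (lv in seq(levels, 1)) {
    f <- 1 / 2^(lv - 1)
    ctr <- (dim(pyr_f[[lv]]) - 1) / 2
    plv <- c(p[1:2] * f, p[3:6])
    scale_par <- c(rep(max(1, 4 * f), 2), 2, 0.05, 0.05, 0.05)
    opt <- stats::optim(plv, obj, mov = pyr_m[[lv]], fix = pyr_f[[lv]],
                        ctr = ctr, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-9,
                                       parscale = scale_par))
    if (!is.finite(opt$value) || opt$value >= 1e6)
      stop("affine registration failed to converge (last similarity ",
           format(-opt$value), ")")
    p <- c(opt$par[1:2] / f, opt$par[3:6])
    val <- -opt$value
  }
  out <- params_to_affine(p, centre)
  attr(out, "similarity") <- val
  out
}

#' Background mask from FLIM intensity
#'
#' A pixel is background when its normalised intensity falls below
#' `threshold` (default 0.05): signal-free regions carry essentially no
#' photons.
#'
#' @param field A clamped [flim_field()].
#' @param ctx A [norm_ctx()].
#' @param threshold Normalised-intensity cutoff.
#' @return Logical matrix, `TRUE` = background.
#' @export
background_mask <- function(field, ctx = norm_ctx(), threshold = 0.05) {
  normalise_intensity(field, ctx) < threshold
}

#' Cut co-registered images into filtered training patches
#'
#' Walks a regular grid of `patch` x `patch` windows at the given stride
#' (top-left origins; partial edge windows are skipped), computes each
#' window's background fraction from `background_mask`, and drops
#' windows with strictly more than `max_background` background. Crops
#' are exact sub-arrays of the inputs.
#'
#' @param input_image A [stain_input()] (or H x W x C array).
#' @param target_image H x W x 3 H&E raster in `[0, 1]`, same grid.
#' @param background_mask Logical H x W matrix, `TRUE` = background.
#' @param patch Patch edge in pixels (default 256).
#' @param stride Grid stride in pixels (default `patch`, non-overlapping).
#' @param max_background Retention bound; a patch is dropped iff its
#'   background fraction exceeds this (default 0.75, strict).
#' @return List of `patch_pair` objects with fields `input_patch`,
#'   `target_patch`, `background_fraction`, `origin` (0-based row, col);
#'   counts kept/dropped in `attr(, "n_dropped")`.
#' @export
extract_patches <- function(input_image, target_image, background_mask,
                            patch = 256, stride = patch,
                            max_background = 0.75) {
  px <- if (inherits(input_image, "stain_input")) input_image$pixels
        else input_image
  if (is.matrix(px)) dim(px) <- c(dim(px), 1L)
  if (is.matrix(target_image)) dim(target_image) <- c(dim(target_image), 1L)
  H <- dim(px)[1]; W <- dim(px)[2]
  stopifnot(all(dim(target_image)[1:2] == c(H, W)),
            all(dim(background_mask) == c(H, W)))
  if (patch > H || patch > W)
    stop("patch size ", patch, " exceeds image size ", H, "x", W)
  origins <- expand.grid(row = seq(1, H - patch + 1, by = stride),
                         col = seq(1, W - patch + 1, by = stride))
  pairs <- list(); dropped <- 0L
  for (i in seq_len(nrow(origins))) {
    r <- origins$row[i]; c <- origins$col[i]
    bf <- mean(background_mask[r:(r + patch - 1), c:(c + patch - 1)])
    if (bf > max_background) { dropped <- dropped + 1L; next }
    pairs[[length(pairs) + 1L]] <- structure(
      list(input_patch = px[r:(r + patch - 1), c:(c + patch - 1), , drop = FALSE],
           target_patch = target_image[r:(r + patch - 1), c:(c + patch - 1), ,
                                       drop = FALSE],
           background_fraction = bf,
           origin = c(row = r - 1L, col = c - 1L)),
      class = "patch_pair")
  }
  log_event("extract_patches", kept = length(pairs), dropped = dropped)
  attr(pairs, "n_dropped") <- dropped
  pairs
}
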