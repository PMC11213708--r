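# Synthetic tissue phantoms.
#
# The phantom generator is the package's paired-data substrate: a
# multi-cell-type tissue layout in which each cell type carries its own
# lifetime distribution and brightness, photon counting is Poisson, and a
# bright-field H&E rendering is derived from the *geometry alone*
# (haematoxylin in nuclei, eosin in cytoplasm, via Beer-Lambert optical
# densities). Because the H&E never sees lifetime or intensity values, a
# translation network trained on phantoms must genuinely learn the
# FLIM-to-stain mapping rather than copy channels through.

#' Default phantom cell types
#'
#' Seven cell types common in the lung tumour microenvironment with mean
#' lifetimes set to published per-type values (0.251-2.42 ns) so phantom
#' demonstrations echo real tissue biology. Brightness makes macrophages
#' bright and red blood cells dim, mirroring their visibility in real
#' FLIM intensity images.
#'
#' @return data.frame with columns `name`, `mean_lifetime` (ns),
#'   `lifetime_sd` (ns), `mean_brightness` (counts), `nucleus_radius`
#'   (px) and `density` (cells per 10^4 px).
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("rbc", "fibroblast", "tumour", "lymphocyte",
             "neutrophil", "plasma", "macrophage"),
    mean_lifetime = c(0.251, 0.376, 0.424, 0.471, 0.659, 0.690, 2.420),
    lifetime_sd = rep(0.05, 7),
    mean_brightness = c(120, 300, 500, 450, 600, 650, 1500),
    nucleus_radius = c(2, 3, 4, 2, 3, 3, 5),
    density = c(1.0, 1.0, 1.2, 1.0, 0.8, 0.8, 0.6),
    stringsAsFactors = FALSE)
}

#' Phantom specification
#'
#' Cells live inside a circular tissue core (emulating a TMA core) filled
#' with autofluorescent stroma; pixels outside the core are signal-free
#' background. A spec whose densities are all zero describes an empty
#' slide region: no core is drawn at all.
#'
#' @param image_size `(H, W)` in pixels.
#' @param cell_types data.frame as in [default_cell_types()].
#' @param background_brightness Poisson mean of signal-free pixels (counts).
#' @param stroma_brightness Poisson mean of extracellular tissue (counts).
#' @param stroma_lifetime,stroma_lifetime_sd Gaussian lifetime of the
#'   stroma compartment (ns); short, collagen-like by default.
#' @param core_radius_frac Tissue-core radius as a fraction of the
#'   smaller image edge.
#' @param pixel_size Pixel edge in micrometres.
#' @param seed Integer; fixes the phantom bit-exactly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256, 256),
                         cell_types = default_cell_types(),
                         background_brightness = 20,
                         stroma_brightness = 150,
                         stroma_lifetime = 0.45, stroma_lifetime_sd = 0.1,
                         core_radius_frac = 0.48,
                         pixel_size = 0.455, seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 16))
  req <- c("name", "mean_lifetime", "lifetime_sd", "mean_brightness",
           "nucleus_radius", "density")
  if (!all(req %in% names(cell_types)))
    stop("cell_types must have columns: ", paste(req, collapse = ", "))
  if (any(cell_types$mean_lifetime <= 0) || any(cell_types$mean_lifetime >= 5))
    stop("mean lifetimes must lie in (0, 5) ns")
  if (any(cell_types$density < 0)) stop("densities must be >= 0")
  structure(list(image_size = as.integer(image_size), cell_types = cell_types,
                 background_brightness = background_brightness,
                 stroma_brightness = stroma_brightness,
                 stroma_lifetime = stroma_lifetime,
                 stroma_lifetime_sd = stroma_lifetime_sd,
                 core_radius_frac = core_radius_frac,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Disk offsets around a centre, clipped to the image.
disk_pixels <- function(cy, cx, r, H, W) {
  ys <- max(1, cy - r):min(H, cy + r)
  xs <- max(1, cx - r):min(W, cx + r)
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$y - cy)^2 + (g$x - cx)^2 <= r^2
  g[keep, , drop = FALSE]
}

#' Generate a paired phantom sample
#'
#' Places non-overlapping cells by rejection sampling at the requested
#' densities, paints circular nuclei with cytoplasm halos into a label
#' mask, draws per-pixel lifetimes from each type's Gaussian, photon
#' counts from Poisson distributions, and renders H&E from the geometry
#' via Beer-Lambert mixing of haematoxylin and eosin optical densities.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_sample`: list with `flim`
#'   ([flim_field()]), `he` (H x W x 3 in `[0, 1]`), `annot`
#'   ([cell_annotation()]), `truth` (per-cell table) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ct <- spec$cell_types
  with_seed(spec$seed, {
    # The tissue core: a centred disc; omitted entirely for an all-zero
    # density spec (empty slide region).
    core_ctr <- c((H + 1) / 2, (W + 1) / 2)
    core_r <- if (sum(ct$density) == 0) 0
              else spec$core_radius_frac * min(H, W)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    core <- (yy - core_ctr[1])^2 + (xx - core_ctr[2])^2 <= core_r^2
    centres <- data.frame(y = integer(), x = integer(), halo = integer(),
                          type = character(), stringsAsFactors = FALSE)
    for (t in seq_len(nrow(ct))) {
      n_t <- round(ct$density[t] * H * W / 1e4)
      halo <- 2L * ct$nucleus_radius[t]
      placed <- 0; attempts <- 0
      while (placed < n_t) {
        attempts <- attempts + 1
        if (attempts > 200 * max(n_t, 1))
          stop("cell density too high: could not place non-overlapping '",
               ct$name[t], "' cells after ", attempts, " attempts")
        cy <- round(runif(1, halo + 1, H - halo))
        cx <- round(runif(1, halo + 1, W - halo))
        if ((cy - core_ctr[1])^2 + (cx - core_ctr[2])^2 >
              max(core_r - halo, 0)^2) next
        if (nrow(centres) > 0) {
          d2 <- (centres$y - cy)^2 + (centres$x - cx)^2
          if (any(d2 < (centres$halo + halo + 1)^2)) next
        }
        centres <- rbind(centres, data.frame(y = cy, x = cx, halo = halo,
                                             type = ct$name[t]))
        placed <- placed + 1
      }
    }
    mask <- matrix(0L, H, W)
    nuc <- matrix(FALSE, H, W)
    cyto <- matrix(FALSE, H, W)
    labels <- data.frame(label = integer(), cell_type = character(),
                         stringsAsFactors = FALSE)
    lifetime <- matrix(0, H, W)
    lifetime[core] <- rnorm(sum(core), spec$stroma_lifetime,
                            spec$stroma_lifetime_sd)
    intensity <- matrix(rpois(H * W, spec$background_brightness), H, W)
    intensity[core] <- rpois(sum(core), spec$stroma_brightness)
    if (nrow(centres) > 0) {
      for (i in seq_len(nrow(centres))) {
        t <- match(centres$type[i], ct$name)
        r <- ct$nucleus_radius[t]
        cell <- disk_pixels(centres$y[i], centres$x[i], 2 * r, H, W)
        nucp <- disk_pixels(centres$y[i], centres$x[i], r, H, W)
        idx <- cbind(cell$y, cell$x)
        nidx <- cbind(nucp$y, nucp$x)
        mask[idx] <- i
        nuc[nidx] <- TRUE
        cyto[idx] <- TRUE
        lifetime[idx] <- rnorm(nrow(idx), ct$mean_lifetime[t],
                               ct$lifetime_sd[t])
        intensity[idx] <- rpois(nrow(idx), ct$mean_brightness[t])
        labels <- rbind(labels, data.frame(label = i,
                                           cell_type = centres$type[i]))
      }
      cyto <- cyto & !nuc
    }
    lifetime <- pmin(pmax(lifetime, 0), 5)
    # Beer-Lambert H&E rendering from geometry only (Ruifrok stain vectors).
    c_h <- c(0.650, 0.704, 0.286)  # haematoxylin absorbance per channel
    c_e <- c(0.092, 0.954, 0.283)  # eosin absorbance per channel
    stroma <- core & !nuc & !cyto
    od_h <- 1.00 * nuc + 0.08 * cyto + 0.03 * stroma
    od_e <- 0.15 * nuc + 0.45 * cyto + 0.25 * stroma
    he <- array(0, c(H, W, 3))
    for (k in 1:3) he[, , k] <- exp(-(od_h * c_h[k] + od_e * c_e[k]))
    flim <- flim_field(intensity, lifetime, spec$pixel_size,
                       sprintf("phantom-%d", spec$seed))
    annot <- cell_annotation(mask, labels)
    truth <- cbind(centres,
                   mean_lifetime = ct$mean_lifetime[match(centres$type, ct$name)])
    structure(list(flim = flim, he = he, annot = annot, truth = truth,
                   spec = spec), class = "phantom_sample")
  })
}

#' Misalign and degrade a phantom pair
#'
#' Warps the H&E rendering by a known affine transform and adds Gaussian
#' pixel noise, retaining the ground-truth transform so registration
#' recovery can be scored against it. Uses the current RNG stream for the
#' noise; seed externally for reproducibility.
#'
#' @param sample A [phantom_sample][generate_phantom()].
#' @param affine An [affine_transform()] (must be invertible).
#' @param noise_sd Gaussian noise standard deviation on `[0, 1]` pixels.
#' @return List with `he` (degraded raster), `true_affine`, `noise_sd`
#'   and the original `sample`.
#' @export
degrade_pair <- function(sample, affine = affine_identity(), noise_sd = 0) {
  stopifnot(inherits(sample, "phantom_sample"))
  he <- apply_affine(sample$he, affine, dim(sample$he)[1:2], fill = 1)
  if (noise_sd > 0)
    he <- clip01(he + array(rnorm(length(he), 0, noise_sd), dim(he)))
  list(he = he, true_affine = affine, noise_sd = noise_sd, sample = sample)
}

#' Build paired training patches from a phantom cohort
#'
#' Generates `n_fields` phantoms (seeds `seed, seed+1, ...`), converts
#' each to the requested network-input format, and cuts
#' background-filtered patches — the in-memory equivalent of the disk
#' pipeline, handy for training experiments and examples.
#'
#' @param n_fields Number of phantom fields.
#' @param image_size `(H, W)` per field.
#' @param patch,stride Patch geometry (see [extract_patches()]).
#' @param seed Base seed; field `i` uses `seed + i - 1`.
#' @param format_tag `"INTENSITY"`, `"ALPHA_FLIM"` or `"IW_FLIM"`.
#' @param max_background Patch-filter bound.
#' @return List of `patch_pair` objects.
#' @export
phantom_patch_pairs <- function(n_fields = 12, image_size = c(256, 256),
                                patch = 64, stride = patch, seed = 1,
                                format_tag = "IW_FLIM",
                                max_background = 0.75) {
  ctx <- norm_ctx()
  pairs <- list()
  for (i in seq_len(n_fields)) {
    ph <- generate_phantom(phantom_spec(image_size = image_size,
                                        seed = seed + i - 1L))
    fld <- clamp_flim(ph$flim)
    si <- switch(format_tag,
                 INTENSITY = make_intensity_input(fld, ctx),
                 ALPHA_FLIM = make_alpha_flim(fld, ctx),
                 IW_FLIM = make_iw_flim(fld, ctx),
                 stop("unknown format_tag: ", format_tag))
    pairs <- c(pairs, extract_patches(si, ph$he, background_mask(fld, ctx),
                                      patch = patch, stride = stride,
                                      max_background = max_background))
  }
  pairs
}

#' Write a phantom sample in the raw-data layout the pipeline consumes
#'
#' Emits `<id>_intensity.tif`, `<id>_lifetime.tif` (float TIFF + JSON
#' sidecars), `<id>_he.png`, `<id>_annot.tif` (16-bit label mask) and
#' `<id>_labels.json` under `dir`.
#'
#' @param sample A phantom sample.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the field id.
#' @export
write_phantom <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sample$flim$field_id
  write_flim_field(sample$flim,
                   file.path(dir, paste0(id, "_intensity.tif")),
                   file.path(dir, paste0(id, "_lifetime.tif")))
  png::writePNG(sample$he, file.path(dir, paste0(id, "_he.png")))
  tiff::writeTIFF(sample$annot$mask / 65535,
                  file.path(dir, paste0(id, "_annot.tif")),
                  bits.per.sample = 16L)
  jsonlite::write_json(sample$annot$labels,
                       file.path(dir, paste0(id, "_labels.json")),
                       digits = NA)
  invisible(id)
}
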