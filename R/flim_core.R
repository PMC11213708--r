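# FLIM data model and file I/O.
#
# A FLIM acquisition exports two single-channel rasters per field: photon
# counts ("intensity") and the fitted decay time in nanoseconds
# ("lifetime"). Raw instrument values are clamped to fixed display ranges
# ([0, 2000] counts, [0, 5] ns) before any downstream processing so that
# all cohorts share one value scale.

#' Construct a FLIM field
#'
#' Bundles the registered intensity and lifetime rasters of one imaged
#' field together with its physical pixel size. Rasters are stored
#' row-major with the origin at the top-left pixel.
#'
#' @param intensity Numeric matrix of photon counts (>= 0).
#' @param lifetime Numeric matrix of fitted lifetimes in ns, same shape.
#' @param pixel_size Physical pixel edge in micrometres (> 0).
#' @param field_id Opaque identifier used in logs and manifests.
#' @return An object of class `flim_field`.
#' @export
flim_field <- function(intensity, lifetime, pixel_size, field_id = "field") {
  intensity <- as_raster2d(intensity, "intensity")
  lifetime <- as_raster2d(lifetime, "lifetime")
  if (!all(dim(intensity) == dim(lifetime)))
    stop("intensity and lifetime rasters differ in shape: ",
         paste(dim(intensity), collapse = "x"), " vs ",
         paste(dim(lifetime), collapse = "x"))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number (micrometres)")
  structure(list(intensity = intensity, lifetime = lifetime,
                 pixel_size = pixel_size, field_id = as.character(field_id)),
            class = "flim_field")
}

#' @export
print.flim_field <- function(x, ...) {
  cat(sprintf("<flim_field '%s' %dx%d px, pixel %.3f um>\n", x$field_id,
              nrow(x$intensity), ncol(x$intensity), x$pixel_size))
  cat(sprintf("  intensity: [%.1f, %.1f] counts; lifetime: [%.3f, %.3f] ns\n",
              min(x$intensity), max(x$intensity),
              min(x$lifetime), max(x$lifetime)))
  invisible(x)
}

#' Clamp a FLIM field to the fixed display ranges
#'
#' Photon counts are clipped to `[0, intensity_max]` and lifetimes to
#' `[0, lifetime_max]` ns; all in-range pixels are untouched. The
#' operation is idempotent.
#'
#' @param field A [flim_field()].
#' @param intensity_max Upper clamp bound for counts (default 2000).
#' @param lifetime_max Upper clamp bound in ns (default 5).
#' @return The clamped `flim_field`.
#' @export
clamp_flim <- function(field, intensity_max = 2000, lifetime_max = 5) {
  stopifnot(inherits(field, "flim_field"))
  field$intensity <- pmin(pmax(field$intensity, 0), intensity_max)
  field$lifetime <- pmin(pmax(field$lifetime, 0), lifetime_max)
  field
}

#' Per-cohort intensity normalisation bounds
#'
#' Intensity is normalised globally per cohort (e.g. per TMA core), never
#' per patch, so brightness differences between fields are preserved.
#' With no cohort statistics the bounds default to the clamp range
#' `(0, 2000)`.
#'
#' @param intensity_min,intensity_max Cohort bounds in photon counts;
#'   `intensity_max > intensity_min >= 0` is required.
#' @return An object of class `norm_ctx`.
#' @export
norm_ctx <- function(intensity_min = 0, intensity_max = 2000) {
  if (!is.finite(intensity_min) || !is.finite(intensity_max) ||
      intensity_min < 0 || intensity_max <= intensity_min)
    stop("degenerate normalisation bounds: need max > min >= 0, got (",
         intensity_min, ", ", intensity_max, ")")
  structure(list(intensity_min = intensity_min,
                 intensity_max = intensity_max), class = "norm_ctx")
}

#' Compute normalisation bounds from a cohort of fields
#'
#' @param fields List of clamped [flim_field()] objects from one cohort.
#' @return A [norm_ctx()] spanning the cohort's intensity range.
#' @export
ctx_from_fields <- function(fields) {
  stopifnot(length(fields) >= 1)
  lo <- min(vapply(fields, function(f) min(f$intensity), numeric(1)))
  hi <- max(vapply(fields, function(f) max(f$intensity), numeric(1)))
  norm_ctx(max(lo, 0), hi)
}

#' Normalise intensity to [0, 1] under cohort bounds
#'
#' Linear rescale `(I - min) / (max - min)`, clipped to `[0, 1]`.
#'
#' @param field A clamped [flim_field()].
#' @param ctx A [norm_ctx()].
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalise_intensity <- function(field, ctx = norm_ctx()) {
  stopifnot(inherits(field, "flim_field"), inherits(ctx, "norm_ctx"))
  clip01((field$intensity - ctx$intensity_min) /
           (ctx$intensity_max - ctx$intensity_min))
}

read_raster_page <- function(path, page = 1L) {
  if (!file.exists(path)) stop("cannot read raster: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (page > length(pages))
      stop("requested page ", page, " but ", path, " has ", length(pages))
    p <- pages[[page]]
    bps <- attr(p, "bits.per.sample") %||% 32
    # 8/16-bit pages hold integer counts (undo the [0,1] rescale);
    # 32-bit pages are float samples stored as is.
    if (bps %in% c(8, 16)) p <- p * (2^bps - 1)
    p
  } else if (ext == "png") {
    png::readPNG(path)
  } else stop("unsupported raster format: ", path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  attributes(img) <- list(dim = dim(img))
  img
}

read_sidecar <- function(path) {
  sc <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

#' Read a FLIM field from instrument-style raster exports
#'
#' Accepts either two single-channel TIFFs (one per channel) or a single
#' two-page TIFF (page 1 intensity, page 2 lifetime). A JSON sidecar
#' (written by [write_flim_field()]) holding scale factors and pixel size
#' is honoured when present; otherwise pixel values are taken at face
#' value (counts, ns). `NaN` lifetime pixels (exponential-fit failures)
#' are replaced by 0 ns and counted in the returned field's
#' `n_fit_failures` attribute.
#'
#' @param intensity_path Path to the intensity raster (or the two-page file).
#' @param lifetime_path Path to the lifetime raster, or `NULL` for the
#'   two-page dialect.
#' @param pixel_size Pixel edge in micrometres; overrides any sidecar value.
#' @param field_id Identifier; defaults to the file stem.
#' @return An unclamped [flim_field()].
#' @export
read_flim_field <- function(intensity_path, lifetime_path = NULL,
                            pixel_size = NULL, field_id = NULL) {
  two_page <- is.null(lifetime_path)
  intens <- read_raster_page(intensity_path, 1L)
  lt <- if (two_page) read_raster_page(intensity_path, 2L)
        else read_raster_page(lifetime_path, 1L)
  if (!all(dim(intens) == dim(lt)))
    stop("intensity (", paste(dim(intens), collapse = "x"),
         ") and lifetime (", paste(dim(lt), collapse = "x"),
         ") rasters differ in shape")
  sc <- read_sidecar(intensity_path)
  if (!is.null(sc)) {
    intens <- intens * (sc$intensity_scale %||% 1)
    lt <- lt * (sc$lifetime_scale %||% 1)
    pixel_size <- pixel_size %||% sc$pixel_size
  }
  pixel_size <- pixel_size %||% 1
  nan_px <- !is.finite(lt)
  n_bad <- sum(nan_px)
  if (n_bad > 0) lt[nan_px] <- 0
  fid <- field_id %||% tools::file_path_sans_ext(basename(intensity_path))
  f <- flim_field(intens, lt, pixel_size, fid)
  attr(f, "n_fit_failures") <- n_bad
  log_event("read_flim_field", field = fid, nan_lifetime = n_bad)
  f
}

#' Write single-channel rasters as a 32-bit float TIFF
#'
#' Minimal uncompressed little-endian baseline TIFF with IEEE float
#' samples (readable by libtiff and instrument software); one image
#' page per list element. Values are stored in their native units, so
#' a read/write/read cycle is bit-exact.
#'
#' @param pages A numeric matrix or list of matrices.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2,
                             endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  n <- length(pages)
  sizes <- vapply(pages, function(p) length(p) * 4L, integer(1))
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  data_off <- 8L + c(0L, cumsum(sizes))[seq_len(n)]
  ifd_off <- 8L + sum(sizes) + (seq_len(n) - 1L) * ifd_bytes
  w4(ifd_off[1])
  for (p in pages)
    writeBin(as.numeric(as.vector(t(p))), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (i in seq_len(n)) {
    H <- nrow(pages[[i]]); W <- ncol(pages[[i]])
    w2(n_entries)
    entry(256, 4, 1, W)            # ImageWidth
    entry(257, 4, 1, H)            # ImageLength
    entry(258, 3, 1, 32)           # BitsPerSample
    entry(259, 3, 1, 1)            # Compression: none
    entry(262, 3, 1, 1)            # Photometric: BlackIsZero
    entry(273, 4, 1, data_off[i])  # StripOffsets
    entry(277, 3, 1, 1)            # SamplesPerPixel
    entry(278, 4, 1, H)            # RowsPerStrip
    entry(279, 4, 1, sizes[i])     # StripByteCounts
    entry(339, 3, 1, 3)            # SampleFormat: IEEE float
    w4(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Write a FLIM field as 32-bit float TIFF plus JSON sidecar
#'
#' Channels are stored in native units (photon counts, ns) as IEEE
#' float samples via [write_float_tiff()]; a read/write/read cycle is
#' bit-exact. The JSON sidecar carries the field id, pixel size and
#' clamp bounds.
#'
#' @param field A [flim_field()].
#' @param intensity_path,lifetime_path Output TIFF paths.
#' @return Invisibly, the sidecar path.
#' @export
write_flim_field <- function(field, intensity_path, lifetime_path) {
  stopifnot(inherits(field, "flim_field"))
  write_float_tiff(field$intensity, intensity_path)
  write_float_tiff(field$lifetime, lifetime_path)
  meta <- list(field_id = field$field_id, pixel_size = field$pixel_size,
               clamp_intensity = c(0, 2000), clamp_lifetime = c(0, 5))
  for (p in c(intensity_path, lifetime_path))
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(p), ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(paste0(tools::file_path_sans_ext(intensity_path), ".json"))
}
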