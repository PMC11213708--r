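# Internal helpers shared across modules.

# Run `code` under a fixed, fully pinned RNG configuration, restoring the
# caller's RNG state afterwards. All stochastic package code funnels through
# this so a seed pins results bit-for-bit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Rec.601 luminance, the greyscale convention used throughout the package.
luminance <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  0.2989 * rgb[, , 1] + 0.5870 * rgb[, , 2] + 0.1140 * rgb[, , 3]
}

as_raster2d <- function(x, what = "raster") {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 3 && d[3] == 1) return(array(x, d[1:2]))
  stop(sprintf("%s must be a 2-D matrix", what), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-line-per-event structured log record (stage, id, counts).
log_event <- function(stage, ..., quiet = getOption("flimstain.quiet", TRUE)) {
  if (isTRUE(quiet)) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  message(msg)
  invisible(NULL)
}
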