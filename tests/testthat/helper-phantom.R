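# Shared fixtures, built in code. Phantoms are cached per (seed, size)
# within a test run since generation is deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture_phantom <- function(seed = 1, size = 128) {
  key <- paste0("ph_", seed, "_", size)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_phantom(
      phantom_spec(image_size = c(size, size), seed = seed))
  .fixtures[[key]]
}

fixture_field <- function(seed = 1, size = 128)
  clamp_flim(fixture_phantom(seed, size)$flim)

# Small deterministic RGB test image with structure (not constant).
fixture_rgb <- function(seed = 1, size = 32) {
  withr::with_seed(seed, array(runif(size * size * 3), c(size, size, 3)))
}
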