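# Shared fixtures, generated in code.

# Small, fast config: fewer pixels and bands than the full study geometry.
small_config <- function(n_classes = 3L, samples_per_class = 5L,
                         n_bands = 64L, image_shape = c(32L, 32L),
                         sample_radius_px = 6L, seed = 11L, ...) {
  synthetic_config(n_classes = n_classes,
                   samples_per_class = samples_per_class,
                   n_bands = n_bands, image_shape = image_shape,
                   sample_radius_px = sample_radius_px, seed = seed, ...)
}

edge_band_mask_for_test <- function(cfg) {
  cfg$wavelengths < cfg$clean_window[1] | cfg$wavelengths > cfg$clean_window[2]
}

# Full-scale well-separated preset: the study's 12 x 30 design with class
# differences large enough for near-perfect discrimination.
study_config <- function(seed = 1L, preset = "well_separated") {
  synthetic_config(preset = preset, seed = seed)
}

# A random cube with smooth values, for I/O round-trips.
random_cube <- function(rows = 4L, cols = 5L, bands = 8L, seed = 2L,
                        max_count = 1000) {
  v <- with_seed_test(seed, array(runif(rows * cols * bands, 0, max_count),
                                  c(rows, cols, bands)))
  spectral_cube(v, seq(900, by = 10, length.out = bands))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
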