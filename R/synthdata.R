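# Synthetic NIR hypercube and spectra generator.
#
# Emulates the qualitative structure of bulb-flake reflectance spectra on an
# 874-1734 nm axis: a gentle increasing-then-flat baseline, shared peaks
# near 1100 and 1300 nm, shared valleys near 1200 and 1460 nm (C-H second
# overtone and O-H first overtone regions), small class-specific
# perturbations with heavy overlap, i.i.d. pixel noise, and extra noise in
# the unstable leading/trailing bands that motivates wavelength cropping.

feature_matrix <- function(x, what) {
  if (is.null(x)) return(matrix(numeric(0), 0, 3))
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- matrix(as.numeric(x), ncol = 3,
              dimnames = list(NULL, c("center", "width", "amplitude")))
  if (any(!is.finite(x))) stopf("non-finite values in %s", what)
  if (any(x[, "width"] <= 0)) stopf("%s widths must be positive", what)
  x
}

default_shared_features <- function() {
  rbind(c(1100, 55,  0.10),   # C-H second overtone peak
        c(1300, 65,  0.08),   # C-H combination peak
        c(1200, 35, -0.07),   # C-H second overtone valley
        c(1460, 45, -0.10))   # O-H first overtone (water) valley
}

default_class_deltas <- function(n_classes, amplitude) {
  lapply(seq_len(n_classes) - 1L, function(k) {
    s1 <- if (k %% 2L == 0L) 1 else -1
    s2 <- if (k %% 3L == 0L) 1 else -1
    rbind(c(960 + 55 * k, 40, amplitude * s1),
          c(1580 - 45 * k, 60, -0.7 * amplitude * s2))
  })
}

#' Configuration for the synthetic hypercube generator
#'
#' Defines the full generative recipe: class endmember profiles (baseline +
#' shared Gaussian features + per-class perturbations), pixel noise, noisy
#' band edges, and imaging geometry. The defaults mirror the study design
#' the package targets: 12 varieties x 30 samples (360 spectra) on an
#' 874-1734 nm axis with 256 bands.
#'
#' @param n_classes number of varieties.
#' @param samples_per_class spectra per variety.
#' @param wavelength_start,wavelength_end axis limits in nm.
#' @param n_bands number of spectral channels.
#' @param shared_features matrix (or list of triples) of
#'   `(center nm, width nm, signed amplitude)` Gaussian features common to
#'   all classes. Defaults place peaks at 1100/1300 nm, valleys at
#'   1200/1460 nm.
#' @param class_deltas list of `n_classes` feature matrices (same triple
#'   format) perturbing each class; `NULL` builds a default ladder of small
#'   position-staggered bumps.
#' @param delta_amplitude amplitude of the default class perturbations, in
#'   reflectance units. The `"default"` preset (0.035) gives strongly
#'   overlapping classes; the `"well_separated"` preset (0.2) gives classes
#'   that a good classifier separates nearly perfectly.
#' @param pixel_noise_sd sd of i.i.d. Gaussian reflectance noise per band.
#' @param edge_noise_sd extra noise sd added outside `clean_window`
#'   (defaults to twice the pixel noise, i.e. tripled total sd at the axis
#'   edges).
#' @param clean_window 2-vector (nm): bands inside get only pixel noise.
#' @param sample_radius_px radius of the simulated sample disc, pixels.
#' @param image_shape `(rows, cols)` of simulated frames.
#' @param seed integer seed; all outputs are pure functions of the config.
#' @param preset `"default"` or `"well_separated"`; shorthand that sets
#'   `delta_amplitude`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 12L, samples_per_class = 30L,
                             wavelength_start = 874, wavelength_end = 1734,
                             n_bands = 256L,
                             shared_features = default_shared_features(),
                             class_deltas = NULL,
                             delta_amplitude = NULL,
                             pixel_noise_sd = 0.01,
                             edge_noise_sd = 0.02,
                             clean_window = c(875, 1546),
                             sample_radius_px = 10L,
                             image_shape = c(64L, 64L),
                             seed = 1L,
                             preset = c("default", "well_separated")) {
  preset <- match.arg(preset)
  n_classes <- check_count(n_classes, "n_classes")
  samples_per_class <- check_count(samples_per_class, "samples_per_class")
  n_bands <- check_count(n_bands, "n_bands", min = 2L)
  if (!is.finite(wavelength_start) || !is.finite(wavelength_end) ||
      wavelength_end <= wavelength_start)
    stopf("wavelength_end must exceed wavelength_start")
  if (is.null(delta_amplitude))
    delta_amplitude <- if (preset == "well_separated") 0.2 else 0.035
  if (!is.finite(delta_amplitude)) stopf("delta_amplitude must be finite")
  shared_features <- feature_matrix(shared_features, "shared_features")
  if (is.null(class_deltas))
    class_deltas <- default_class_deltas(n_classes, delta_amplitude)
  if (length(class_deltas) != n_classes)
    stopf("class_deltas must have exactly %d entries", n_classes)
  class_deltas <- lapply(class_deltas, feature_matrix, what = "class_deltas")
  if (pixel_noise_sd < 0 || edge_noise_sd < 0)
    stopf("noise sds must be non-negative")
  structure(list(
    n_classes = n_classes, samples_per_class = samples_per_class,
    wavelengths = seq(wavelength_start, wavelength_end,
                      length.out = n_bands),
    shared_features = shared_features, class_deltas = class_deltas,
    pixel_noise_sd = pixel_noise_sd, edge_noise_sd = edge_noise_sd,
    clean_window = as.numeric(clean_window),
    sample_radius_px = check_count(sample_radius_px, "sample_radius_px"),
    image_shape = as.integer(image_shape), seed = as.integer(seed),
    preset = preset), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d classes x %d samples, %d bands ",
                     "(%.0f-%.0f nm), preset '%s', seed %d\n"),
              x$n_classes, x$samples_per_class, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$preset, x$seed))
  invisible(x)
}

gaussian_features <- function(wavelengths, features) {
  out <- numeric(length(wavelengths))
  for (i in seq_len(nrow(features)))
    out <- out + features[i, 3] *
      exp(-0.5 * ((wavelengths - features[i, 1]) / features[i, 2])^2)
  out
}

# Smooth baseline: rises through the lower NIR then flattens, staying in a
# plausible [0.2, 0.7] reflectance range.
baseline_curve <- function(wavelengths) {
  0.25 + 0.30 * stats::plogis((wavelengths - 1050) / 180)
}

#' Noiseless class endmember profiles
#'
#' Each profile is `baseline + shared features + class deltas`, clipped to
#' `[0, 1]`; all classes share the peak/valley positions of the shared
#' features.
#'
#' @param config a [synthetic_config()].
#' @return numeric matrix `n_classes x n_bands`; attribute `"wavelengths"`
#'   carries the axis.
#' @export
make_class_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wl <- config$wavelengths
  base <- baseline_curve(wl) + gaussian_features(wl, config$shared_features)
  P <- t(vapply(config$class_deltas,
                function(d) base + gaussian_features(wl, d),
                numeric(length(wl))))
  P[P < 0] <- 0
  P[P > 1] <- 1
  rownames(P) <- paste0("class", seq_len(config$n_classes) - 1L)
  attr(P, "wavelengths") <- wl
  P
}

edge_band_mask <- function(config) {
  wl <- config$wavelengths
  wl < config$clean_window[1] | wl > config$clean_window[2]
}

#' Simulate a labelled spectra table
#'
#' Draws `samples_per_class` spectra per class: the class profile plus
#' i.i.d. Gaussian pixel noise, with extra edge noise outside the clean
#' wavelength window. Deterministic given the config's seed.
#'
#' @param config a [synthetic_config()].
#' @return a [spectra_table()] with `n_classes * samples_per_class` rows and
#'   0-based integer labels.
#' @export
simulate_spectra_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  P <- make_class_profiles(config)
  nb <- length(config$wavelengths)
  n <- config$n_classes * config$samples_per_class
  edge <- edge_band_mask(config)
  with_seed(config$seed, {
    X <- P[rep(seq_len(config$n_classes), each = config$samples_per_class), ,
           drop = FALSE]
    X <- X + matrix(stats::rnorm(n * nb, sd = config$pixel_noise_sd), n, nb)
    if (any(edge) && config$edge_noise_sd > 0)
      X[, edge] <- X[, edge] +
        matrix(stats::rnorm(n * sum(edge), sd = config$edge_noise_sd),
               n, sum(edge))
    labels <- rep(seq_len(config$n_classes) - 1L,
                  each = config$samples_per_class)
    spectra_table(X, config$wavelengths, labels = labels,
                  provenance = data.frame(
                    class = labels,
                    replicate = rep(seq_len(config$samples_per_class),
                                    times = config$n_classes)))
  })
}

#' Simulate a raw-count hypercube of one sample
#'
#' Places a disc of `sample_radius_px` pixels at the frame centre carrying
#' the class spectrum (plus pixel noise), encodes reflectance to counts by
#' inverting the white/dark calibration
#' (`raw = reflectance * (white - dark) + dark`), and surrounds it with
#' near-dark background. The white/dark frames used for the encoding and
#' the ground-truth disc mask are returned with the cube, so
#' `calibrate()`-ing the cube with its own references recovers the
#' reflectance exactly.
#'
#' @param config a [synthetic_config()].
#' @param class_id 0-based class id in `[0, n_classes)`.
#' @return list with elements `raw` (a raw-counts [spectral_cube()]),
#'   `white`, `dark` (3-D reference frames), `mask` (logical rows x cols
#'   ground-truth disc) and `reflectance` (the encoded reflectance cube).
#' @export
simulate_cube <- function(config, class_id) {
  stopifnot(inherits(config, "synthetic_config"))
  if (class_id < 0 || class_id >= config$n_classes || class_id != round(class_id))
    stopf("class_id must be an integer in [0, %d)", config$n_classes)
  sh <- config$image_shape
  r <- config$sample_radius_px
  if (2 * r + 2 >= min(sh))
    stopf("sample disc (radius %d px) does not fit in a %d x %d frame",
          r, sh[1], sh[2])
  wl <- config$wavelengths
  nb <- length(wl)
  P <- make_class_profiles(config)
  profile <- P[class_id + 1L, ]
  ci <- (sh[1] + 1) / 2
  cj <- (sh[2] + 1) / 2
  mask <- outer(seq_len(sh[1]), seq_len(sh[2]),
                function(i, j) (i - ci)^2 + (j - cj)^2 <= r^2)
  edge <- edge_band_mask(config)
  npx <- prod(sh)
  with_seed(config$seed + 7919L * (class_id + 1L), {
    # references: smooth band-dependent white level, low dark level,
    # with mild per-pixel structure
    white_level <- 3000 + 800 * exp(-((wl - 1300) / 400)^2)
    dark_level <- 120
    white <- aperm(array(white_level, c(nb, sh[1], sh[2])), c(2, 3, 1)) *
      (1 + array(stats::rnorm(npx * nb, sd = 0.002), c(sh, nb)))
    dark <- dark_level *
      (1 + array(stats::rnorm(npx * nb, sd = 0.01), c(sh, nb)))
    refl <- array(0.02, c(sh, nb))  # faint background reflectance
    noise <- array(stats::rnorm(npx * nb, sd = config$pixel_noise_sd),
                   c(sh, nb))
    if (any(edge) && config$edge_noise_sd > 0)
      noise[, , edge] <- noise[, , edge] +
        array(stats::rnorm(npx * sum(edge), sd = config$edge_noise_sd),
              c(sh, sum(edge)))
    disc <- array(rep(mask, nb), c(sh, nb))
    prof_cube <- aperm(array(profile, c(nb, sh[1], sh[2])), c(2, 3, 1))
    refl[disc] <- prof_cube[disc]
    refl <- refl + noise
    refl[refl < 0] <- 0
    raw <- refl * (white - dark) + dark
    list(raw = spectral_cube(raw, wl, kind = "raw_counts"),
         white = white, dark = dark, mask = mask,
         reflectance = spectral_cube(refl, wl, kind = "reflectance"))
  })
}
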