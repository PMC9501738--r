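test_that("select_band picks the nearest band, ties toward lower wavelength", {
  mk <- function(wl) spectral_cube(array(seq_along(wl),
                                         c(1, 1, length(wl))), wl)
  b <- select_band(mk(c(1000, 1019, 1040)), 1019)
  expect_equal(attr(b, "band"), 1L)          # exact hit (0-based)
  b <- select_band(mk(c(1000, 1020)), 1009)  # 9 vs 11 away
  expect_equal(attr(b, "band"), 0L)
  b <- select_band(mk(c(1000, 1020)), 1010)  # exact tie
  expect_equal(attr(b, "band"), 0L)
  expect_error(select_band(mk(c(1000, 1020)), 900), "outside")
})

test_that("threshold_mask segments a bimodal image and rejects degenerate input", {
  img <- with_seed_test(7L, {
    m <- matrix(rnorm(64 * 64, 0.05, 0.01), 64, 64)
    truth <- outer(1:64, 1:64, function(i, j) (i - 32)^2 + (j - 32)^2 <= 100)
    m[truth] <- rnorm(sum(truth), 0.6, 0.01)
    attr(m, "truth") <- truth
    m
  })
  truth <- attr(img, "truth")
  mask <- threshold_mask(img)
  expect_gte(mean(mask == truth), 0.99)
  expect_error(threshold_mask(matrix(1, 8, 8)), "constant")
})

test_that("two-level images threshold exactly", {
  img <- matrix(0, 10, 10)
  img[3:8, 4:9] <- 1
  mask <- threshold_mask(img, min_region_px = 0L)
  expect_identical(matrix(mask, 10, 10), img == 1)
  thr <- attr(mask, "threshold")
  expect_true(thr > 0 && thr < 1)
})

test_that("small connected components are removed", {
  img <- matrix(0, 32, 32)
  img[5:20, 5:20] <- 1       # 256-px region
  img[28:29, 28:29] <- 1     # 4-px speckle
  mask <- threshold_mask(img, min_region_px = 20L)
  expect_true(all(mask[5:20, 5:20]))
  expect_false(any(mask[28:29, 28:29]))
})

test_that("extract_pixel_spectra returns raster-ordered rows with provenance", {
  cfg <- small_config(pixel_noise_sd = 0, edge_noise_sd = 0)
  sim <- simulate_cube(cfg, 0L)
  refl <- calibrate(sim$raw, sim$white, sim$dark)
  tab <- extract_pixel_spectra(refl, sim$mask, label = 0L)
  # row count = brute-force count of true pixels
  expect_equal(nrow(tab$X), sum(sim$mask))
  # zero-noise cube: every ROI row equals the class profile
  P <- make_class_profiles(cfg)
  expect_equal(max(abs(sweep(tab$X, 2, P[1, ]))), 0, tolerance = 1e-12)
  # provenance is raster (row-major) ordered, 0-based
  expect_true(all(diff(tab$provenance$row) >= 0))
  expect_identical(tab$provenance$row[1] >= 0, TRUE)
  one <- which(sim$mask, arr.ind = TRUE)[1, ]
  expect_true(any(tab$provenance$row == one[1] - 1 &
                  tab$provenance$col == one[2] - 1))

  # single-pixel mask -> that pixel's spectrum
  m1 <- matrix(FALSE, cfg$image_shape[1], cfg$image_shape[2])
  m1[3, 4] <- TRUE
  t1 <- extract_pixel_spectra(refl, m1)
  expect_equal(drop(t1$X), refl$values[3, 4, ])
  expect_error(extract_pixel_spectra(refl, matrix(TRUE, 2, 2)), "mask shape")
})

test_that("mean_spectrum matches a brute-force loop", {
  X <- with_seed_test(9L, matrix(rnorm(35), 5, 7))
  tab <- spectra_table(X, seq(1000, 1600, length.out = 7))
  m <- mean_spectrum(tab)
  oracle <- numeric(7)
  for (j in 1:7) {
    s <- 0
    for (i in 1:5) s <- s + X[i, j]
    oracle[j] <- s / 5
  }
  expect_equal(m, oracle)
  one <- spectra_table(X[2, , drop = FALSE], tab$wavelengths)
  expect_equal(mean_spectrum(one), X[2, ])
})

test_that("crop_wavelengths keeps the closed interval and is idempotent", {
  wl <- c(900, 1000, 1100)
  tab <- spectra_table(matrix(1:6, 2, 3), wl)
  full <- crop_wavelengths(tab, 900, 1100)
  expect_identical(full$X, tab$X)
  mid <- crop_wavelengths(tab, 950, 1050)
  expect_equal(mid$wavelengths, 1000)
  expect_error(crop_wavelengths(tab, 1200, 1300), "no bands")
  expect_error(crop_wavelengths(tab, 1100, 1000), "lo_nm")

  # retained count equals brute force on a random axis; idempotence
  axis <- sort(with_seed_test(10L, runif(40, 800, 1800)))
  rt <- spectra_table(matrix(0, 3, 40), axis)
  cr <- crop_wavelengths(rt, 1000, 1500)
  expect_equal(ncol(cr$X), sum(axis >= 1000 & axis <= 1500))
  expect_identical(crop_wavelengths(cr, 1000, 1500)$X, cr$X)
})

test_that("full chain recovers the class profile from a simulated cube", {
  cfg <- study_config(seed = 13L)
  sim <- simulate_cube(cfg, 4L)
  refl <- calibrate(sim$raw, sim$white, sim$dark)
  mask <- threshold_mask(select_band(refl, 1019))
  tab <- extract_pixel_spectra(refl, mask)
  avg <- mean_spectrum(tab)
  tab_m <- spectra_table(matrix(avg, 1), refl$wavelengths)
  cropped <- crop_wavelengths(tab_m, 875, 1546)
  den <- drop(denoise_spectra(cropped)$X)
  P <- make_class_profiles(cfg)
  truth <- crop_wavelengths(spectra_table(P[5, , drop = FALSE],
                                          cfg$wavelengths), 875, 1546)
  expect_gt(stats::cor(den, drop(truth$X)), 0.99)
})
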