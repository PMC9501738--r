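# ROI extraction: band selection, threshold segmentation, pixel spectra,
# wavelength cropping.

#' Select the band nearest a target wavelength
#'
#' @param cube a [spectral_cube()].
#' @param target_nm wavelength in nm; must lie within the axis range.
#' @return the rows x cols image of the nearest band; ties between two
#'   equally distant bands are broken toward the lower wavelength.
#'   Attribute `"band"` gives the 0-based band index, `"wavelength"` the
#'   band centre.
#' @export
select_band <- function(cube, target_nm) {
  stopifnot(inherits(cube, "spectral_cube"))
  wl <- cube$wavelengths
  if (target_nm < min(wl) || target_nm > max(wl))
    stopf("target %g nm is outside the axis range [%g, %g]",
          target_nm, min(wl), max(wl))
  d <- abs(wl - target_nm)
  idx <- which(d == min(d))[1L]   # which() scans ascending: tie -> lower wl
  img <- cube$values[, , idx]
  attr(img, "band") <- idx - 1L
  attr(img, "wavelength") <- wl[idx]
  img
}

#' Threshold segmentation of a sample image
#'
#' Computes an Otsu threshold (maximising between-class variance, i.e. the
#' "maximum contrast" criterion), keeps pixels above it, and removes
#' connected components smaller than `min_region_px`.
#'
#' @param image numeric matrix (e.g. from [select_band()]).
#' @param min_region_px connected components with fewer pixels are dropped.
#' @return logical matrix of the same shape (the foreground mask), with the
#'   threshold stored in attribute `"threshold"`.
#' @export
threshold_mask <- function(image, min_region_px = 20L) {
  image <- unclass(image)
  attributes(image) <- list(dim = dim(image))
  if (any(!is.finite(image))) stopf("image must be finite")
  rng <- range(image)
  if (rng[1] == rng[2])
    stopf("degenerate input: image is constant, no threshold exists")
  scaled <- (image - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr01
  if (min_region_px > 0L) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[sizes >= min_region_px])
    mask <- matrix(as.integer(lab) %in% keep, nrow(image), ncol(image))
  }
  if (!any(mask))
    stopf("segmentation produced an empty mask (min_region_px = %d)",
          min_region_px)
  attr(mask, "threshold") <- rng[1] + thr01 * (rng[2] - rng[1])
  mask
}

#' Extract per-pixel ROI spectra
#'
#' One row per `TRUE` mask pixel in raster (row-major) order; provenance
#' records each pixel's 0-based `(row, col)`.
#'
#' @param cube a reflectance [spectral_cube()].
#' @param mask logical matrix matching the cube's spatial shape.
#' @param label optional class id attached to every row.
#' @return a [spectra_table()].
#' @export
extract_pixel_spectra <- function(cube, mask, label = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  if (!all(dim(mask) == d[1:2]))
    stopf("mask shape (%d x %d) does not match cube (%d x %d)",
          nrow(mask), ncol(mask), d[1], d[2])
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("mask has no TRUE pixels")
  ord <- order(idx[, 1L], idx[, 2L])   # raster order: row by row
  idx <- idx[ord, , drop = FALSE]
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  X <- flat[idx[, 1L] + (idx[, 2L] - 1L) * d[1], , drop = FALSE]
  spectra_table(X, cube$wavelengths,
                labels = if (is.null(label)) NULL else
                  rep(as.integer(label), nrow(idx)),
                provenance = data.frame(row = idx[, 1L] - 1L,
                                        col = idx[, 2L] - 1L))
}

#' Column-wise mean spectrum of a table
#'
#' @param table a [spectra_table()] with at least one row.
#' @return numeric vector, one value per band.
#' @export
mean_spectrum <- function(table) {
  stopifnot(inherits(table, "spectra_table"))
  if (nrow(table$X) == 0L) stopf("cannot average an empty table")
  colMeans(table$X)
}

#' Crop a spectra table to a wavelength window
#'
#' Keeps exactly the bands with `lo_nm <= wavelength <= hi_nm` (closed
#' interval). The default window trims the noisy leading/trailing bands of
#' the instrument range.
#'
#' @param table a [spectra_table()].
#' @param lo_nm,hi_nm window limits in nm, `lo_nm < hi_nm`.
#' @return the cropped [spectra_table()].
#' @export
crop_wavelengths <- function(table, lo_nm = 875, hi_nm = 1546) {
  stopifnot(inherits(table, "spectra_table"))
  if (lo_nm >= hi_nm) stopf("lo_nm must be below hi_nm")
  keep <- table$wavelengths >= lo_nm & table$wavelengths <= hi_nm
  if (!any(keep))
    stopf("window [%g, %g] nm contains no bands", lo_nm, hi_nm)
  spectra_table(table$X[, keep, drop = FALSE], table$wavelengths[keep],
                labels = table$labels, provenance = table$provenance)
}
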