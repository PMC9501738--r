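#' Construct a spectra table
#'
#' The package's tabular container: a samples x bands reflectance matrix
#' with a shared wavelength axis, optional integer class labels in
#' `[0, n_classes)`, and optional per-row provenance (e.g. pixel
#' coordinates or sample ids).
#'
#' @param X numeric matrix, samples x bands.
#' @param wavelengths numeric vector (nm), length `ncol(X)`, strictly
#'   increasing.
#' @param labels optional integer class ids, `0 ..  K-1`, length `nrow(X)`.
#' @param provenance optional data.frame with `nrow(X)` rows.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(X, wavelengths, labels = NULL, provenance = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(X) != length(wavelengths))
    stopf("X has %d columns but %d wavelengths given", ncol(X),
          length(wavelengths))
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stopf("wavelengths must be finite and strictly increasing")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(X))
      stopf("labels length %d does not match %d rows", length(labels), nrow(X))
    if (any(is.na(labels)) || any(labels < 0L))
      stopf("labels must be non-negative integers (0-based class ids)")
  }
  if (!is.null(provenance) && nrow(provenance) != nrow(X))
    stopf("provenance must have one row per sample")
  structure(list(X = X, wavelengths = wavelengths, labels = labels,
                 provenance = provenance),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d spectra x %d bands (%.1f-%.1f nm)\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("  labels: %d classes, %s samples per class\n", length(tab),
                paste(unique(range(tab)), collapse = "-")))
  }
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$X)

#' Read/write a spectra table as delimited text
#'
#' Format: one header row (`label`, then the wavelengths in nm), one row
#' per sample. A label of `NA` is written for unlabelled tables.
#'
#' @param table a [spectra_table()].
#' @param path file path.
#' @param sep field separator.
#' @return `write_spectra`: `path`, invisibly. `read_spectra`: a
#'   [spectra_table()].
#' @export
write_spectra <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "spectra_table"))
  lab <- if (is.null(table$labels)) rep(NA_integer_, nrow(table$X)) else
    table$labels
  df <- data.frame(label = lab, table$X, check.names = FALSE)
  colnames(df) <- c("label", format(table$wavelengths, trim = TRUE))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE)
  if (colnames(df)[1] != "label")
    stopf("'%s' does not look like a spectra table (no label column)", path)
  wl <- as.numeric(colnames(df)[-1])
  lab <- df[[1]]
  if (all(is.na(lab))) lab <- NULL
  spectra_table(as.matrix(df[, -1, drop = FALSE]), wl, labels = lab)
}
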