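#' Principal component analysis of a spectra table
#'
#' Centred (not scaled) PCA via singular value decomposition, the standard
#' exploratory step for reflectance spectra. Explained percentages are
#' eigenvalue shares of the total variance; loading signs follow a fixed
#' convention (the largest-magnitude element of each loading is positive)
#' so results are deterministic.
#'
#' @param table a [spectra_table()] (or plain matrix) with at least 2 rows.
#' @param k number of components to retain,
#'   `k <= min(samples - 1, bands)`.
#' @return object of class `spectra_pca` with elements `scores`
#'   (samples x k), `loadings` (bands x k, orthonormal columns),
#'   `explained_pct` (length k, non-increasing), `mean` (band-wise centring
#'   vector), `labels` (copied from the table, if any).
#' @export
spectra_pca <- function(table, k = 2L) {
  X <- if (inherits(table, "spectra_table")) table$X else as.matrix(table)
  n <- nrow(X)
  if (n < 2L) stopf("PCA needs at least 2 samples")
  kmax <- min(n - 1L, ncol(X))
  k <- check_count(k, "k")
  if (k > kmax) stopf("k = %d exceeds min(samples - 1, bands) = %d", k, kmax)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0, nv = kmax)
  eig <- sv$d[seq_len(kmax)]^2 / (n - 1L)
  total_var <- sum(apply(Xc, 2L, stats::var))
  explained <- 100 * eig / total_var
  V <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(V, 2L, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  V <- sweep(V, 2L, flip, `*`)
  structure(list(scores = Xc %*% V, loadings = V,
                 explained_pct = explained[seq_len(k)],
                 explained_pct_all = explained, mean = ctr,
                 labels = if (inherits(table, "spectra_table"))
                   table$labels else NULL,
                 k = k),
            class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf("<spectra_pca> %d components of %d-band spectra\n",
              x$k, length(x$mean)))
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explained_pct), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.spectra_pca <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_table")) newdata$X else
    as.matrix(newdata)
  sweep(X, 2L, object$mean) %*% object$loadings
}

#' @export
plot.spectra_pca <- function(x, comps = c(1L, 2L), ...) {
  s <- x$scores[, comps, drop = FALSE]
  col <- if (is.null(x$labels)) 1L else x$labels + 1L
  graphics::plot(s[, 1L], s[, 2L], col = col, pch = 19,
                 xlab = sprintf("PC%d (%.2f%%)", comps[1L],
                                x$explained_pct[comps[1L]]),
                 ylab = sprintf("PC%d (%.2f%%)", comps[2L],
                                x$explained_pct[comps[2L]]), ...)
  invisible(x)
}

#' Cumulative explained variance
#'
#' Sum of the first `m` per-component explained percentages.
#'
#' @param result a [spectra_pca()] fit, or a plain numeric vector of
#'   per-component percentages.
#' @param m number of leading components, `1 <= m <= k`.
#' @return a single percentage.
#' @export
cumulative_variance <- function(result, m) {
  pct <- if (inherits(result, "spectra_pca")) result$explained_pct else
    as.numeric(result)
  m <- check_count(m, "m")
  if (m > length(pct)) stopf("m = %d exceeds the %d available components",
                             m, length(pct))
  sum(pct[seq_len(m)])
}
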