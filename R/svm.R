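#' Fit an RBF-kernel SVM with grid search
#'
#' Exhaustive grid search over the penalty parameter `c` and kernel width
#' `g`, scored by stratified inner cross-validation on the training rows;
#' the best pair is refit on all training rows. Ties are broken toward the
#' smallest `c`, then the smallest `g`, so the choice is deterministic.
#' The underlying machine is \code{\link[e1071]{svm}}.
#'
#' @param x a [spectra_table()] or samples x bands matrix.
#' @param labels 0-based integer class ids (taken from the table if
#'   omitted).
#' @param c_grid,g_grid positive hyperparameter grids.
#' @param inner_cv_folds folds of the inner stratified CV.
#' @param standardize learn `(x - mean)/sd` scaling from training rows.
#' @param seed seed for the inner CV fold assignment.
#' @return object of classes `svm_classifier`, `herb_classifier`; element
#'   `grid` records every `(c, g)` pair with its CV accuracy (the
#'   grid-search surface).
#' @export
fit_svm_rbf <- function(x, labels = NULL,
                        c_grid = 2^seq(-1, 9, by = 2),
                        g_grid = 2^seq(-11, -1, by = 2),
                        inner_cv_folds = 5L, standardize = TRUE,
                        seed = 1L) {
  d <- resolve_xy(x, labels)
  if (any(c_grid <= 0) || any(g_grid <= 0))
    stopf("c_grid and g_grid must be positive")
  if (!length(c_grid) || !length(g_grid)) stopf("empty hyperparameter grid")
  folds <- check_count(inner_cv_folds, "inner_cv_folds", min = 2L)
  if (min(table(d$y)) < folds)
    stopf("smallest class (%d rows) has fewer rows than %d folds",
          min(table(d$y)), folds)
  std <- if (standardize) standardize_fit(d$X) else NULL
  X <- if (is.null(std)) d$X else standardize_apply(std, d$X)
  yf <- factor(d$y, levels = 0:(d$K - 1L))
  fold_id <- with_seed(seed, {
    id <- integer(length(d$y))
    for (cl in levels(yf)) {
      rows <- which(yf == cl)
      id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    id
  })
  c_grid <- sort(c_grid)
  g_grid <- sort(g_grid)
  grid <- expand.grid(g = g_grid, c = c_grid)[, c("c", "g")]
  grid$accuracy <- NA_real_
  best <- list(acc = -1, c = NA, g = NA)
  for (r in seq_len(nrow(grid))) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      cost = grid$c[r], gamma = grid$g[r], scale = FALSE)
      pred <- predict(m, X[!tr, , drop = FALSE])
      hits <- hits + sum(pred == yf[!tr])
    }
    acc <- hits / length(d$y)
    grid$accuracy[r] <- acc
    # grid is ordered by (c, g); strict ">" keeps the first (smallest) tie
    if (acc > best$acc) best <- list(acc = acc, c = grid$c[r], g = grid$g[r])
  }
  model <- e1071::svm(X, yf, kernel = "radial", cost = best$c,
                      gamma = best$g, scale = FALSE)
  structure(list(kind = "svm_rbf", model = model, c = best$c, g = best$g,
                 cv_accuracy = best$acc, grid = grid, K = d$K,
                 standardizer = std),
            class = c("svm_classifier", "herb_classifier"))
}

#' @export
predict.svm_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_table")) newdata$X else
    as.matrix(newdata)
  if (!is.null(object$standardizer))
    X <- standardize_apply(object$standardizer, X)
  as.integer(as.character(predict(object$model, X)))
}

#' @export
print.herb_classifier <- function(x, ...) {
  extra <- switch(x$kind,
                  plsda = sprintf("%d latent variables", x$ncomp),
                  svm_rbf = sprintf("c = %g, g = %g", x$c, x$g),
                  cnn = sprintf("%d epochs trained", length(x$history$loss)),
                  "")
  cat(sprintf("<herb_classifier> %s, %d classes%s\n", x$kind, x$K,
              if (nzchar(extra)) paste0(" (", extra, ")") else ""))
  invisible(x)
}
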