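#' Stratified train/test split
#'
#' Randomly partitions row indices class by class at the given ratio
#' (default 4:1, i.e. 80:20). When a class size is divisible by the ratio
#' total the split is exact; otherwise the test share is rounded, keeping
#' at least one test row per class.
#'
#' @param labels integer class ids (0-based) or factor.
#' @param ratio length-2 `c(train, test)` ratio.
#' @param seed integer seed; identical seeds give identical splits.
#' @return object of class `split_indices` with integer vectors
#'   `train_rows` and `test_rows` (1-based row indices) and the seed.
#' @export
stratified_split <- function(labels, ratio = c(4, 1), seed = 1L) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  total <- sum(ratio)
  counts <- table(labels)
  small <- names(counts)[counts < total]
  if (length(small))
    stopf("class(es) %s have fewer than %d members; cannot split %s",
          paste(small, collapse = ", "), total,
          paste(ratio, collapse = ":"))
  with_seed(seed, {
    test <- integer(0)
    for (cl in sort(unique(labels))) {
      rows <- which(labels == cl)
      n_test <- max(1L, round(length(rows) * ratio[2L] / total))
      test <- c(test, sort(sample(rows, n_test)))
    }
    train <- setdiff(seq_along(labels), test)
    structure(list(train_rows = train, test_rows = sort(test),
                   seed = as.integer(seed)),
              class = "split_indices")
  })
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> %d train / %d test (seed %d)\n",
              length(x$train_rows), length(x$test_rows), x$seed))
  invisible(x)
}

#' Per-band standardization learned from training rows
#'
#' `standardize_fit` learns band-wise means and standard deviations
#' (denominator n-1) from the training matrix; `standardize_apply`
#' transforms any matrix as `(x - mean) / sd` with those statistics, so
#' test data never leaks into the scaling. Constant bands (sd = 0) are
#' flagged and their sd replaced by 1.
#'
#' @param X_train numeric matrix, at least 2 rows.
#' @return `standardize_fit`: object of class `standardizer` with `mean`,
#'   `sd` and `constant` (logical flags). `standardize_apply`: the
#'   transformed matrix.
#' @export
standardize_fit <- function(X_train) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2L) stopf("need at least 2 training rows")
  m <- colMeans(X_train)
  s <- apply(X_train, 2L, stats::sd)
  constant <- s == 0
  s[constant] <- 1
  structure(list(mean = m, sd = s, constant = constant),
            class = "standardizer")
}

#' @rdname standardize_fit
#' @param std a `standardizer`.
#' @param X matrix to transform with the training statistics.
#' @export
standardize_apply <- function(std, X) {
  stopifnot(inherits(std, "standardizer"))
  X <- as.matrix(X)
  if (ncol(X) != length(std$mean))
    stopf("X has %d columns, standardizer expects %d", ncol(X),
          length(std$mean))
  sweep(sweep(X, 2L, std$mean), 2L, std$sd, `/`)
}
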