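test_that("PLS-DA separates two well-separated Gaussian classes with 1 LV", {
  X <- with_seed_test(1L, rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
                                matrix(rnorm(40, 3, 0.2), 20, 2)))
  y <- rep(0:1, each = 20L)
  fit <- fit_plsda(X, y, ncomp = 1L)
  expect_identical(predict(fit, X), y)
})

test_that("auto component selection finds the needed dimensionality", {
  # three clusters spanning exactly two informative directions
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  X2 <- with_seed_test(2L, centers[rep(1:3, each = 12L), ] +
                         matrix(rnorm(72, sd = 0.15), 36, 2))
  X <- cbind(X2, with_seed_test(3L, matrix(rnorm(36 * 4, sd = 0.15), 36, 4)))
  y <- rep(0:2, each = 12L)
  fit <- fit_plsda(X, y, ncomp = "auto", max_ncomp = 5L,
                   standardize = FALSE)
  expect_identical(fit$ncomp, 2L)
  expect_equal(max(fit$loo_accuracy), fit$loo_accuracy[2])
  expect_identical(predict(fit, X), y)
})

test_that("PLS-DA memorizes a one-row-per-class dataset", {
  X <- with_seed_test(4L, matrix(rnorm(40), 4, 10))
  y <- 0:3
  fit <- fit_plsda(X, y, ncomp = 3L, standardize = FALSE)
  expect_identical(predict(fit, X), y)
})

test_that("PLS-DA rejects degenerate labellings", {
  X <- matrix(rnorm(40), 8, 5)
  expect_error(fit_plsda(X, rep(0L, 8)), "at least 2 classes")
})

test_that("PLS-DA predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  tab <- simulate_spectra_table(small_config(seed = 31L,
                                             preset = "well_separated"))
  fit <- fit_plsda(tab$X, tab$labels, ncomp = 3L, standardize = FALSE)
  Xr <- tab$X
  rownames(Xr) <- paste0("s", seq_len(nrow(Xr)))
  colnames(Xr) <- paste0("b", seq_len(ncol(Xr)))
  mo <- mixOmics::plsda(Xr, factor(tab$labels), ncomp = 3L, scale = FALSE)
  mo_pred <- predict(mo, Xr)$class$max.dist[, 3]
  expect_identical(predict(fit, tab$X), as.integer(as.character(mo_pred)))
})

test_that("leave-one-out accuracy matches a brute-force loop", {
  X <- with_seed_test(5L, matrix(rnorm(100), 10, 10))
  y <- rep(0:1, 5L)
  train_fn <- function(X, y) fit_plsda(X, y, ncomp = 1L, standardize = FALSE)
  acc <- loo_cv(train_fn, X, y)
  correct <- 0L
  for (i in 1:10) {
    m <- train_fn(X[-i, , drop = FALSE], y[-i])
    correct <- correct + (predict(m, X[i, , drop = FALSE]) == y[i])
  }
  expect_equal(acc, correct / 10)
})

test_that("leave-one-out bounds: constant and perfect learners", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(0:1, each = 10L)
  constant_model <- structure(list(), class = "herbtest_constant")
  registerS3method("predict", "herbtest_constant",
                   function(object, newdata, ...) rep(0L, nrow(newdata)))
  expect_equal(loo_cv(function(X, y) constant_model, X, y), 0.5)

  Xsep <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
                matrix(rnorm(20, 5, 0.1), 10, 2))
  expect_equal(loo_cv(function(X, y) fit_plsda(X, y, ncomp = 1L), Xsep, y), 1)
})

test_that("the RBF-SVM solves the XOR pattern that defeats linear models", {
  centers <- rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0))
  lab <- c(0L, 0L, 1L, 1L)
  X <- with_seed_test(6L, centers[rep(1:4, each = 10L), ] +
                        matrix(rnorm(80, sd = 0.15), 40, 2))
  y <- lab[rep(1:4, each = 10L)]
  fit <- fit_svm_rbf(X, y, c_grid = c(1, 10), g_grid = c(0.1, 1),
                     inner_cv_folds = 5L, standardize = FALSE, seed = 7L)
  expect_identical(predict(fit, X), y)
})

test_that("grid search is exhaustive, bounded and deterministic on ties", {
  X <- with_seed_test(8L, rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
                                matrix(rnorm(40, 4, 0.2), 20, 2)))
  y <- rep(0:1, each = 20L)
  single <- fit_svm_rbf(X, y, c_grid = 2, g_grid = 0.5,
                        inner_cv_folds = 4L, seed = 1L)
  expect_equal(single$c, 2)
  expect_equal(single$g, 0.5)
  # trivially separable: every grid point scores 1.0 -> smallest c then g
  tied <- fit_svm_rbf(X, y, c_grid = c(8, 1), g_grid = c(2, 0.25),
                      inner_cv_folds = 4L, seed = 1L)
  expect_true(all(tied$grid$accuracy == 1))
  expect_equal(tied$c, 1)
  expect_equal(tied$g, 0.25)
  # chosen pair always comes from the supplied grid
  expect_true(tied$c %in% c(8, 1) && tied$g %in% c(2, 0.25))
  expect_identical(nrow(tied$grid), 4L)
})

test_that("SVM input validation", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(0:1, 5L)
  expect_error(fit_svm_rbf(X, y, c_grid = numeric(0)), "empty|positive")
  expect_error(fit_svm_rbf(X, y, c_grid = -1), "positive")
  expect_error(fit_svm_rbf(X, y, inner_cv_folds = 8L), "folds")
})
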