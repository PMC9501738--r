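test_that("confusion counts match a brute-force double loop", {
  y_true <- with_seed_test(18L, sample(0:4, 50, replace = TRUE))
  y_pred <- with_seed_test(19L, sample(0:4, 50, replace = TRUE))
  cm <- confusion(y_true, y_pred, 5L)
  oracle <- matrix(0L, 5, 5)
  for (i in seq_along(y_true))
    for (t in 0:4) for (p in 0:4)
      if (y_true[i] == t && y_pred[i] == p)
        oracle[t + 1, p + 1] <- oracle[t + 1, p + 1] + 1L
  expect_equal(unclass(unname(cm)), oracle)
  expect_equal(sum(cm), 50L)
})

test_that("confusion handles perfect and single-sample cases", {
  y <- c(0L, 1L, 2L, 1L)
  cm <- confusion(y, y, 3L)
  expect_equal(unname(diag(cm)), c(1L, 2L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm1 <- confusion(0L, 1L, 2L)
  expect_equal(unname(cm1[1, 2]), 1L)
  expect_equal(sum(cm1), 1L)
  expect_error(confusion(c(0L, 3L), c(0L, 0L), 3L), "outside")
})

test_that("metrics reproduce hand arithmetic on a 2-class matrix", {
  cm <- matrix(c(8L, 3L, 2L, 7L), 2, 2)  # rows true: [[8,2],[3,7]]
  m <- metrics(cm)
  expect_equal(m$per_class$precision, c(8 / 11, 7 / 9))
  expect_equal(m$per_class$recall, c(8 / 10, 7 / 10))
  f0 <- 2 * (8 / 11) * (8 / 10) / (8 / 11 + 8 / 10)
  f1 <- 2 * (7 / 9) * (7 / 10) / (7 / 9 + 7 / 10)
  expect_equal(m$per_class$fscore, c(f0, f1))
  expect_equal(m$macro_fscore, mean(c(f0, f1)))
  expect_equal(m$accuracy, 15 / 20)
})

test_that("a perfect diagonal gives all-ones metrics, for any labelling", {
  for (s in 1:5) {
    y <- with_seed_test(100L + s, sample(0:3, 30, replace = TRUE))
    y <- c(y, 0:3)  # ensure every class occurs
    m <- metrics(confusion(y, y, 4L))
    expect_equal(m$macro_precision, 1)
    expect_equal(m$macro_recall, 1)
    expect_equal(m$macro_fscore, 1)
    expect_equal(m$accuracy, 1)
  }
})

test_that("micro precision = micro recall = accuracy on random matrices", {
  for (s in 1:100) {
    K <- with_seed_test(200L + s, sample(2:6, 1))
    cm <- with_seed_test(300L + s,
                         matrix(rpois(K * K, 3), K, K))
    if (sum(cm) == 0) cm[1, 1] <- 1L
    m <- metrics(cm)
    expect_equal(m$micro_precision, m$accuracy)
    expect_equal(m$micro_recall, m$accuracy)
    # macro F never exceeds the arithmetic mean of macro P and R bound
    expect_lte(m$macro_fscore, 1)
  }
})

test_that("F-score is the harmonic mean, bounded by the arithmetic mean", {
  expect_equal(round(fscore(0.8988, 0.8889), 4), 0.8938)
  expect_equal(round(fscore(0.9267, 0.9259), 4), 0.9263)
  expect_equal(round(fscore(0.8333, 0.8194), 4), 0.8263)
  # published F for (0.9705, 0.9688) is 0.9697, apparently from unrounded
  # inputs; the harmonic mean of the printed values is 0.969649
  expect_lt(abs(fscore(0.9705, 0.9688) - 0.9697), 1e-4)
  expect_equal(fscore(0.5, 0.5), 0.5)
  pr <- with_seed_test(20L, cbind(runif(50), runif(50)))
  f <- fscore(pr[, 1], pr[, 2])
  expect_true(all(f <= rowMeans(pr) + 1e-12))
  expect_warning(f0 <- fscore(0, 0), "both 0")
  expect_equal(f0, 0)
  expect_error(fscore(1.2, 0.5), "\\[0, 1\\]")
})

test_that("classes never predicted get precision 0 and are flagged", {
  cm <- matrix(c(5L, 5L, 0L, 0L), 2, 2)  # everything predicted as class 0
  m <- metrics(cm)
  expect_equal(m$per_class$precision[2], 0)
  expect_identical(m$empty_prediction_classes, 1L)
})

test_that("model_report reproduces metrics() per partition", {
  tab <- simulate_spectra_table(small_config(seed = 61L,
                                             preset = "well_separated"))
  sp <- stratified_split(tab$labels, seed = 2L)
  fit <- fit_plsda(tab$X[sp$train_rows, ], tab$labels[sp$train_rows],
                   ncomp = 2L)
  rep_df <- model_report(list(plsda = fit), sp, tab)
  expect_identical(nrow(rep_df), 2L)
  for (part in c("training", "testing")) {
    idx <- if (part == "training") sp$train_rows else sp$test_rows
    m <- metrics(confusion(tab$labels[idx],
                           predict(fit, tab$X[idx, , drop = FALSE]), 3L))
    row <- rep_df[rep_df$partition == part, ]
    expect_equal(row$precision, m$macro_precision)
    expect_equal(row$recall, m$macro_recall)
    expect_equal(row$fscore, m$macro_fscore)
    expect_equal(row$accuracy, m$accuracy)
  }
})

test_that("report rows scale with the number of models; perfect model is all ones", {
  tab <- simulate_spectra_table(small_config(seed = 62L,
                                             preset = "well_separated",
                                             pixel_noise_sd = 0.001))
  sp <- stratified_split(tab$labels, seed = 3L)
  m1 <- fit_plsda(tab$X[sp$train_rows, ], tab$labels[sp$train_rows],
                  ncomp = 2L)
  m2 <- fit_svm_rbf(tab$X[sp$train_rows, ], tab$labels[sp$train_rows],
                    c_grid = 10, g_grid = 0.01, inner_cv_folds = 2L)
  rep_df <- model_report(list(plsda = m1, svm = m2), sp, tab)
  expect_identical(nrow(rep_df), 4L)
  expect_true(all(abs(rep_df$accuracy - 1) < 1e-12))
  expect_true(all(abs(rep_df$fscore - 1) < 1e-12))
})
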