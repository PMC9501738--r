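test_that("activation, softmax, loss and schedule match closed forms", {
  expect_equal(elu(2), 2)
  expect_equal(elu(0), 0)
  expect_equal(elu(-1, 1), exp(-1) - 1)
  expect_error(elu(1, alpha = 0), "positive")
  # continuity and monotonicity around 0
  xs <- seq(-3, 3, by = 0.01)
  expect_true(all(diff(elu(xs, 0.7)) > 0))
  expect_lt(abs(elu(1e-9) - elu(-1e-9)), 1e-8)

  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(1, 2)), c(0.26894, 0.73106), tolerance = 1e-5)
  expect_equal(softmax(c(1, 2)), softmax(c(1, 2) + 1000))  # shift invariance
  big <- softmax(c(1e4, 0))
  expect_true(all(is.finite(big)))

  p <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(cross_entropy_loss(p, c(0L, 0L)),
               (-log(0.9) - log(0.5)) / 2)
  expect_equal(cross_entropy_loss(diag(3), 0:2), 0, tolerance = 1e-10)
  expect_equal(cross_entropy_loss(matrix(1 / 12, 1, 12), 0L), log(12))

  expect_equal(lr_schedule(0, 5e-4, 0.045), 5e-4)
  expect_equal(lr_schedule(10, 1e-3, 0), 1e-3)
  expect_equal(lr_schedule(800, 5e-4, 0.045), 5e-4 / 37)
  ts <- 0:100
  expect_true(all(diff(lr_schedule(ts, 5e-4, 0.045)) <= 0))
})

test_that("softmax rows are probability vectors for random logits", {
  Z <- with_seed_test(14L, matrix(rnorm(200, sd = 5), 20, 10))
  P <- softmax(Z)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-6)
})

test_that("the block geometry halves the sequence five times", {
  expect_equal(pooled_lengths(176L), c(88L, 44L, 22L, 11L, 5L))
  expect_equal(pooled_lengths(199L), c(99L, 49L, 24L, 12L, 6L))
  expect_error(build_cnn(cnn_spec(), 20L), "too short")
})

test_that("spec invariants are enforced", {
  expect_error(cnn_spec(kernel = 4L), "odd")
  expect_error(cnn_spec(filters = c(32, 16)), "non-decreasing")
  expect_error(cnn_spec(dropout_p = 1), "dropout_p")
})

test_that("an untrained network predicts the uniform distribution", {
  spec <- cnn_spec(n_classes = 12L, seed = 2L)
  model <- build_cnn(spec, 64L)
  X <- with_seed_test(15L, matrix(rnorm(5 * 64), 5, 64))
  fw <- herbspec:::cnn_forward(model, X, training = FALSE)
  expect_equal(dim(fw$logits), c(5L, 12L))
  expect_equal(softmax(fw$logits), matrix(1 / 12, 5, 12), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  spec <- cnn_spec(n_classes = 3L, filters = c(2L, 2L), fc_width = 4L,
                   dropout_p = 0, seed = 5L)
  model <- build_cnn(spec, 8L)
  X <- with_seed_test(16L, matrix(rnorm(4 * 8), 4, 8))
  y <- c(0L, 1L, 2L, 0L)
  Y <- herbspec:::one_hot(y, 3L)
  loss_at <- function(params) {
    m <- model
    m$params <- params
    fw <- herbspec:::cnn_forward(m, X, training = TRUE)
    cross_entropy_loss(softmax(fw$logits), Y)
  }
  fw <- herbspec:::cnn_forward(model, X, training = TRUE)
  dlogits <- (softmax(fw$logits) - Y) / 4
  grads <- herbspec:::cnn_backward(model, fw, dlogits)
  eps <- 1e-5
  for (nm in c("b1_c1_W", "b2_c2_W", "b1_c2_gamma", "b2_c1_beta",
               "fc1_W", "fc2_b")) {
    th <- model$params[[nm]]
    idx <- with_seed_test(17L, sample(length(th), min(4L, length(th))))
    for (i in idx) {
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_lt(abs(grads[[nm]][i] - fd), 1e-6 + 1e-4 * abs(fd))
    }
  }
})

test_that("training is deterministic and starts near the uniform loss", {
  cfg <- small_config(seed = 51L, preset = "well_separated")
  tab <- simulate_spectra_table(cfg)
  spec <- cnn_spec(n_classes = 3L, seed = 9L, batch_size = 8L)
  f1 <- fit_cnn(tab, spec = spec, epochs = 2L)
  f2 <- fit_cnn(tab, spec = spec, epochs = 2L)
  expect_identical(f1$history$loss, f2$history$loss)
  # 3 balanced classes: first recorded loss near log(3)
  expect_lt(abs(f1$history$loss[1] - log(3)), 0.3)
})

test_that("a short training run masters the well-separated small fixture", {
  cfg <- small_config(seed = 52L, preset = "well_separated",
                      samples_per_class = 10L)
  tab <- simulate_spectra_table(cfg)
  fit <- fit_cnn(tab, spec = cnn_spec(n_classes = 3L, seed = 1L,
                                      batch_size = 16L), epochs = 25L)
  expect_gte(mean(predict(fit, tab) == tab$labels), 0.99)
  prob <- predict(fit, tab, type = "prob")
  expect_equal(rowSums(prob), rep(1, 30), tolerance = 1e-6)
  expect_equal(length(fit$history$loss), 25L)
  expect_true(fit$history$best_epoch >= 1L)
})

test_that("out-of-range labels are rejected", {
  spec <- cnn_spec(n_classes = 2L, filters = c(2L, 2L), fc_width = 2L)
  model <- build_cnn(spec, 8L)
  expect_error(train_cnn(model, matrix(rnorm(16), 2, 8), c(0L, 5L)),
               "labels")
})
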