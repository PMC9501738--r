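# One-dimensional VGG-style convolutional network for spectra, implemented
# directly on BLAS matrix kernels: five blocks of
# [conv(k3,s1,p1) -> batch-norm -> ELU] x 2 -> max-pool(2), then
# flatten -> dense -> ELU -> dropout -> dense(K), trained with Adam on the
# softmax cross-entropy loss under a 1/(1+kt) learning-rate decay.

#' Exponential linear unit
#'
#' `x` for `x > 0`, `alpha * (exp(x) - 1)` otherwise; continuous and
#' monotone increasing.
#'
#' @param x numeric vector/array.
#' @param alpha positive saturation parameter.
#' @return elementwise ELU of `x`.
#' @export
elu <- function(x, alpha = 1) {
  if (alpha <= 0) stopf("alpha must be positive")
  ifelse(x > 0, x, alpha * (exp(x) - 1))
}

elu_grad <- function(x, alpha = 1) ifelse(x > 0, 1, alpha * exp(x))

#' Numerically stable softmax
#'
#' Exponentials are taken after subtracting the row maximum, so arbitrarily
#' large logits do not overflow; output rows are probability vectors.
#'
#' @param z numeric vector, or matrix with one sample per row.
#' @return probabilities with the same shape as `z`.
#' @export
softmax <- function(z) {
  if (is.null(dim(z))) {
    e <- exp(z - max(z))
    return(e / sum(e))
  }
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

#' Mean softmax cross-entropy loss
#'
#' `-sum_i sum_j label_ij log(p_ij) / n`, with the log argument clamped at
#' `1e-12`.
#'
#' @param p matrix of class probabilities, one sample per row.
#' @param labels one-hot matrix of the same shape, or a 0-based integer
#'   label vector.
#' @return mean loss over the batch (a single number).
#' @export
cross_entropy_loss <- function(p, labels) {
  p <- rbind(p)
  if (is.null(dim(labels)))
    labels <- one_hot(as.integer(labels), ncol(p))
  if (!all(dim(labels) == dim(p)))
    stopf("labels shape (%s) does not match probabilities (%s)",
          paste(dim(labels), collapse = "x"), paste(dim(p), collapse = "x"))
  -sum(labels * log(pmax(p, 1e-12))) / nrow(p)
}

#' Hyperbolic learning-rate decay
#'
#' `eta0 / (1 + k * t)` for epoch `t >= 0`; monotone non-increasing.
#'
#' @param t epoch index (0-based).
#' @param eta0 initial learning rate.
#' @param k decay constant.
#' @return the learning rate at epoch `t`.
#' @export
lr_schedule <- function(t, eta0 = 5e-4, k = 0.045) {
  if (any(t < 0) || eta0 <= 0 || k < 0) stopf("need t >= 0, eta0 > 0, k >= 0")
  eta0 / (1 + k * t)
}

#' Specification of the 1-D convolutional classifier
#'
#' Defaults follow the reference architecture: five blocks of two
#' 3-tap convolutions (stride 1, padding 1) with batch normalization and
#' ELU(1.0), filter ladder 16-32-64-128-128, max-pooling of 2 after each
#' block, a 256-wide dense layer with dropout 0.5, and Adam over 800
#' epochs at batch size 256 with learning rate `0.0005 / (1 + 0.045 t)`.
#'
#' @param n_classes number of output classes.
#' @param filters filters per block (positive, non-decreasing).
#' @param kernel odd convolution kernel size.
#' @param alpha ELU saturation.
#' @param fc_width width of the hidden dense layer.
#' @param dropout_p dropout probability in `[0, 1)`.
#' @param epochs,batch_size,eta0,k_decay training schedule.
#' @param seed seed for weight initialization, shuffling and dropout.
#' @return object of class `cnn_spec`.
#' @export
cnn_spec <- function(n_classes = 12L, filters = c(16L, 32L, 64L, 128L, 128L),
                     kernel = 3L, alpha = 1.0, fc_width = 256L,
                     dropout_p = 0.5, epochs = 800L, batch_size = 256L,
                     eta0 = 5e-4, k_decay = 0.045, seed = 1L) {
  if (kernel %% 2L != 1L) stopf("kernel size must be odd")
  if (any(filters <= 0) || any(diff(filters) < 0))
    stopf("filters must be positive and non-decreasing")
  if (dropout_p < 0 || dropout_p >= 1) stopf("dropout_p must be in [0, 1)")
  structure(list(n_classes = check_count(n_classes, "n_classes", 2L),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 convs_per_block = 2L, alpha = alpha,
                 fc_width = check_count(fc_width, "fc_width"),
                 dropout_p = dropout_p,
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 eta0 = eta0, k_decay = k_decay, seed = as.integer(seed)),
            class = "cnn_spec")
}

# ---- layer kernels -------------------------------------------------------

conv1d_forward <- function(A, W, b) {
  d <- dim(A)                       # B, L, Cin
  B <- d[1]; L <- d[2]; Cin <- d[3]
  k <- nrow(W) / Cin                # taps
  pad <- (k - 1) / 2
  Ap <- array(0, c(B, L + 2 * pad, Cin))
  Ap[, (pad + 1):(pad + L), ] <- A
  Xcol <- matrix(0, B * L, k * Cin)
  for (j in seq_len(k))
    Xcol[, ((j - 1) * Cin + 1):(j * Cin)] <-
      matrix(Ap[, j:(j + L - 1), , drop = FALSE], B * L, Cin)
  Z <- Xcol %*% W
  Z <- sweep(Z, 2L, b, `+`)
  list(out = array(Z, c(B, L, ncol(W))), Xcol = Xcol, dims = d, k = k)
}

conv1d_backward <- function(cache, W, dY) {
  d <- cache$dims
  B <- d[1]; L <- d[2]; Cin <- d[3]
  k <- cache$k
  pad <- (k - 1) / 2
  dYm <- matrix(dY, B * L, ncol(W))
  dW <- crossprod(cache$Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- dYm %*% t(W)
  dAp <- array(0, c(B, L + 2 * pad, Cin))
  for (j in seq_len(k))
    dAp[, j:(j + L - 1), ] <- dAp[, j:(j + L - 1), , drop = FALSE] +
      array(dXcol[, ((j - 1) * Cin + 1):(j * Cin)], c(B, L, Cin))
  list(dA = dAp[, (pad + 1):(pad + L), , drop = FALSE], dW = dW, db = db)
}

bn_forward <- function(A, gamma, beta, run, training, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(A)
  M <- matrix(A, prod(d[1:2]), d[3])
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(M, 2L, mu), 2L, inv_std, `*`)
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = array(Y, d), xhat = xhat, inv_std = inv_std, run = run,
       dims = d)
}

bn_backward <- function(cache, gamma, dY) {
  d <- cache$dims
  N <- prod(d[1:2])
  dYm <- matrix(dY, N, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, `*`)
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / N)
  t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / N, `*`)
  dM <- sweep(t1 - t2, 2L, cache$inv_std, `*`)
  list(dA = array(dM, d), dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(A) {
  d <- dim(A)
  Lo <- d[2] %/% 2L
  A1 <- A[, seq(1L, 2L * Lo, 2L), , drop = FALSE]
  A2 <- A[, seq(2L, 2L * Lo, 2L), , drop = FALSE]
  take1 <- A1 >= A2
  list(out = ifelse(take1, A1, A2), take1 = take1, dims = d, Lo = Lo)
}

maxpool_backward <- function(cache, dY) {
  d <- cache$dims
  dA <- array(0, d)
  Lo <- cache$Lo
  dA[, seq(1L, 2L * Lo, 2L), ] <- dY * cache$take1
  dA[, seq(2L, 2L * Lo, 2L), ] <- dY * !cache$take1
  dA
}

# ---- model construction --------------------------------------------------

#' Pooled sequence lengths through the convolutional blocks
#'
#' @param n_bands input spectrum length.
#' @param n_blocks number of pool-by-2 blocks.
#' @return integer vector of the length after each block (floor division).
#' @export
pooled_lengths <- function(n_bands, n_blocks = 5L) {
  out <- integer(n_blocks)
  len <- as.integer(n_bands)
  for (i in seq_len(n_blocks)) {
    len <- len %/% 2L
    out[i] <- len
  }
  out
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build an untrained 1-D CNN
#'
#' Allocates He-initialized weights for the block structure of
#' [cnn_spec()] given the input spectrum length. The spectrum must survive
#' one halving per block (`n_bands >= 2^n_blocks`).
#'
#' @param spec a [cnn_spec()].
#' @param n_bands input spectrum length.
#' @return object of class `cnn_model` holding parameters, running
#'   batch-norm statistics and layer geometry.
#' @export
build_cnn <- function(spec, n_bands) {
  stopifnot(inherits(spec, "cnn_spec"))
  n_blocks <- length(spec$filters)
  lens <- pooled_lengths(n_bands, n_blocks)
  if (lens[n_blocks] < 1L)
    stopf("spectrum of %d bands is too short for %d pooling halvings",
          n_bands, n_blocks)
  k <- spec$kernel
  params <- list()
  run <- list()
  with_seed(spec$seed, {
    cin <- 1L
    for (b in seq_len(n_blocks)) {
      cout <- spec$filters[b]
      for (cv in seq_len(spec$convs_per_block)) {
        id <- sprintf("b%d_c%d", b, cv)
        params[[paste0(id, "_W")]] <- he_init(k * cin, cout, k * cin)
        params[[paste0(id, "_b")]] <- numeric(cout)
        params[[paste0(id, "_gamma")]] <- rep(1, cout)
        params[[paste0(id, "_beta")]] <- numeric(cout)
        run[[id]] <- list(mean = numeric(cout), var = rep(1, cout))
        cin <- cout
      }
    }
    flat <- lens[n_blocks] * spec$filters[n_blocks]
    params$fc1_W <- he_init(flat, spec$fc_width, flat)
    params$fc1_b <- numeric(spec$fc_width)
    # zero-initialized output layer: the untrained network predicts the
    # uniform distribution, so the initial loss is log(K)
    params$fc2_W <- matrix(0, spec$fc_width, spec$n_classes)
    params$fc2_b <- numeric(spec$n_classes)
  })
  structure(list(spec = spec, n_bands = as.integer(n_bands),
                 n_blocks = n_blocks, params = params, run = run,
                 pooled = lens),
            class = "cnn_model")
}

# Forward pass. training = TRUE uses batch statistics and dropout and
# returns caches for backprop; otherwise running statistics, no dropout.
cnn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  p <- model$params
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- list()
  run <- model$run
  for (b in seq_len(model$n_blocks)) {
    for (cv in seq_len(spec$convs_per_block)) {
      id <- sprintf("b%d_c%d", b, cv)
      cc <- conv1d_forward(A, p[[paste0(id, "_W")]], p[[paste0(id, "_b")]])
      bnc <- bn_forward(cc$out, p[[paste0(id, "_gamma")]],
                        p[[paste0(id, "_beta")]], run[[id]], training)
      run[[id]] <- bnc$run
      A <- elu(bnc$out, spec$alpha)
      if (training)
        caches[[id]] <- list(conv = cc, bn = bnc, pre_elu = bnc$out)
    }
    mp <- maxpool_forward(A)
    A <- mp$out
    if (training) caches[[sprintf("pool%d", b)]] <- mp
  }
  flat <- matrix(A, B, prod(dim(A)[2:3]))
  z1 <- sweep(flat %*% p$fc1_W, 2L, p$fc1_b, `+`)
  a1 <- elu(z1, spec$alpha)
  if (training && spec$dropout_p > 0) {
    mask <- matrix(stats::runif(length(a1)) >= spec$dropout_p,
                   nrow(a1), ncol(a1)) / (1 - spec$dropout_p)
    a1d <- a1 * mask
  } else {
    mask <- NULL
    a1d <- a1
  }
  logits <- sweep(a1d %*% p$fc2_W, 2L, p$fc2_b, `+`)
  list(logits = logits, run = run,
       cache = if (training) list(caches = caches, flat = flat, z1 = z1,
                                  a1 = a1, mask = mask, a1d = a1d,
                                  flat_dims = dim(A)) else NULL)
}

cnn_backward <- function(model, fw, dlogits) {
  spec <- model$spec
  p <- model$params
  ch <- fw$cache
  grads <- list()
  grads$fc2_W <- crossprod(ch$a1d, dlogits)
  grads$fc2_b <- colSums(dlogits)
  da1 <- dlogits %*% t(p$fc2_W)
  if (!is.null(ch$mask)) da1 <- da1 * ch$mask
  dz1 <- da1 * elu_grad(ch$z1, spec$alpha)
  grads$fc1_W <- crossprod(ch$flat, dz1)
  grads$fc1_b <- colSums(dz1)
  dA <- array(dz1 %*% t(p$fc1_W), ch$flat_dims)
  for (b in rev(seq_len(model$n_blocks))) {
    dA <- maxpool_backward(ch$caches[[sprintf("pool%d", b)]], dA)
    for (cv in rev(seq_len(spec$convs_per_block))) {
      id <- sprintf("b%d_c%d", b, cv)
      lc <- ch$caches[[id]]
      dpre <- dA * elu_grad(lc$pre_elu, spec$alpha)
      bb <- bn_backward(lc$bn, p[[paste0(id, "_gamma")]], dpre)
      grads[[paste0(id, "_gamma")]] <- bb$dgamma
      grads[[paste0(id, "_beta")]] <- bb$dbeta
      cb <- conv1d_backward(lc$conv, p[[paste0(id, "_W")]], bb$dA)
      grads[[paste0(id, "_W")]] <- cb$dW
      grads[[paste0(id, "_b")]] <- cb$db
      dA <- cb$dA
    }
  }
  grads
}

#' Train a built CNN with Adam
#'
#' Mini-batch Adam on the softmax cross-entropy loss with the hyperbolic
#' learning-rate decay of [lr_schedule()]. Shuffling, dropout and weight
#' initialization all derive from the spec's seed, so identical seeds give
#' identical runs. The returned model carries the parameters of the epoch
#' with the lowest training loss and the full per-epoch loss history.
#'
#' @param model a [build_cnn()] model.
#' @param X standardized samples x bands matrix.
#' @param y 0-based integer labels in `[0, n_classes)`.
#' @param epochs overrides the spec's epoch count (e.g. for short runs).
#' @return the trained `cnn_model` with elements `history` (epoch losses)
#'   and `best_epoch`.
#' @export
train_cnn <- function(model, X, y, epochs = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  spec <- model$spec
  X <- as.matrix(X)
  y <- as.integer(y)
  if (any(y < 0L | y >= spec$n_classes))
    stopf("labels must lie in [0, %d)", spec$n_classes)
  n <- nrow(X)
  epochs <- if (is.null(epochs)) spec$epochs else check_count(epochs, "epochs")
  Y <- one_hot(y, spec$n_classes)
  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  step <- 0L
  history <- numeric(epochs)
  best <- list(loss = Inf, params = model$params, run = model$run,
               epoch = 0L)
  with_seed(spec$seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr <- lr_schedule(ep - 1L, spec$eta0, spec$k_decay)
      perm <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = spec$batch_size)) {
        rows <- perm[start:min(start + spec$batch_size - 1L, n)]
        fw <- cnn_forward(model, X[rows, , drop = FALSE], training = TRUE)
        model$run <- fw$run
        prob <- softmax(fw$logits)
        loss <- cross_entropy_loss(prob, Y[rows, , drop = FALSE])
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d", ep)
        ep_loss <- ep_loss + loss * length(rows)
        dlogits <- (prob - Y[rows, , drop = FALSE]) / length(rows)
        grads <- cnn_backward(model, fw, dlogits)
        step <- step + 1L
        bc1 <- 1 - beta1^step
        bc2 <- 1 - beta2^step
        for (nm in names(grads)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
          model$params[[nm]] <- model$params[[nm]] -
            lr * (adam_m[[nm]] / bc1) / (sqrt(adam_v[[nm]] / bc2) + aeps)
        }
      }
      history[ep] <- ep_loss / n
      if (history[ep] < best$loss)
        best <- list(loss = history[ep], params = model$params,
                     run = model$run, epoch = ep)
    }
  })
  model$params <- best$params
  model$run <- best$run
  model$history <- list(loss = history, best_epoch = best$epoch)
  model$trained <- TRUE
  model
}

#' Fit the CNN classifier on spectra
#'
#' Convenience wrapper: learns a per-band standardizer from the training
#' rows, builds the network for the table's band count, trains it, and
#' returns the uniform classifier object.
#'
#' @param x a [spectra_table()] or samples x bands matrix.
#' @param labels 0-based integer class ids (taken from the table if
#'   omitted).
#' @param spec a [cnn_spec()]; its `n_classes` is checked against the
#'   labels.
#' @param epochs optional override of `spec$epochs`.
#' @return object of classes `cnn_classifier`, `herb_classifier`.
#' @export
fit_cnn <- function(x, labels = NULL, spec = NULL, epochs = NULL) {
  d <- resolve_xy(x, labels)
  if (is.null(spec)) spec <- cnn_spec(n_classes = d$K)
  if (spec$n_classes < d$K)
    stopf("spec has %d classes but labels contain %d", spec$n_classes, d$K)
  std <- standardize_fit(d$X)
  Xs <- standardize_apply(std, d$X)
  model <- build_cnn(spec, ncol(Xs))
  model <- train_cnn(model, Xs, d$y, epochs = epochs)
  structure(list(kind = "cnn", model = model, K = spec$n_classes,
                 standardizer = std, history = model$history),
            class = c("cnn_classifier", "herb_classifier"))
}

#' @export
predict.cnn_classifier <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectra_table")) newdata$X else
    as.matrix(newdata)
  if (!is.null(object$standardizer))
    X <- standardize_apply(object$standardizer, X)
  prob <- matrix(0, nrow(X), object$K)
  for (start in seq(1L, nrow(X), by = 512L)) {
    rows <- start:min(start + 511L, nrow(X))
    fw <- cnn_forward(object$model, X[rows, , drop = FALSE],
                      training = FALSE)
    prob[rows, ] <- softmax(fw$logits)
  }
  if (type == "prob") return(prob)
  max.col(prob, ties.method = "first") - 1L
}
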