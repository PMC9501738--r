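# Partial least squares discriminant analysis: PLS2 regression on a
# one-hot class-indicator matrix (SIMPLS algorithm), argmax decision rule,
# with leave-one-out selection of the number of latent variables.

# SIMPLS on centred X (n x p) and Y (n x m). Returns weight/loading
# matrices; regression coefficients for any a <= ncomp are
# R[, 1:a] %*% t(Q[, 1:a]), so one fit yields predictions for every
# component count up to ncomp.
simpls <- function(Xc, Yc, ncomp) {
  p <- ncol(Xc)
  m <- ncol(Yc)
  S <- crossprod(Xc, Yc)
  R <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    q <- svd(S, nu = 0, nv = 1)$v[, 1]
    r <- S %*% q
    t_sc <- Xc %*% r
    nt <- sqrt(sum(t_sc^2))
    if (nt < 1e-12) { ncomp <- a - 1L; break }
    t_sc <- t_sc / nt
    r <- r / nt
    pl <- crossprod(Xc, t_sc)
    ql <- crossprod(Yc, t_sc)
    v <- pl
    if (a > 1L) {
      Va <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pl)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    Q[, a] <- ql
    V[, a] <- v
  }
  list(R = R[, seq_len(ncomp), drop = FALSE],
       Q = Q[, seq_len(ncomp), drop = FALSE], ncomp = ncomp)
}

plsda_coefs <- function(fit, a) {
  fit$R[, seq_len(a), drop = FALSE] %*% t(fit$Q[, seq_len(a), drop = FALSE])
}

one_hot <- function(y, K) {
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

resolve_xy <- function(x, labels) {
  if (inherits(x, "spectra_table")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$X
  }
  if (is.null(labels)) stopf("class labels are required")
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  x <- as.matrix(x)
  if (nrow(x) != length(labels))
    stopf("%d rows but %d labels", nrow(x), length(labels))
  list(X = x, y = labels, K = max(labels) + 1L)
}

#' Fit a PLS-DA classifier
#'
#' Regresses a one-hot class-indicator matrix on the (standardized)
#' spectra by SIMPLS partial least squares; the predicted class is the
#' argmax of the predicted indicator responses. With `ncomp = "auto"` the
#' number of latent variables is chosen by leave-one-out cross-validation
#' over `1..max_ncomp`, taking the smallest count on ties.
#'
#' @param x a [spectra_table()] or samples x bands matrix.
#' @param labels 0-based integer class ids (taken from the table if
#'   omitted).
#' @param ncomp number of latent variables, or `"auto"`.
#' @param max_ncomp upper end of the auto-selection grid.
#' @param standardize learn per-band `(x - mean)/sd` scaling from the
#'   training rows and reapply it at prediction time.
#' @return object of classes `plsda_classifier`, `herb_classifier`; when
#'   `ncomp = "auto"` the element `loo_accuracy` records the accuracy
#'   profile over the grid.
#' @export
fit_plsda <- function(x, labels = NULL, ncomp = "auto", max_ncomp = 20L,
                      standardize = TRUE) {
  d <- resolve_xy(x, labels)
  if (d$K < 2L) stopf("PLS-DA needs at least 2 classes")
  std <- if (standardize) standardize_fit(d$X) else NULL
  X <- if (is.null(std)) d$X else standardize_apply(std, d$X)
  n <- nrow(X)
  kmax <- min(max_ncomp, n - 2L, ncol(X))
  loo_acc <- NULL
  if (identical(ncomp, "auto")) {
    hits <- matrix(0L, n, kmax)
    for (i in seq_len(n)) {
      pred <- plsda_predict_core(X[-i, , drop = FALSE], d$y[-i], d$K,
                                 X[i, , drop = FALSE], kmax)
      hits[i, ] <- as.integer(pred == d$y[i])
    }
    loo_acc <- colMeans(hits)
    ncomp <- which.max(loo_acc)   # which.max takes the first (smallest) tie
  } else {
    ncomp <- check_count(ncomp, "ncomp")
    if (ncomp > min(n - 1L, ncol(X)))
      stopf("ncomp = %d exceeds min(samples - 1, bands)", ncomp)
  }
  Yc <- scale(one_hot(d$y, d$K), scale = FALSE)
  ybar <- attr(Yc, "scaled:center")
  Xc <- scale(X, scale = FALSE)
  fit <- simpls(Xc, Yc, ncomp)
  structure(list(kind = "plsda", coef = plsda_coefs(fit, fit$ncomp),
                 x_center = attr(Xc, "scaled:center"), y_center = ybar,
                 ncomp = fit$ncomp, K = d$K, standardizer = std,
                 loo_accuracy = loo_acc),
            class = c("plsda_classifier", "herb_classifier"))
}

# fit on (Xtr, ytr), predict classes of Xte for every ncomp in 1..kmax
plsda_predict_core <- function(Xtr, ytr, K, Xte, kmax) {
  kmax <- min(kmax, nrow(Xtr) - 1L, ncol(Xtr))
  Yc <- scale(one_hot(ytr, K), scale = FALSE)
  Xc <- scale(Xtr, scale = FALSE)
  fit <- simpls(Xc, Yc, kmax)
  Xte_c <- sweep(Xte, 2L, attr(Xc, "scaled:center"))
  out <- integer(kmax)
  for (a in seq_len(fit$ncomp)) {
    Yhat <- sweep(Xte_c %*% plsda_coefs(fit, a), 2L,
                  attr(Yc, "scaled:center"), `+`)
    out[a] <- max.col(Yhat, ties.method = "first") - 1L
  }
  if (fit$ncomp < kmax) out[(fit$ncomp + 1L):kmax] <- out[fit$ncomp]
  out
}

#' @export
predict.plsda_classifier <- function(object, newdata,
                                     type = c("class", "response"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectra_table")) newdata$X else
    as.matrix(newdata)
  if (!is.null(object$standardizer))
    X <- standardize_apply(object$standardizer, X)
  Yhat <- sweep(sweep(X, 2L, object$x_center) %*% object$coef, 2L,
                object$y_center, `+`)
  if (type == "response") return(Yhat)
  max.col(Yhat, ties.method = "first") - 1L
}

#' Leave-one-out cross-validated accuracy
#'
#' For every row, trains on the remaining rows and predicts the held-out
#' row; returns the fraction predicted correctly.
#'
#' @param train_fn function `(X, y) -> model` with a `predict(model, X)`
#'   method returning 0-based class labels.
#' @param X samples x features matrix.
#' @param y 0-based integer labels.
#' @return accuracy in `[0, 1]`.
#' @export
loo_cv <- function(train_fn, X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (n < 2L) stopf("leave-one-out needs at least 2 rows")
  correct <- 0L
  for (i in seq_len(n)) {
    model <- train_fn(X[-i, , drop = FALSE], y[-i])
    pred <- predict(model, X[i, , drop = FALSE])
    correct <- correct + as.integer(pred[1L] == y[i])
  }
  correct / n
}
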