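# Confusion matrices and macro precision / recall / F-score.

#' Confusion matrix
#'
#' `counts[t, p]` is the number of samples with true class `t` predicted
#' as class `p` (0-based ids).
#'
#' @param y_true,y_pred 0-based integer label vectors of equal length.
#' @param K number of classes; labels must lie in `[0, K)`.
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, K = NULL) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred differ in length")
  if (is.null(K)) K <- max(y_true, y_pred) + 1L
  K <- check_count(K, "K")
  if (any(y_true < 0L | y_true >= K) || any(y_pred < 0L | y_pred >= K))
    stopf("labels outside [0, %d)", K)
  cm <- matrix(0L, K, K,
               dimnames = list(true = 0:(K - 1L), pred = 0:(K - 1L)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  class(cm) <- c("confusion_matrix", "matrix")
  cm
}

#' F-score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`; defined as 0 when both are 0 (the
#' degenerate case is flagged with a warning).
#'
#' @param precision,recall values in `[0, 1]`.
#' @return the F-score.
#' @export
fscore <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1))
    stopf("precision and recall must lie in [0, 1]")
  degenerate <- precision + recall == 0
  if (any(degenerate))
    warning("precision and recall both 0; F-score set to 0")
  ifelse(degenerate, 0, 2 * precision * recall / (precision + recall))
}

#' Classification metrics from a confusion matrix
#'
#' Per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and their
#' harmonic-mean F-score. Macro values are unweighted means across
#' classes; accuracy is `trace/total`. Classes never predicted get
#' precision 0 (flagged). Micro-averaged precision/recall (both equal to
#' accuracy) are included as a consistency check.
#'
#' @param cm a [confusion()] matrix (rows = true, cols = predicted).
#' @return object of class `metrics_report`.
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0)
    stopf("need a non-empty square confusion matrix")
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  predicted <- colSums(cm) > 0
  precision <- ifelse(predicted, tp / (tp + fp), 0)
  recall <- ifelse(rowSums(cm) > 0, tp / (tp + fn), 0)
  f <- ifelse(precision + recall == 0, 0,
              2 * precision * recall / (precision + recall))
  structure(list(per_class = data.frame(class = 0:(K - 1L),
                                        precision = precision,
                                        recall = recall, fscore = f,
                                        support = rowSums(cm),
                                        row.names = NULL),
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_fscore = mean(f),
                 accuracy = sum(tp) / sum(cm),
                 micro_precision = sum(tp) / sum(cm),
                 micro_recall = sum(tp) / sum(cm),
                 empty_prediction_classes = which(!predicted) - 1L,
                 n = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4L, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  accuracy        %.*f\n", digits, x$accuracy))
  cat(sprintf("  macro precision %.*f\n", digits, x$macro_precision))
  cat(sprintf("  macro recall    %.*f\n", digits, x$macro_recall))
  cat(sprintf("  macro F-score   %.*f\n", digits, x$macro_fscore))
  if (length(x$empty_prediction_classes))
    cat("  never predicted:",
        paste(x$empty_prediction_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Side-by-side train/test report for several models
#'
#' Evaluates each trained classifier on the training and testing partition
#' of one split and tabulates macro precision, recall, F-score and
#' accuracy — one row per (model, partition).
#'
#' @param models named list of `herb_classifier` objects trained on the
#'   split's training rows.
#' @param split a [stratified_split()].
#' @param table the labelled [spectra_table()] the split indexes.
#' @return data.frame of class `model_report`.
#' @export
model_report <- function(models, split, table) {
  stopifnot(inherits(split, "split_indices"),
            inherits(table, "spectra_table"))
  if (is.null(table$labels)) stopf("table must be labelled")
  n <- nrow(table$X)
  if (max(split$train_rows, split$test_rows) > n ||
      length(split$train_rows) + length(split$test_rows) != n)
    stopf("split does not match the table (%d rows)", n)
  K <- max(table$labels) + 1L
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$kind, "")
  rows <- list()
  for (nm in names(models)) {
    for (part in c("training", "testing")) {
      idx <- if (part == "training") split$train_rows else split$test_rows
      pred <- predict(models[[nm]], table$X[idx, , drop = FALSE])
      mr <- metrics(confusion(table$labels[idx], pred, K))
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, partition = part,
        precision = mr$macro_precision, recall = mr$macro_recall,
        fscore = mr$macro_fscore, accuracy = mr$accuracy)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("model_report", "data.frame")
  out
}

#' @export
print.model_report <- function(x, digits = 4L, ...) {
  y <- as.data.frame(x)
  y[c("precision", "recall", "fscore", "accuracy")] <-
    lapply(y[c("precision", "recall", "fscore", "accuracy")], round,
           digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
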