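#' Classification accuracy
#'
#' Fraction of test images whose predicted class equals the true class.
#'
#' @param predicted,true equal-length 0-based integer label vectors.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_score <- function(predicted, true) {
  if (length(predicted) != length(true) || !length(true)) {
    stopf("predicted and true labels must have equal positive length")
  }
  mean(as.integer(predicted) == as.integer(true))
}

#' Confusion matrix
#'
#' @param predicted,true 0-based integer labels.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` count matrix; rows = true class, columns =
#'   predicted class.
#' @export
confusion_counts <- function(predicted, true, n_classes = 18L) {
  if (length(predicted) != length(true)) stopf("length mismatch")
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1L),
                              predicted = 0:(n_classes - 1L)))
  for (i in seq_along(true)) {
    m[true[i] + 1L, predicted[i] + 1L] <- m[true[i] + 1L, predicted[i] + 1L] + 1L
  }
  m
}

#' Macro-averaged precision and recall
#'
#' Per-class precision `TP / (TP + FP)` and recall `TP / (TP + FN)`, averaged
#' unweighted across classes. A class that is never predicted contributes
#' precision 0 (with a warning); a class absent from the truth contributes
#' recall 0.
#'
#' @param predicted,true 0-based integer labels.
#' @param n_classes number of classes.
#' @return Named list: `macro_precision`, `macro_recall`, plus per-class
#'   vectors `precision` and `recall`.
#' @export
macro_precision_recall <- function(predicted, true, n_classes = 18L) {
  if (length(predicted) != length(true) || !length(true)) {
    stopf("predicted and true labels must have equal positive length")
  }
  cm <- confusion_counts(predicted, true, n_classes)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  if (any(pred_tot == 0)) {
    warning(sprintf("class(es) never predicted (precision set to 0): %s",
                    paste(which(pred_tot == 0) - 1L, collapse = ", ")))
  }
  list(macro_precision = mean(precision), macro_recall = mean(recall),
       precision = precision, recall = recall)
}

#' Full evaluation report
#'
#' @param predicted,true 0-based integer labels.
#' @param n_classes number of classes.
#' @return Object of class `ir_report`: list with `accuracy`,
#'   `macro_precision`, `macro_recall` and the `confusion` matrix.
#' @export
evaluation_report <- function(predicted, true, n_classes = 18L) {
  pr <- suppressWarnings(macro_precision_recall(predicted, true, n_classes))
  structure(list(accuracy = accuracy_score(predicted, true),
                 macro_precision = pr$macro_precision,
                 macro_recall = pr$macro_recall,
                 confusion = confusion_counts(predicted, true, n_classes)),
            class = "ir_report")
}

#' @export
print.ir_report <- function(x, ...) {
  cat(sprintf("<ir_report: accuracy %.4f, macro precision %.4f, macro recall %.4f (n = %d)>\n",
              x$accuracy, x$macro_precision, x$macro_recall, sum(x$confusion)))
  invisible(x)
}
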