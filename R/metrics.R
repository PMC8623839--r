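# Evaluation metrics: confusion matrices, balanced (macro-recall) and
# unbalanced accuracy.  The rest pose (label 0) is a first-class label
# throughout, which is why balanced accuracy is the headline metric: rest
# dominates the window stream and inflates plain accuracy.

#' Confusion matrix
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Class label set; defaults to the union of observed labels.
#' @return A `K x K` matrix of counts, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty input")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  ti <- factor(y_true, levels = classes)
  pi <- factor(y_pred, levels = classes)
  as.matrix(table(true = ti, predicted = pi))
}

#' Balanced classification accuracy
#'
#' Macro-average of per-class recall over the classes present in `y_true`
#' (classes with no support are excluded, since their recall is undefined).
#' The rest class participates like any other.
#'
#' @param y_true,y_pred Label vectors of equal length (non-empty).
#' @return A scalar in `[0, 1]`.
#' @examples
#' balanced_accuracy(c(0, 0, 1, 1), c(0, 1, 1, 1))  # (0.5 + 1)/2
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty input")
  present <- sort(unique(y_true))
  recalls <- vapply(present, function(k) {
    mean(y_pred[y_true == k] == k)
  }, numeric(1))
  mean(recalls)
}

#' Unbalanced (plain) classification accuracy
#'
#' @param y_true,y_pred Label vectors of equal length (non-empty).
#' @return Fraction of exact matches.
#' @export
unbalanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty input")
  mean(y_true == y_pred)
}

#' Full metric report for a prediction
#'
#' @param y_true,y_pred Label vectors of equal length (non-empty).
#' @return An object of class `emg_metric_report`: `balanced_accuracy`,
#'   `unbalanced_accuracy`, per-class `recall` and `support` (classes present
#'   in `y_true`), and the `confusion` matrix.
#' @export
metric_report <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  present <- sort(unique(y_true))
  recall <- vapply(present, function(k) mean(y_pred[y_true == k] == k),
                   numeric(1))
  names(recall) <- present
  support <- vapply(present, function(k) sum(y_true == k), numeric(1))
  names(support) <- present
  structure(list(balanced_accuracy = mean(recall),
                 unbalanced_accuracy = mean(y_true == y_pred),
                 recall = recall, support = support, confusion = cm),
            class = "emg_metric_report")
}

#' @export
print.emg_metric_report <- function(x, ...) {
  cat(sprintf("balanced accuracy %.4f | unbalanced %.4f | %d classes\n",
              x$balanced_accuracy, x$unbalanced_accuracy, length(x$recall)))
  print(round(x$recall, 4))
  invisible(x)
}
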