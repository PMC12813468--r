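# Confusion matrices and accuracy / precision / recall / F1 summaries for
# the five-group classification task.

#' Confusion matrix
#'
#' Rows are true groups, columns predicted groups, both labelled with the
#' diagnostic group names.
#'
#' @param y_true,y_pred integer group codes 0..(n_classes-1), equal length.
#' @param n_classes number of classes (default 5).
#' @return integer `n_classes x n_classes` matrix of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 5L) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= n_classes)) {
    stop("labels must be in 0..", n_classes - 1L, call. = FALSE)
  }
  lev <- 0:(n_classes - 1L)
  cm <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  cm <- unclass(matrix(as.integer(cm), n_classes, n_classes))
  nm <- if (n_classes == 5L) names(GROUP_CODES)[order(GROUP_CODES)] else
    as.character(lev)
  dimnames(cm) <- list(true = nm, predicted = nm)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  y <- x
  attr(y, "class") <- NULL
  print(y, ...)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and
#' `F1 = 2PR / (P + R)` are computed from the matrix, together with overall
#' accuracy `trace / total` and two aggregates: micro (pooled counts; for
#' single-label data micro precision = micro recall = accuracy) and
#' support-weighted (per-class values weighted by true-class counts, the
#' headline aggregate). A class absent from both truth and predictions gets
#' metric 0 and is flagged in `undefined_classes`.
#'
#' @param cm a [confusion_matrix()] (any square count matrix works).
#' @return list of class `metrics_report`: `accuracy`, `per_class`
#'   data.frame, `micro` and `weighted` precision/recall/F1, and
#'   `undefined_classes`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0)) {
    stop("cm must be a square non-negative count matrix", call. = FALSE)
  }
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  support <- rowSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  undefined <- which(support == 0 & colSums(cm) == 0)
  w <- support / total
  micro_p <- sum(tp) / (sum(tp) + sum(fp))
  micro_r <- sum(tp) / (sum(tp) + sum(fn))
  structure(list(
    accuracy = sum(tp) / total,
    per_class = data.frame(
      class = if (is.null(rownames(cm))) seq_len(nrow(cm)) - 1L else
        rownames(cm),
      support = as.integer(support), precision = precision,
      recall = recall, f1 = f1, row.names = NULL),
    micro = c(precision = micro_p, recall = micro_r,
              f1 = safe_div(2 * micro_p * micro_r, micro_p + micro_r)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    undefined_classes = as.integer(undefined) - 1L,
    n = as.integer(total)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n = %d | accuracy %.4f | weighted P/R/F1 %.4f/%.4f/%.4f\n",
    x$n, x$accuracy, x$weighted["precision"], x$weighted["recall"],
    x$weighted["f1"]))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Evaluate a trained model on a labelled heatmap set
#'
#' Convenience wrapper: predicts, builds the confusion matrix and metrics,
#' and reports the test cross-entropy.
#'
#' @param model trained `longiheat_model`.
#' @param x heatmap array.
#' @param y true group codes.
#' @return list with `confusion`, `metrics`, `loss`, `y_pred`.
#' @export
evaluate_model <- function(model, x, y) {
  x <- as_batch(x, model$spec)
  ml <- model_loss(model, x, y,
                   isTRUE(model$train_config$mask_loss))
  probs <- subject_probs(model, ml$fwd, dim(x)[1L])
  y_pred <- max.col(probs) - 1L
  cm <- confusion_matrix(y, y_pred, model$spec$n_classes)
  list(confusion = cm, metrics = classification_metrics(cm),
       loss = ml$ce$loss, y_pred = y_pred)
}
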