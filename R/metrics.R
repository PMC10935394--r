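## area under the precision-recall curve by step integration
## (average-precision form: sum over positives of precision at each recall step)
prAUC <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive)
  if (n_pos == 0L || n_pos == length(positive)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  pos <- positive[o]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  ## step integral: precision is averaged within tied-score blocks implicitly
  ## by taking the last point of each block
  keep <- c(diff(scores[o]) != 0, TRUE)
  prec <- prec[keep]; rec <- rec[keep]
  sum(diff(c(0, rec)) * prec)
}

rocAUC <- function(scores, positive) {
  if (length(unique(positive)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = positive, predictor = scores,
                                 levels = c(FALSE, TRUE),
                                 direction = "<", quiet = TRUE)))
}

f1Score <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Binary classification metrics for the necrosis/vital task
#'
#' Computes the full metric panel from necrosis-probability scores:
#' per class (necrosis, vital) the AUROC and AUPR with that class as
#' positive, precision, recall, f1 and the misclassification ratio (defined
#' as the per-class error rate, `1 - recall`), plus overall accuracy and
#' macro / support-weighted averages of precision, recall and f1. Hard
#' labels are obtained by `score >= threshold` -> necrosis.
#'
#' @param scores numeric vector of necrosis probabilities.
#' @param labels character/factor vector in `{"necrosis", "vital"}`.
#' @param threshold decision threshold on the necrosis-probability axis.
#' @return A `class_metrics` list with elements `per_class` (data.frame),
#'   `accuracy`, `macro` and `weighted` (named vectors of
#'   precision/recall/f1), `threshold` and the confusion counts.
#' @examples
#' m <- classMetrics(c(0.9, 0.8, 0.3, 0.1), c("necrosis", "vital",
#'                   "necrosis", "vital"), threshold = 0.5)
#' m$accuracy
#' @export
classMetrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("necrosis", "vital")),
            is.finite(threshold))
  pred <- ifelse(scores >= threshold, "necrosis", "vital")
  per <- lapply(c(necrosis = "necrosis", vital = "vital"), function(cl) {
    pos <- labels == cl
    pred_pos <- pred == cl
    tp <- sum(pos & pred_pos); fp <- sum(!pos & pred_pos)
    fn <- sum(pos & !pred_pos)
    s <- if (cl == "necrosis") scores else 1 - scores
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (sum(pos) == 0) NA_real_ else tp / sum(pos)
    data.frame(class = cl, support = sum(pos),
               auroc = rocAUC(s, pos), aupr = prAUC(s, pos),
               precision = precision, recall = recall,
               f1 = f1Score(tp, fp, fn),
               misclassification_ratio = 1 - recall,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- per$class
  w <- per$support / sum(per$support)
  macro <- colMeans(per[, c("precision", "recall", "f1")])
  weighted <- colSums(per[, c("precision", "recall", "f1")] * w)
  structure(list(per_class = per,
                 accuracy = mean(pred == labels),
                 macro = macro, weighted = weighted,
                 threshold = threshold,
                 confusion = table(truth = factor(labels,
                                     c("necrosis", "vital")),
                                   predicted = factor(pred,
                                     c("necrosis", "vital")))),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("Binary necrosis/vital metrics (threshold %.3f): accuracy %.3f\n",
              x$threshold, x$accuracy))
  print(x$per_class[, -1], digits = 3)
  cat(sprintf("  macro    P/R/f1: %.3f / %.3f / %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("  weighted P/R/f1: %.3f / %.3f / %.3f\n",
              x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  invisible(x)
}
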