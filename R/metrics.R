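#' Confusion matrix from truth/prediction label vectors
#'
#' @param truth,pred integer class labels in `1..n_classes`.
#' @param n_classes number of classes K.
#' @return A `K x K` integer matrix; rows index the true class, columns the
#'   predicted class.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  if (length(truth) != length(pred))
    stop_invalid("truth and pred must have equal length")
  cm <- matrix(0L, n_classes, n_classes)
  tab <- tabulate((pred - 1L) * n_classes + truth, nbins = n_classes^2)
  cm[] <- tab
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is the pooled proportion correct (`trace / total`);
#' average accuracy is the unweighted mean of per-class recalls; Cohen's
#' kappa is `(po - pe) / (1 - pe)` with observed agreement `po = trace /
#' total` and chance agreement `pe = sum_i(row_i * col_i) / total^2`.
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and the F1
#' harmonic mean are reported per class; classes with a zero denominator
#' yield 0 and are flagged in `undefined`.
#'
#' @param cm square non-negative matrix (rows = truth, cols = prediction).
#' @return An object of class `sst_metrics`: list with `cm`, `oa`, `aa`,
#'   `kappa`, `precision`, `recall`, `f1`, `undefined`, `n_test`.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_invalid("confusion matrix must be square")
  if (any(cm < 0)) stop_invalid("confusion matrix entries must be >= 0")
  total <- sum(cm)
  if (total == 0) stop_invalid("confusion matrix is empty")
  tp <- diag(cm)
  rowsum_ <- rowSums(cm)   # per-class truth counts (TP + FN)
  colsum_ <- colSums(cm)   # per-class prediction counts (TP + FP)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  recall <- safe_div(tp, rowsum_)
  precision <- safe_div(tp, colsum_)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  po <- sum(tp) / total
  pe <- sum(rowsum_ * colsum_) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  structure(list(cm = cm, oa = po, aa = mean(recall), kappa = kappa,
                 precision = precision, recall = recall, f1 = f1,
                 undefined = which(rowsum_ == 0 | colsum_ == 0 |
                                     (precision + recall) == 0),
                 n_test = total),
            class = "sst_metrics")
}

#' @export
print.sst_metrics <- function(x, ...) {
  cat(sprintf("OA %.2f%%  AA %.2f%%  kappa %.2f (x100)  [n = %d]\n",
              100 * x$oa, 100 * x$aa, 100 * x$kappa, x$n_test))
  invisible(x)
}
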