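# Ranking and classification metrics: one-vs-rest AUROC (Mann-Whitney
# concordance with half credit for ties), step-rule AUPRC (average
# precision), and macro/weighted F1 with the confusion matrix.

# binary AUROC of scores against 0/1 labels via the rank formula
auroc_binary <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# binary average precision: precision at each recall increment of the
# score-descending sweep, ties grouped by distinct score
auprc_binary <- function(scores, labels) {
  pos <- labels == 1
  P <- sum(pos)
  if (P == 0 || all(pos)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- as.numeric(pos[ord])
  grp_last <- cumsum(rle(s)$lengths)          # last index of each tie group
  tp <- cumsum(y)[grp_last]
  n_seen <- grp_last
  precision <- tp / n_seen
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' One-vs-rest AUROC per class and macro average
#'
#' Per class `c`, the AUROC of posterior column `c` against the indicator
#' `label == c`, computed as the Mann-Whitney concordance with ties counted
#' one half. A class absent from `labels` gets `NA` and is excluded from the
#' macro average with a warning.
#'
#' @param posteriors `M x C` matrix of class scores, columns in class-code
#'   order (colnames are the class codes).
#' @param labels length-M vector of true class codes.
#' @return list with `per_class` (named numeric) and `macro`.
#' @export
auroc_ovr <- function(posteriors, labels) {
  classes <- colnames(posteriors)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(posteriors)) - 1L)
  per <- vapply(seq_along(classes), function(j) {
    auroc_binary(posteriors[, j], as.numeric(labels == classes[j]))
  }, numeric(1))
  names(per) <- classes
  if (all(is.na(per))) {
    ieeg_error("no class has both positive and negative examples", "ieegsift_degenerate_labels")
  }
  if (anyNA(per)) {
    warning("classes absent from labels excluded from macro AUROC: ",
            paste(classes[is.na(per)], collapse = ", "))
  }
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' One-vs-rest AUPRC (average precision) per class and macro average
#'
#' Area under the precision-recall step curve: precision evaluated at each
#' recall increment of the descending-score sweep (no trapezoids).
#'
#' @inheritParams auroc_ovr
#' @return list with `per_class` and `macro`.
#' @export
auprc_ovr <- function(posteriors, labels) {
  classes <- colnames(posteriors)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(posteriors)) - 1L)
  per <- vapply(seq_along(classes), function(j) {
    auprc_binary(posteriors[, j], as.numeric(labels == classes[j]))
  }, numeric(1))
  names(per) <- classes
  if (all(is.na(per))) {
    ieeg_error("no class has both positive and negative examples", "ieegsift_degenerate_labels")
  }
  if (anyNA(per)) {
    warning("classes absent from labels excluded from macro AUPRC: ",
            paste(classes[is.na(per)], collapse = ", "))
  }
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' Macro and weighted F1 with the confusion matrix
#'
#' Per-class `F1 = 2PR/(P+R)` with the 0-convention when `P + R = 0`; macro is
#' the unweighted mean, weighted the support-weighted mean. Confusion-matrix
#' rows are true classes, columns predicted.
#'
#' @param predictions,labels aligned vectors of class codes.
#' @param classes class codes fixing the matrix order (default: union seen).
#' @return list with `macro_f1`, `weighted_f1`, `per_class_f1`, `precision`,
#'   `recall`, `confusion`.
#' @export
f1_scores <- function(predictions, labels, classes = NULL) {
  if (length(predictions) != length(labels)) {
    ieeg_error("predictions and labels differ in length", "ieegsift_shape_mismatch")
  }
  if (is.null(classes)) classes <- sort(unique(c(predictions, labels)))
  f_true <- factor(labels, levels = classes)
  f_pred <- factor(predictions, levels = classes)
  cm <- table(true = f_true, predicted = f_pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(cm)
  list(macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * support) / sum(support),
       per_class_f1 = stats::setNames(as.numeric(f1), classes),
       precision = stats::setNames(as.numeric(prec), classes),
       recall = stats::setNames(as.numeric(rec), classes),
       confusion = cm)
}
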