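# Binary classification metrics used to score DDI predictions.

#' Classification metrics for DDI predictions
#'
#' ACC, F1, precision and recall are computed at the given decision threshold
#' (default 0.5, the natural choice for 1:1 positive/negative sampling); AUC
#' is the Mann-Whitney rank statistic over positive/negative pairs (ties
#' count one half) and AP is the area under the precision-recall curve
#' accumulated over distinct score thresholds. If the labels contain only one
#' class, AUC and AP are `NA`.
#'
#' @param labels 0/1 labels.
#' @param probs Predicted probabilities of the same length.
#' @param threshold Decision threshold for the thresholded metrics.
#' @return One-row tibble with columns `acc`, `auc`, `f1`, `prec`, `rec`,
#'   `ap`, `n`.
#' @export
ddi_metrics <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs))
  labels <- as.integer(labels)
  pred <- as.integer(probs >= threshold)

  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  acc <- mean(pred == labels)
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else {
    NA_real_
  }

  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    auc <- NA_real_
    ap <- NA_real_
  } else {
    r <- rank(probs)
    auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ap <- average_precision(labels, probs)
  }

  tibble::tibble(acc = acc, auc = auc, f1 = f1, prec = prec, rec = rec,
                 ap = ap, n = length(labels))
}

# AP = sum over thresholds of (recall step) * precision, thresholds taken at
# the distinct predicted scores in decreasing order
average_precision <- function(labels, probs) {
  thr <- sort(unique(probs), decreasing = TRUE)
  n1 <- sum(labels == 1L)
  ap <- 0
  prev_rec <- 0
  for (t in thr) {
    sel <- probs >= t
    tp <- sum(labels[sel] == 1L)
    prec <- tp / sum(sel)
    rec <- tp / n1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
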