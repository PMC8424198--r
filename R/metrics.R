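#' Confusion-matrix metrics at a score threshold
#'
#' Predicts positive when `score >= threshold` (default 0.5) and returns
#' accuracy, precision, recall and F1 from the standard confusion-matrix
#' definitions. When nothing is predicted positive, precision is reported
#' as 0 with a warning (and F1 follows suit).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold, default 0.5.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  if (tp + fp == 0) {
    warning("no predicted positives at threshold ", threshold,
            "; precision reported as 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / length(labels),
    precision = precision, recall = recall, f1 = f1)
}

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted half — computed from midranks, which
#' is exactly the trapezoidal ROC integral.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("roc_auc needs both classes present")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' The average-precision estimator: scanning pairs in decreasing score
#' order, the precision at each positive is averaged over all positives.
#' Ties are broken by original position (stable), which is documented
#' rather than interpolated away; with the package's continuous scores ties
#' are measure-zero.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1)
  if (np == 0 || np == length(labels)) stop("pr_auc needs both classes present")
  ord <- order(-scores)
  y <- labels[ord]
  cum_tp <- cumsum(y)
  sum((cum_tp / seq_along(y))[y == 1]) / np
}

# All six evaluation metrics as one named vector.
all_metrics <- function(scores, labels, threshold = 0.5) {
  c(binary_metrics(scores, labels, threshold),
    auc = roc_auc(scores, labels),
    aupr = pr_auc(scores, labels))
}

#' Split samples into k near-equal folds
#'
#' Seeded shuffle followed by contiguous slicing; fold sizes differ by at
#' most one and the folds partition all samples.
#'
#' @param n number of samples.
#' @param k number of folds (default 5).
#' @param seed optional integer seed.
#' @return integer vector of fold assignments (1..k) per sample.
#' @export
kfold_split <- function(n, k = 5, seed = NULL) {
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("need at least k samples")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}
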