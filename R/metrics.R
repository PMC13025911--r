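#' Area under the ROC curve
#'
#' Tie-aware pairwise definition: the probability that a random positive
#' scores above a random negative, with half credit for ties, computed via
#' midranks in O(n log n).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 outcomes.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  assert_prob_labels(scores, labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- length(labels) - n1
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over unique score thresholds: the sum of
#' precision times the recall increment at each threshold, descending. Under
#' random scores its expectation is approximately the outcome prevalence,
#' which makes it the metric of choice at 7% positive rates.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 outcomes (at least one positive).
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  assert_prob_labels(scores, labels, require_both = FALSE)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop_posticu("AUPR requires at least one positive.", "degenerate")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate at the last index of each tied block of scores
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Operating threshold by Youden's J
#'
#' Returns the cut maximizing sensitivity + specificity - 1 over midpoints
#' between adjacent distinct scores (so perfectly separated scores yield the
#' midpoint of the gap); ties in J are broken toward the higher threshold,
#' i.e. toward higher specificity.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 outcomes.
#' @return The numeric threshold; predictions at or above it are positive.
#' @export
optimal_threshold <- function(scores, labels) {
  assert_prob_labels(scores, labels)
  u <- sort(unique(scores))
  cuts <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  cuts <- c(min(u) - 1, cuts, max(u) + 1)
  n1 <- sum(labels == 1); n0 <- length(labels) - n1
  j <- vapply(cuts, function(ct) {
    sens <- sum(scores >= ct & labels == 1) / n1
    spec <- sum(scores < ct & labels == 0) / n0
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cuts[max(best)]
}
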