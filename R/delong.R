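#' DeLong test for two correlated AUROCs
#'
#' Nonparametric paired comparison of two scores of the same stays via
#' placement values (structural components): for each score, the positive
#' placements `V10` and negative placements `V01` are computed from midranks
#' in O(n log n); the variance of the AUROC difference follows from their
#' empirical covariances, and the p-value from a two-sided normal
#' approximation. When the two scores rank the stays identically the
#' difference has zero variance; the result is flagged degenerate with
#' p = 1.
#'
#' @param scores_a,scores_b Paired risk scores on identical stays.
#' @param labels Binary 0/1 outcomes.
#' @return A `delong_test` list: `auroc_a`, `auroc_b`, `delta`, `z`,
#'   `p_value`, `var_delta`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  assert_prob_labels(scores_a, labels)
  assert_prob_labels(scores_b, labels)
  comp_a <- delong_components(scores_a, labels)
  comp_b <- delong_components(scores_b, labels)
  m <- length(comp_a$v10); n <- length(comp_a$v01)
  s10 <- stats::cov(cbind(comp_a$v10, comp_b$v10))
  s01 <- stats::cov(cbind(comp_a$v01, comp_b$v01))
  # var(theta_a - theta_b)
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- comp_a$theta - comp_b$theta
  degenerate <- var_delta <= .Machine$double.eps
  z <- if (degenerate) 0 else delta / sqrt(var_delta)
  p <- if (degenerate) 1 else 2 * pnorm(-abs(z))
  structure(list(auroc_a = comp_a$theta, auroc_b = comp_b$theta,
                 delta = delta, z = z, p_value = p, var_delta = var_delta,
                 degenerate = degenerate),
            class = "delong_test")
}

# Placement values via midranks (the fast structural-components algorithm).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n            # P(X > Y | X = x_i)
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m    # P(X > Y | Y = y_j)
  theta <- mean(v10)
  list(v10 = v10, v01 = v01, theta = theta)
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf(
    "DeLong paired AUROC test\n  AUROC A: %.4f   AUROC B: %.4f   diff: %+.4f\n  z = %.3f, two-sided p = %.4g%s\n",
    x$auroc_a, x$auroc_b, x$delta, x$z, x$p_value,
    if (x$degenerate) "  [degenerate: identical rankings]" else ""))
  invisible(x)
}
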