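# ROC/AUC computation and inference: the Mann-Whitney AUC estimator, the
# DeLong confidence interval, significance of the AUC against 0.5 via its
# rank-sum (Mason-Graham) correspondence, and Benjamini-Hochberg FDR
# adjustment.

check_scored_labels <- function(score, label) {
  if (length(score) != length(label)) stop("length mismatch", call. = FALSE)
  if (any(!label %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (!any(label == 1) || !any(label == 0))
    stop("both outcome classes must be present", call. = FALSE)
  invisible(TRUE)
}

#' Mann-Whitney AUC estimator
#'
#' Fraction of (positive, negative) score pairs ranked correctly, ties
#' counted one half — the area under the empirical ROC curve. Computed via
#' average ranks, identical to the explicit pair count.
#'
#' @param score continuous classifier score per subject.
#' @param label binary outcome per subject (1 = positive class).
#' @return The AUC in \[0, 1\].
#' @export
auc <- function(score, label) {
  check_scored_labels(score, label)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the AUC
#'
#' Normal-quantile interval with the DeLong (1988) variance estimate,
#' truncated to \[0, 1\]: the AUC variance is estimated from the
#' placement-value components `var(V10)/n1 + var(V01)/n0`, ties counted
#' one half. A degenerate AUC of exactly 0 or 1 collapses the interval
#' with a warning.
#'
#' @param score,label as in [auc()]; each class needs >= 2 members.
#' @param level confidence level (default 0.95).
#' @return `c(lo, hi)`.
#' @export
auc_ci <- function(score, label, level = 0.95) {
  check_scored_labels(score, label)
  x <- score[label == 1]; y <- score[label == 0]
  if (length(x) < 2 || length(y) < 2)
    stop("each class needs >= 2 members for a CI", call. = FALSE)
  a <- auc(score, label)
  # placement values via midranks (O(n log n) form of the pairwise count)
  r_all <- rank(score)
  v10 <- (r_all[label == 1] - rank(x)) / length(y)
  v01 <- 1 - (r_all[label == 0] - rank(y)) / length(x)
  s2 <- var(v10) / length(x) + var(v01) / length(y)
  if (s2 <= 0)
    warning("degenerate AUC: DeLong variance is zero, interval collapses")
  z <- qnorm(1 - (1 - level) / 2)
  c(lo = max(0, a - z * sqrt(s2)), hi = min(1, a + z * sqrt(s2)))
}

#' Mason-Graham significance of the AUC against 0.5
#'
#' Two-sided p-value for H0: AUC = 0.5, exploiting the identity between
#' the AUC and the Mann-Whitney U statistic: U = n1 n0 AUC. The exact
#' rank-sum null distribution is used when `n1 * n0 <= max_exact` and the
#' scores are tie-free; otherwise a normal approximation with tie
#' correction.
#'
#' @param score,label as in [auc()].
#' @param max_exact largest `n1 * n0` for which the exact null is
#'   enumerated (default `1e4`, covering cohorts of the size in scope).
#' @return The two-sided p-value.
#' @export
mason_graham_p <- function(score, label, max_exact = 1e4) {
  check_scored_labels(score, label)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  u <- auc(score, label) * n1 * n0
  ties <- anyDuplicated(score) > 0
  if (!ties && n1 * n0 <= max_exact) {
    u <- round(u)
    p <- 2 * min(pwilcox(u, n1, n0),
                 1 - if (u >= 1) pwilcox(u - 1, n1, n0) else 0)
    return(min(1, p))
  }
  N <- n1 + n0
  mu <- n1 * n0 / 2
  tie_tab <- table(score)
  sigma2 <- n1 * n0 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, returned in the
#' original order.
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return The adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  stop_if_not_prob(p)
  p.adjust(p, method = "BH")
}
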