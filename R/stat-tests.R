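# Univariate group-comparison statistics: Welch t-tests (from raw data or
# published summaries), Fisher exact tests on r x c contingency tables, and
# the Spearman correlation screen among continuous covariates.

#' Welch two-sample t-test from group summaries
#'
#' Computes the Welch statistic, Welch-Satterthwaite degrees of freedom
#' (left non-integer) and two-sided p-value directly from per-group sample
#' size, mean and standard deviation, so published summary tables can be
#' re-tested without raw data.
#'
#' @param n1,m1,s1 size, mean and sd of group 1.
#' @param n2,m2,s2 size, mean and sd of group 2.
#' @return A list with elements `t`, `df` and `p`.
#' @export
welch_t_from_summaries <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be > 0", call. = FALSE)
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' @rdname welch_t_from_summaries
#' @param x,y raw observation vectors (length >= 2, positive variance).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2", call. = FALSE)
  if (var(x) <= 0 || var(y) <= 0) stop("zero within-group variance", call. = FALSE)
  welch_t_from_summaries(length(x), mean(x), sd(x),
                         length(y), mean(y), sd(y))
}

#' Fisher exact test for an r x c contingency table
#'
#' Two-sided exact p-value under the multivariate hypergeometric null with
#' fixed margins, summing the probabilities of all tables no more probable
#' than the observed one (the Freeman-Halton convention for tables larger
#' than 2 x 2). Rows or columns with zero margin are dropped with a
#' warning.
#'
#' @param table matrix of non-negative counts, at least 2 x 2 after
#'   dropping empty margins.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  rz <- rowSums(table) == 0; cz <- colSums(table) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-margin rows/columns")
    table <- table[!rz, !cz, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("table must be at least 2 x 2 after dropping empty margins",
         call. = FALSE)
  fisher.test(table, workspace = 2e6)$p.value
}

#' Spearman correlation matrix of continuous covariates
#'
#' Pairwise rank correlations with average ranks for ties. Constant
#' columns give undefined correlations, reported as `NA` with a warning.
#'
#' @param x data.frame or matrix of continuous covariates, >= 3 rows.
#' @return The correlation matrix.
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 subjects", call. = FALSE)
  const <- apply(x, 2, function(v) var(v) == 0)
  if (any(const))
    warning("constant columns give undefined correlations: ",
            paste(colnames(x)[const], collapse = ", "))
  suppressWarnings(cor(x, method = "spearman"))
}
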