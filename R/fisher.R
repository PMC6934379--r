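# Exact contingency-table test and false-discovery-rate adjustment used for
# the cluster-membership comparisons.

#' Fisher's exact test for a 2 x k table
#'
#' Two-sided exact test by the point-probability method: over all tables
#' with the observed margins, the p-value sums the multivariate
#' hypergeometric probabilities of every table whose probability does not
#' exceed the observed table's (within a relative tolerance of about 1e-7
#' for floating-point ties). Delegates to [stats::fisher.test()], which
#' implements exactly this enumeration. All-zero columns admit a single
#' allocation and contribute nothing to the enumeration, so they are dropped
#' before testing; a table with an all-zero row, or with fewer than two
#' non-empty columns, is degenerate: p = 1 with `degenerate = TRUE`.
#'
#' @param table 2 x k matrix of non-negative integer counts (k >= 2); rows
#'   are typically genotypes, columns performance groups.
#' @return list with `p`, `method` and `degenerate`.
#' @export
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))$p  # 34/70
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2) {
    stopf("expected a 2 x k table with k >= 2")
  }
  if (any(table < 0) || any(table != round(table))) {
    stopf("counts must be non-negative integers")
  }
  if (sum(table) == 0) stopf("empty table")
  table <- table[, colSums(table) > 0, drop = FALSE]
  degenerate <- any(rowSums(table) == 0) || ncol(table) < 2
  p <- if (degenerate) 1 else stats::fisher.test(table)$p.value
  list(p = min(p, 1), method = "Fisher's exact test (two-sided)",
       degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with order statistics
#' `p(1) <= ... <= p(m)`, `adj(i) = min over j >= i of min(1, p(j) * m / j)`,
#' mapped back to input order. Delegates to
#' [stats::p.adjust()]`(method = "BH")`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.005, 0.05, 0.5))  # 0.015 0.075 0.500
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
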