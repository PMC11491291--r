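# ANCOM differential abundance.
#
# Analysis of composition of microbiomes: for each taxon i, form the
# additive log-ratio log((c_i + 1) / (c_j + 1)) against every other
# taxon j, compare the ratio between the two groups with a two-sided
# Mann-Whitney U test, apply Benjamini-Hochberg correction across taxon
# i's m - 1 tests, and count rejections:
#   W_i = #{ j : q_ij < alpha }.
# Taxon i is declared differentially abundant when W_i >= cutoff
# fraction * (m - 1).  Because log-ratios are scale-free, the statistic
# is invariant to per-sample sequencing depth (up to the pseudocount).

#' ANCOM W statistic between two groups
#'
#' @param counts Count matrix, samples x taxa (ASV-level or
#'   genus-collapsed).
#' @param groups Two-level label per sample (in row order).
#' @param alpha Per-ratio significance level after BH correction
#'   (default 0.05).
#' @param cutoff_fraction Fraction of the m - 1 ratio tests that must
#'   reject for detection (default 0.7).
#' @param pseudocount Added to every count before taking logs
#'   (default 1).
#' @return Data frame with one row per taxon: `taxon`, `W`, `detected`,
#'   `cutoff` (the W threshold used).
#' @export
ancom_w <- function(counts, groups, alpha = 0.05, cutoff_fraction = 0.7,
                    pseudocount = 1) {
  counts <- as.matrix(unclass(counts))
  groups <- as.factor(groups)
  if (length(groups) != nrow(counts)) stop("one group label per sample required")
  if (nlevels(groups) != 2) stop("ANCOM requires exactly two groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  m <- ncol(counts)
  if (m < 2) stop("ANCOM requires at least 2 taxa")

  lc <- log(counts + pseudocount)
  g1 <- groups == levels(groups)[1]
  # p[i, j]: Mann-Whitney p for the log-ratio of taxon i over taxon j
  pmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      if (j < i) {  # ratio j/i is the negation of i/j: same two-sided p
        pmat[i, j] <- pmat[j, i]
        next
      }
      ratio <- lc[, i] - lc[, j]
      pmat[i, j] <- mann_whitney_u(ratio[g1], ratio[!g1])$p_value
    }
  }
  w <- integer(m)
  for (i in seq_len(m)) {
    q <- bh_fdr(pmat[i, -i])
    w[i] <- sum(q < alpha)
  }
  cutoff <- ceiling(cutoff_fraction * (m - 1))
  data.frame(taxon = colnames(counts), W = w,
             detected = w >= cutoff, cutoff = cutoff,
             stringsAsFactors = FALSE)
}
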