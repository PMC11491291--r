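# Taxonomy-based exclusion, genus collapsing, rarefaction.
#
# These steps reproduce the standard QIIME-style preprocessing chain:
# drop organellar and unassigned ASVs, convert to relative abundance,
# summarise at genus level, and rarefy for diversity comparisons.

#' Drop ASVs matching organellar or unassigned taxonomy
#'
#' An ASV is removed when any part of its lineage contains one of the
#' patterns (case-insensitive substring match), or when it has no
#' taxonomy assignment at all — no lineage entry, or a lineage that stops
#' at domain level.
#'
#' @param table Feature table (samples x ASVs).
#' @param taxonomy Taxonomy data.frame.
#' @param patterns Character patterns to exclude; the default removes
#'   mitochondrial and chloroplast reads and unassigned ASVs.
#' @return Feature table restricted to the retained ASVs.
#' @export
exclude_taxa <- function(table, taxonomy,
                         patterns = c("mitochondria", "chloroplast",
                                      "unassigned")) {
  asvs <- colnames(table)
  idx <- match(asvs, taxonomy$asv_id)
  lineage <- taxonomy$lineage[idx]
  drop_unassigned <- "unassigned" %in% tolower(patterns)
  substr_patterns <- setdiff(tolower(patterns), "unassigned")

  has_rank_below_domain <- !is.na(idx) &
    rowSums(!is.na(as.matrix(taxonomy[idx, .tax_ranks[-1], drop = FALSE]))) > 0
  unassigned <- !has_rank_below_domain |
    grepl("unassigned", ifelse(is.na(lineage), "", lineage),
          ignore.case = TRUE)

  lineage_lc <- tolower(ifelse(is.na(lineage), "", lineage))
  matched <- rep(FALSE, length(asvs))
  for (p in substr_patterns) {
    matched <- matched | grepl(p, lineage_lc, fixed = TRUE)
  }
  drop <- matched | (drop_unassigned & unassigned)
  keep <- !drop
  if (!any(keep)) warning("taxonomy exclusion removed every ASV")
  feature_table(unclass(table)[, keep, drop = FALSE])
}

#' Collapse an abundance table to genus level
#'
#' Sums values over all ASVs assigned to the same genus.  ASVs without a
#' genus-level assignment are pooled under `unclassified_<rank>_<name>`
#' built from their deepest known rank (or `unassigned` when nothing is
#' known), so no abundance mass is lost.
#'
#' @param x Matrix (samples x ASVs), either relative abundances or raw
#'   counts; the collapse simply sums columns within genus.
#' @param taxonomy Taxonomy data.frame.
#' @return Matrix samples x genus labels.
#' @export
collapse_to_genus <- function(x, taxonomy) {
  labels <- genus_labels(taxonomy, colnames(x))
  groups <- factor(labels, levels = unique(labels))
  out <- t(rowsum(t(unclass(x)), groups))
  colnames(out) <- levels(groups)
  out
}

#' Genus label per ASV, with fallbacks for partial lineages
#'
#' @param taxonomy Taxonomy data.frame.
#' @param asv_ids ASV identifiers.
#' @return Character vector: the genus where known, otherwise
#'   `unclassified_<rank>_<deepest known name>`, otherwise `"unassigned"`.
#' @export
genus_labels <- function(taxonomy, asv_ids) {
  idx <- match(asv_ids, taxonomy$asv_id)
  vapply(idx, function(i) {
    if (is.na(i)) return("unassigned")
    g <- taxonomy$genus[i]
    if (!is.na(g)) return(g)
    known <- !is.na(unlist(taxonomy[i, .tax_ranks]))
    if (!any(known)) return("unassigned")
    deepest <- max(which(known))
    sprintf("unclassified_%s_%s", .tax_ranks[deepest],
            taxonomy[[.tax_ranks[deepest]]][i])
  }, character(1))
}

#' Median and IQR of the cumulative abundance of the top-k genera
#'
#' The k most abundant genera of a host are chosen by mean relative
#' abundance across that host's samples (ties broken alphabetically);
#' the statistic is the per-sample sum of their proportions, summarised
#' as median and interquartile range across samples.
#'
#' @param genus Genus table (samples x genera, proportions).
#' @param samples Sample ids defining the host's sample set.
#' @param k Number of top genera (default 5).
#' @return List with `top_genera`, `per_sample` (named sums), `median`,
#'   and `iqr` (quartiles Q1, Q3).
#' @export
top_k_cumulative <- function(genus, samples, k = 5) {
  if (length(samples) == 0) stop("empty sample set")
  missing <- setdiff(samples, rownames(genus))
  if (length(missing) > 0) {
    stop("sample(s) absent from genus table: ", paste(missing, collapse = ", "))
  }
  if (k > ncol(genus)) stop("k exceeds the number of genera")
  sub <- genus[samples, , drop = FALSE]
  means <- colMeans(sub)
  ord <- order(-means, colnames(sub))
  top <- colnames(sub)[ord[seq_len(k)]]
  sums <- rowSums(sub[, top, drop = FALSE])
  q <- stats::quantile(sums, c(0.25, 0.5, 0.75), names = FALSE)
  list(top_genera = top, per_sample = sums,
       median = q[2], iqr = c(q1 = q[1], q3 = q[3]))
}

#' Rarefy samples to a fixed read depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads.  Samples with fewer total
#' reads than `depth` are dropped with a warning.
#'
#' @param table Feature table.
#' @param depth Target reads per sample (>= 1).
#' @param seed Optional seed.
#' @return Feature table of the retained samples, each summing to `depth`;
#'   the ASV set (columns) is preserved, zeros allowed.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (depth <= 0) stop("rarefaction depth must be >= 1")
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(table)[!keep], collapse = ", "))
  }
  sub <- unclass(table)[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(feature_table(sub))
  }
  # counts are validated and depth pre-filtered, so vegan's data-shape
  # heuristics cannot apply here
  out <- .with_seed(seed, suppressWarnings(vegan::rrarefy(sub, depth)))
  feature_table(out)
}

#' Rarefaction curves of mean Shannon diversity
#'
#' For each sample and each depth on a grid, the sample is rarefied
#' `reps` times and the Shannon index averaged.  Depth 0 is defined as
#' diversity 0; depths exceeding a sample's total reads are omitted for
#' that sample.
#'
#' @param table Feature table.
#' @param depths Integer vector of depths (default 0 to 10000 in steps
#'   of 500).
#' @param reps Rarefactions per (sample, depth) (default 10).
#' @param seed Optional seed.
#' @param base Logarithm base for Shannon (default 2).
#' @return Long data.frame with columns `sample_id`, `depth`,
#'   `mean_shannon`.
#' @export
rarefaction_curve <- function(table, depths = seq(0, 10000, by = 500),
                              reps = 10, seed = NULL, base = 2) {
  stopifnot(reps >= 1)
  totals <- rowSums(table)
  .with_seed(seed, {
    rows <- lapply(rownames(table), function(s) {
      ds <- depths[depths <= totals[s]]
      if (length(ds) == 0) return(NULL)
      h <- vapply(ds, function(d) {
        if (d == 0) return(0)
        mean(vapply(seq_len(reps), function(r) {
          shannon(drop(suppressWarnings(
            vegan::rrarefy(unclass(table)[s, , drop = FALSE], d))),
            base = base)
        }, numeric(1)))
      }, numeric(1))
      data.frame(sample_id = s, depth = ds, mean_shannon = h,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
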