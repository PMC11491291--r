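# Alpha diversity and the rank / multiple-testing statistics used to
# compare hosts and time points.

#' Shannon diversity of one sample
#'
#' Entropy of the sample's relative-abundance vector,
#' H = -sum p_a log(p_a) over ASVs with p_a > 0.  Base-2 logarithms
#' (bits) are the default; pass `base = exp(1)` for nats.
#'
#' @param counts Numeric vector of counts (or proportions) for one
#'   sample.
#' @param base Logarithm base (default 2).
#' @return Shannon index, in units of log `base`.
#' @export
shannon <- function(counts, base = 2) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("cannot compute Shannon diversity of an all-zero sample")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value by enumeration when both groups have at most
#' `exact_max` observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_max Largest per-group size for the exact test
#'   (default 8).
#' @param label Optional comparison label carried into the result.
#' @return List with `statistic` (U for the first sample), `p_value`,
#'   `method`, and `label`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8, label = NA_character_) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = if (exact) "exact" else "normal approximation",
       label = label)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control: on sorted p-values,
#' q_(i) = min over j >= i of p_(j) * n / j, capped at 1, mapped back to
#' the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Within-pair distances at one time point
#'
#' For every cohabitation pair with both hosts sampled at the time
#' point, look up the distance between the two members' samples.  Pairs
#' missing either sample are skipped and reported.
#'
#' @param dm Distance matrix with sample ids as dimnames.
#' @param metadata Sample metadata.
#' @param timepoint Time-point label.
#' @return List with `distances` (named by pair id) and `incomplete`
#'   (pair ids skipped).
#' @export
pair_distances <- function(dm, metadata, timepoint) {
  md <- metadata[metadata$timepoint == timepoint, , drop = FALSE]
  hosts <- sort(unique(metadata$host))
  if (length(hosts) != 2) stop("pair distances need exactly two host labels")
  pairs <- sort(unique(md$pair_id))
  out <- numeric(0)
  incomplete <- character(0)
  for (pr in pairs) {
    s1 <- md$sample_id[md$pair_id == pr & md$host == hosts[1]]
    s2 <- md$sample_id[md$pair_id == pr & md$host == hosts[2]]
    if (length(s1) == 1 && length(s2) == 1) {
      out[pr] <- dm[s1, s2]
    } else {
      incomplete <- c(incomplete, pr)
    }
  }
  if (length(incomplete) > 0) {
    message("pair_distances: skipped incomplete pair(s) at ", timepoint,
            ": ", paste(incomplete, collapse = ", "))
  }
  list(distances = out, incomplete = incomplete)
}

#' Within-individual community shift between two time points
#'
#' For each individual of the given host sampled at both time points,
#' the distance between its own two samples — the magnitude of temporal
#' change in that individual's community.
#'
#' @param dm Distance matrix with sample ids as dimnames.
#' @param metadata Sample metadata.
#' @param host Host label selecting the individuals.
#' @param interval Length-2 vector of time-point labels (t1, t2).
#' @return Named numeric vector of distances, one per individual
#'   (named by pair id); individuals missing either sample are omitted.
#' @export
subject_shift <- function(dm, metadata, host, interval) {
  stopifnot(length(interval) == 2)
  md <- metadata[metadata$host == host, , drop = FALSE]
  pairs <- sort(unique(md$pair_id))
  out <- numeric(0)
  for (pr in pairs) {
    s1 <- md$sample_id[md$pair_id == pr & md$timepoint == interval[1]]
    s2 <- md$sample_id[md$pair_id == pr & md$timepoint == interval[2]]
    if (length(s1) == 1 && length(s2) == 1) {
      out[pr] <- dm[s1, s2]
    }
  }
  out
}
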