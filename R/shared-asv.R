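# Shared-ASV detection: the bespoke computation at the centre of the
# pipeline.  An ASV is "shared" within a cohabitation pair when its
# within-sample relative abundance exceeds the threshold (the
# p-percentage, default 1%) in BOTH members of the pair at the SAME time
# point.  The threshold screens out low-abundance noise; requiring both
# members keeps the call symmetric in the two hosts.

#' Configuration of the shared-ASV detector
#'
#' @param threshold Relative-abundance threshold (the p-percentage);
#'   must lie strictly between 0 and 1.  Default 0.01, i.e. "more than
#'   1%".
#' @param strict If `TRUE` (default) abundance must strictly exceed the
#'   threshold; if `FALSE`, equality counts.
#' @param one_sided If `TRUE`, only one member of the pair must pass the
#'   threshold while the other merely has non-zero abundance; default
#'   `FALSE` (both members must pass).
#' @return List of class `shared_config`.
#' @export
shared_config <- function(threshold = 0.01, strict = TRUE,
                          one_sided = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1")
  }
  structure(list(threshold = threshold, strict = strict,
                 one_sided = one_sided), class = "shared_config")
}

#' ASVs above the abundance threshold in one sample
#'
#' @param rel Relative-abundance matrix (samples x ASVs).
#' @param sample_id Sample to inspect.
#' @param cfg A [shared_config()].
#' @return Character vector of ASV ids whose relative abundance passes
#'   the threshold in this sample.
#' @export
presence_set <- function(rel, sample_id, cfg = shared_config()) {
  if (!sample_id %in% rownames(rel)) {
    stop("unknown sample: ", sample_id)
  }
  p <- rel[sample_id, ]
  pass <- if (cfg$strict) p > cfg$threshold else p >= cfg$threshold
  colnames(rel)[pass]
}

# internal: sample ids of the two members of a pair at a timepoint
.pair_samples <- function(metadata, pair_id, timepoint) {
  hosts <- sort(unique(metadata$host))
  sel <- metadata$pair_id == pair_id & metadata$timepoint == timepoint
  lapply(hosts, function(h) metadata$sample_id[sel & metadata$host == h])
}

#' Shared ASVs for one pair at one time point
#'
#' The intersection of the two members' threshold-passing ASV sets.  A
#' pair with either member unsampled at the time point yields an empty
#' result flagged `"incomplete"`, which is distinct from a genuinely
#' empty intersection (`"complete"`).
#'
#' @param rel Relative-abundance matrix.
#' @param metadata Sample metadata.
#' @param pair_id,timepoint The pair and visit to examine.
#' @param cfg A [shared_config()].
#' @return List with `asv_ids` (character vector) and `status`
#'   (`"complete"` or `"incomplete"`).
#' @export
shared_asvs_for_pair <- function(rel, metadata, pair_id, timepoint,
                                 cfg = shared_config()) {
  ss <- .pair_samples(metadata, pair_id, timepoint)
  if (any(lengths(ss) != 1)) {
    return(list(asv_ids = character(0), status = "incomplete"))
  }
  set1 <- presence_set(rel, ss[[1]], cfg)
  set2 <- presence_set(rel, ss[[2]], cfg)
  shared <- if (cfg$one_sided) {
    nz1 <- colnames(rel)[rel[ss[[1]], ] > 0]
    nz2 <- colnames(rel)[rel[ss[[2]], ] > 0]
    union(intersect(set1, nz2), intersect(set2, nz1))
  } else {
    intersect(set1, set2)
  }
  list(asv_ids = shared, status = "complete")
}

#' Enumerate all shared-ASV events and summarise sharing per ASV
#'
#' Scans every complete (pair, time point) combination, records one
#' event per shared ASV with both members' relative abundances, and
#' summarises how many distinct pairs share each ASV at each time point
#' (the long-table and per-ASV-count views of the result).
#'
#' @param rel Relative-abundance matrix.
#' @param metadata Sample metadata.
#' @param cfg A [shared_config()].
#' @param taxonomy Optional taxonomy data.frame used to annotate each
#'   event with its genus.
#' @return List with `events` (data.frame: asv_id, pair_id, timepoint,
#'   rel_abund_host1, rel_abund_host2, genus), `summary` (data.frame:
#'   asv_id, timepoint, n_pairs, pair ids), and `incomplete`
#'   (data.frame of skipped pair/timepoint combinations).
#' @export
shared_asv_summary <- function(rel, metadata, cfg = shared_config(),
                               taxonomy = NULL) {
  hosts <- sort(unique(metadata$host))
  timepoints <- levels(metadata$timepoint)
  pairs <- sort(unique(metadata$pair_id))
  ev <- list()
  skipped <- list()
  for (tp in timepoints) {
    for (pr in pairs) {
      res <- shared_asvs_for_pair(rel, metadata, pr, tp, cfg)
      if (res$status == "incomplete") {
        if (any(metadata$pair_id == pr & metadata$timepoint == tp)) {
          skipped[[length(skipped) + 1]] <-
            data.frame(pair_id = pr, timepoint = tp,
                       stringsAsFactors = FALSE)
        }
        next
      }
      if (length(res$asv_ids) == 0) next
      ss <- .pair_samples(metadata, pr, tp)
      ev[[length(ev) + 1]] <- data.frame(
        asv_id = res$asv_ids, pair_id = pr, timepoint = tp,
        rel_abund_host1 = rel[ss[[1]], res$asv_ids],
        rel_abund_host2 = rel[ss[[2]], res$asv_ids],
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev) > 0) {
    do.call(rbind, ev)
  } else {
    data.frame(asv_id = character(), pair_id = character(),
               timepoint = character(), rel_abund_host1 = numeric(),
               rel_abund_host2 = numeric(), stringsAsFactors = FALSE)
  }
  rownames(events) <- NULL
  events$genus <- if (!is.null(taxonomy)) {
    genus_labels(taxonomy, events$asv_id)
  } else {
    NA_character_
  }
  summary <- if (nrow(events) > 0) {
    agg <- stats::aggregate(pair_id ~ asv_id + timepoint, data = events,
                            FUN = function(p) paste(sort(unique(p)),
                                                    collapse = ","))
    agg$n_pairs <- vapply(strsplit(agg$pair_id, ","), length, integer(1))
    agg[order(agg$asv_id, match(agg$timepoint, timepoints)),
        c("asv_id", "timepoint", "n_pairs", "pair_id")]
  } else {
    data.frame(asv_id = character(), timepoint = character(),
               n_pairs = integer(), pair_id = character(),
               stringsAsFactors = FALSE)
  }
  names(summary)[names(summary) == "pair_id"] <- "pairs"
  rownames(summary) <- NULL
  incomplete <- if (length(skipped) > 0) {
    do.call(rbind, skipped)
  } else {
    data.frame(pair_id = character(), timepoint = character(),
               stringsAsFactors = FALSE)
  }
  list(events = events, summary = summary, incomplete = incomplete,
       hosts = hosts)
}

#' Abundance trajectory of one ASV in both members of a pair
#'
#' The per-time-point relative abundance of the ASV in each member of
#' the pair, the data behind a back-to-back ("butterfly") trajectory
#' plot.  Missing samples are `NA`, which is distinct from an observed
#' abundance of zero.
#'
#' @param rel Relative-abundance matrix.
#' @param metadata Sample metadata.
#' @param asv_id,pair_id The ASV and pair to trace.
#' @return Data frame with one row per configured time point and one
#'   abundance column per host.
#' @export
asv_trajectory <- function(rel, metadata, asv_id, pair_id) {
  if (!asv_id %in% colnames(rel)) stop("unknown ASV: ", asv_id)
  if (!pair_id %in% metadata$pair_id) stop("unknown pair: ", pair_id)
  hosts <- sort(unique(metadata$host))
  timepoints <- levels(metadata$timepoint)
  out <- data.frame(timepoint = timepoints, stringsAsFactors = FALSE)
  for (h in hosts) {
    out[[h]] <- vapply(timepoints, function(tp) {
      s <- metadata$sample_id[metadata$pair_id == pair_id &
                                metadata$host == h &
                                metadata$timepoint == tp]
      if (length(s) == 1 && s %in% rownames(rel)) rel[s, asv_id]
      else NA_real_
    }, numeric(1))
  }
  out
}

#' Number of ASVs observed in at least one sample
#'
#' @param table Feature table.
#' @return Integer count of ASVs with a non-zero count somewhere.
#' @export
total_asv_count <- function(table) {
  sum(colSums(unclass(table)) > 0)
}
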