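# Core data structures.
#
# The package follows the vegan/picante convention of plain base-R objects:
# an ASV count table is an integer matrix with samples in rows and ASVs in
# columns, sample metadata is a data.frame, a taxonomy map is a data.frame
# keyed by ASV id, and a phylogeny is an ape "phylo" object.  Constructors
# validate invariants once; downstream functions assume validated inputs.

#' Default ordered time-point labels
#'
#' The cohabitation design samples each host pair before adoption and at
#' three later visits.  All metadata handling uses this ordered set unless
#' another one is supplied.
#'
#' @return Character vector of time-point labels in temporal order.
#' @export
default_timepoints <- function() {
  c("pre", "week2", "month1", "month3")
}

.tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct and validate an ASV feature table
#'
#' A feature table holds non-negative integer read counts with samples in
#' rows and ASVs in columns.  Row and column names must be unique and
#' non-empty.
#'
#' @param counts Numeric matrix of read counts (samples x ASVs) with
#'   dimnames.  Values must be non-negative integers.
#' @return The validated count matrix with class `feature_table`.
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) {
    counts <- as.matrix(counts)
  }
  validate_feature_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' Validate feature-table invariants
#'
#' Checks that a count matrix has unique sample and ASV identifiers and
#' only non-negative integral entries.  Called by [feature_table()]; also
#' useful to re-validate a matrix after manual editing.
#'
#' @param counts Matrix to validate.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_feature_table <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("feature table must have sample (row) and ASV (column) names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample identifiers in feature table")
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate ASV identifiers in feature table")
  }
  if (!is.numeric(counts)) {
    stop("feature table entries must be numeric read counts")
  }
  if (anyNA(counts)) {
    stop("feature table contains missing values")
  }
  if (any(counts < 0)) {
    stop("feature table contains negative counts")
  }
  if (any(counts != round(counts))) {
    stop("feature table contains non-integer counts")
  }
  invisible(TRUE)
}

#' Construct and validate sample metadata
#'
#' Each sample carries a host label (a two-level set such as human/dog), a
#' cohabitation pair identifier, and a time point drawn from an ordered
#' label set.  The combination (host, pair_id, timepoint) must be unique:
#' each member of a pair is sampled at most once per visit.
#'
#' @param df Data frame with columns `sample_id`, `host`, `pair_id`,
#'   `timepoint`.
#' @param timepoints Ordered character vector of admissible time-point
#'   labels; defaults to [default_timepoints()].
#' @return Validated data.frame; `timepoint` becomes an ordered factor.
#' @export
sample_metadata <- function(df, timepoints = default_timepoints()) {
  required <- c("sample_id", "host", "pair_id", "timepoint")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata")
  }
  bad_tp <- setdiff(unique(df$timepoint), timepoints)
  if (length(bad_tp) > 0) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "),
         " (expected one of: ", paste(timepoints, collapse = ", "), ")")
  }
  key <- paste(df$host, df$pair_id, df$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop("duplicate (host, pair_id, timepoint) combination: ",
         paste(dup$host[1], dup$pair_id[1], dup$timepoint[1], sep = "/"))
  }
  df$timepoint <- factor(df$timepoint, levels = timepoints, ordered = TRUE)
  rownames(df) <- df$sample_id
  df
}

#' Convert counts to within-sample relative abundances
#'
#' Divides each sample's counts by its total so that every row sums to one.
#' Relative abundance is the unit in which the shared-ASV threshold and all
#' genus summaries are expressed.
#'
#' @param table Feature table (samples x ASVs count matrix).
#' @return Numeric matrix of proportions with the same dimnames.
#' @export
relative_abundance <- function(table) {
  totals <- rowSums(table)
  zero <- totals == 0
  if (any(zero)) {
    stop("sample(s) with zero total count: ",
         paste(rownames(table)[zero], collapse = ", "))
  }
  rel <- unclass(table) / totals
  storage.mode(rel) <- "double"
  rel
}

# internal: sanity-check a relative-abundance matrix
.check_rel_abund <- function(rel, tol = 1e-9) {
  stopifnot(is.matrix(rel), !is.null(rownames(rel)), !is.null(colnames(rel)))
  if (any(rel < -tol) || any(rel > 1 + tol)) {
    stop("relative abundances must lie in [0, 1]")
  }
  if (any(abs(rowSums(rel) - 1) > 1e-6)) {
    stop("relative-abundance rows must sum to 1")
  }
  invisible(TRUE)
}

#' Extract the genus of each ASV from a taxonomy map
#'
#' @param taxonomy Taxonomy data.frame as returned by [read_taxonomy()] or
#'   [parse_lineage()].
#' @param asv_ids ASV identifiers to look up.
#' @return Character vector of genus names; `NA` where the lineage stops
#'   above genus or the ASV is absent from the map.
#' @export
taxonomy_genus <- function(taxonomy, asv_ids) {
  idx <- match(asv_ids, taxonomy$asv_id)
  taxonomy$genus[idx]
}

#' Parse semicolon-delimited lineage strings into ranked columns
#'
#' Accepts QIIME-style lineages (`d__Bacteria; p__Firmicutes; ...`) or bare
#' rank names.  Single-letter rank prefixes (`d__`, `p__`, ...) are
#' stripped; absent or empty ranks become `NA`.
#'
#' @param asv_id Character vector of ASV identifiers.
#' @param lineage Character vector of lineage strings, parallel to
#'   `asv_id`.
#' @return Data frame with columns `asv_id`, `lineage`, and one column per
#'   rank from domain to genus.
#' @export
parse_lineage <- function(asv_id, lineage) {
  if (anyDuplicated(asv_id)) {
    stop("duplicate asv_id in taxonomy")
  }
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  ranks <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-zA-Z]__", "", p)
    p[p == ""] <- NA_character_
    length(p) <- length(.tax_ranks)
    p
  }, character(length(.tax_ranks))))
  out <- data.frame(asv_id = as.character(asv_id),
                    lineage = as.character(lineage),
                    stringsAsFactors = FALSE)
  for (i in seq_along(.tax_ranks)) out[[.tax_ranks[i]]] <- ranks[, i]
  out
}

# internal: run code under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.  All stochastic operations in
# the package route through this so that a seed argument never clobbers
# the user's session RNG.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
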