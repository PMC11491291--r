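# Readers and writers for the four plain-text input formats: TSV count
# table, TSV metadata, TSV taxonomy, newick tree.  All TSV readers use
# UTF-8, tab delimiters, and ignore lines starting with "#".  Writers emit
# the same dialect so that write -> read is an identity.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8", colClasses = "character")
}

#' Read an ASV count table from TSV
#'
#' The file has a header row and one identifier column first.  By default
#' rows are ASVs and columns are samples (the QIIME feature-table export
#' convention); set `rows = "samples"` for the transposed dialect.  The
#' returned table is always oriented samples x ASVs.
#'
#' @param path Path to a tab-separated file.
#' @param rows Either `"asvs"` (default) or `"samples"`: what the file's
#'   rows represent.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, rows = c("asvs", "samples")) {
  rows <- match.arg(rows)
  df <- .read_tsv(path)
  if (ncol(df) < 2) {
    stop("feature table needs an identifier column plus at least one data column")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in first column of ", path)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  if (anyNA(num)) {
    stop("non-numeric count cell in ", path)
  }
  dimnames(num) <- list(ids, colnames(mat))
  if (rows == "asvs") num <- t(num)
  feature_table(num)
}

#' Write an ASV count table to TSV
#'
#' @param table Feature table (samples x ASVs).
#' @param path Output path.
#' @param rows Orientation of the written file; default ASVs in rows.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, rows = c("asvs", "samples")) {
  rows <- match.arg(rows)
  mat <- unclass(table)
  id_col <- "asv_id"
  if (rows == "asvs") mat <- t(mat) else id_col <- "sample_id"
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `host`, `pair_id`, `timepoint`.  Time-point
#' labels are validated against the configured ordered set.
#'
#' @param path Path to a tab-separated file.
#' @param timepoints Ordered admissible time-point labels.
#' @return Validated metadata data.frame (see [sample_metadata()]).
#' @export
read_metadata <- function(path, timepoints = default_timepoints()) {
  sample_metadata(.read_tsv(path), timepoints = timepoints)
}

#' Write sample metadata to TSV
#'
#' @param metadata Metadata data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(metadata, path) {
  df <- metadata[, c("sample_id", "host", "pair_id", "timepoint")]
  df$timepoint <- as.character(df$timepoint)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxonomy map from TSV
#'
#' Accepts two-column files with headers `asv_id`/`lineage` or the QIIME
#' export headers `Feature ID`/`Taxon`.  Lineages are semicolon-delimited
#' rank strings; see [parse_lineage()].
#'
#' @param path Path to a tab-separated file.
#' @return Taxonomy data.frame with parsed rank columns.  An empty file
#'   (header only) yields an empty, valid map.
#' @export
read_taxonomy <- function(path) {
  df <- .read_tsv(path)
  nm <- tolower(gsub("[ _]", "", names(df)))
  id_col <- match(TRUE, nm %in% c("asvid", "featureid", "otuid"))
  lin_col <- match(TRUE, nm %in% c("lineage", "taxon", "taxonomy"))
  if (is.na(id_col) || is.na(lin_col)) {
    stop("taxonomy file must have asv_id and lineage (or Feature ID / Taxon) columns")
  }
  parse_lineage(df[[id_col]], df[[lin_col]])
}

#' Write a taxonomy map to TSV
#'
#' @param taxonomy Taxonomy data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- taxonomy[, c("asv_id", "lineage")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Tip labels are ASV identifiers and must be unique.  Edges with no
#' length in the file are assigned length 0 with a warning, so that the
#' tree remains usable for weighted UniFrac without inventing lengths.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse newick file ",
                                            path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse newick file ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("tree has missing branch lengths; set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths")
  }
  tree
}

#' Write a phylogeny to a newick file
#'
#' Branch lengths are written with 17 significant digits so that a
#' write/read round trip reproduces them exactly.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}
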