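# End-to-end orchestration: simulate (optional) -> preprocess ->
# diversity -> shared ASVs -> ANCOM, with every stage's outputs written
# as TSV and a key-value report for reproducibility.

#' Pipeline configuration
#'
#' Either point at the four on-disk inputs (count table, metadata,
#' taxonomy, newick tree) or supply a `simulate` block, in which case a
#' synthetic cohort is generated and written first.
#'
#' @param feature_table,metadata,taxonomy,tree Paths to the input files
#'   (ignored when `simulate` is given).
#' @param simulate Optional [cohort_config()]; when supplied, inputs are
#'   generated rather than read.
#' @param out_dir Output directory.
#' @param timepoints Ordered time-point labels.
#' @param exclude Taxonomy patterns to drop (see [exclude_taxa()]).
#' @param threshold,one_sided Shared-ASV options (see [shared_config()]).
#' @param normalized_unifrac Use normalised weighted UniFrac.
#' @param shannon_base Logarithm base for Shannon diversity.
#' @param n_perm PERMANOVA permutations (default 5000).
#' @param ancom_alpha,ancom_cutoff ANCOM options (see [ancom_w()]).
#' @param seed Seed for the permutation stream (and, with `simulate`,
#'   the default cohort seed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_table = NULL, metadata = NULL,
                            taxonomy = NULL, tree = NULL, simulate = NULL,
                            out_dir = tempfile("pairshare_"),
                            timepoints = default_timepoints(),
                            exclude = c("mitochondria", "chloroplast",
                                        "unassigned"),
                            threshold = 0.01, one_sided = FALSE,
                            normalized_unifrac = FALSE, shannon_base = 2,
                            n_perm = 5000, ancom_alpha = 0.05,
                            ancom_cutoff = 0.7, seed = 1) {
  if (is.null(simulate)) {
    paths <- c(feature_table = feature_table, metadata = metadata,
               taxonomy = taxonomy, tree = tree)
    if (length(paths) != 4) {
      stop("either all four input paths or a simulate block must be given")
    }
  } else {
    stopifnot(inherits(simulate, "cohort_config"))
  }
  structure(as.list(environment())[setdiff(ls(), "paths")],
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full paired-cohort analysis pipeline
#'
#' Stages: (1) load or simulate the inputs; (2) preprocess — taxonomy
#' exclusion, relative abundance, genus collapse; (3) diversity —
#' per-sample Shannon, weighted UniFrac distance matrix, PCoA,
#' PERMANOVA on host labels, within-pair distances per time point;
#' (4) shared-ASV detection with per-event trajectories; (5) ANCOM on
#' genus-collapsed counts.  All tables are written under
#' `config$out_dir`; a `report.txt` records input checksums, parameters
#' and headline numbers.  The same config and seed always reproduce the
#' same outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   report lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  inputs <- .stage("load", {
    if (!is.null(config$simulate)) {
      cohort <- generate_cohort(config$simulate)
      paths <- write_cohort(cohort, file.path(out, "inputs"))
      list(table = cohort$table, metadata = cohort$metadata,
           taxonomy = cohort$taxonomy, tree_path = paths[["tree"]],
           paths = paths)
    } else {
      paths <- c(feature_table = config$feature_table,
                 metadata = config$metadata, taxonomy = config$taxonomy,
                 tree = config$tree)
      for (p in paths[c("feature_table", "metadata", "taxonomy")]) {
        if (!file.exists(p)) stop("input file not found: ", p)
      }
      list(table = read_feature_table(paths[["feature_table"]]),
           metadata = read_metadata(paths[["metadata"]],
                                    timepoints = config$timepoints),
           taxonomy = read_taxonomy(paths[["taxonomy"]]),
           tree_path = paths[["tree"]], paths = paths)
    }
  })

  pre <- .stage("preprocess", {
    filtered <- exclude_taxa(inputs$table, inputs$taxonomy,
                             patterns = config$exclude)
    md <- inputs$metadata[inputs$metadata$sample_id %in% rownames(filtered), ,
                          drop = FALSE]
    rel <- relative_abundance(filtered)
    genus <- collapse_to_genus(rel, inputs$taxonomy)
    write_feature_table(filtered, file.path(out, "filtered_table.tsv"))
    .write_tsv(data.frame(sample_id = rownames(genus), genus,
                          check.names = FALSE),
               file.path(out, "genus_table.tsv"))
    list(table = filtered, metadata = md, rel = rel, genus = genus)
  })

  div <- .stage("diversity", {
    tree <- read_tree(inputs$tree_path)
    dm <- distance_matrix(pre$rel, tree,
                          normalized = config$normalized_unifrac)
    ord <- pcoa(dm)
    alpha <- apply(unclass(pre$table), 1, shannon,
                   base = config$shannon_base)
    perm <- permanova(dm, pre$metadata[rownames(dm), "host"],
                      n_perm = config$n_perm, seed = config$seed)
    within_pair <- lapply(levels(pre$metadata$timepoint), function(tp) {
      pd <- suppressMessages(pair_distances(dm, pre$metadata, tp))
      if (length(pd$distances) == 0) return(NULL)
      data.frame(timepoint = tp, pair_id = names(pd$distances),
                 distance = unname(pd$distances), stringsAsFactors = FALSE)
    })
    within_pair <- do.call(rbind, within_pair)
    .write_tsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
               file.path(out, "distance_matrix.tsv"))
    .write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                          ord$coordinates, check.names = FALSE),
               file.path(out, "pcoa_coordinates.tsv"))
    .write_tsv(data.frame(sample_id = names(alpha), shannon = alpha),
               file.path(out, "shannon.tsv"))
    if (!is.null(within_pair)) {
      .write_tsv(within_pair, file.path(out, "within_pair_distances.tsv"))
    }
    list(dm = dm, ordination = ord, shannon = alpha, permanova = perm,
         within_pair = within_pair)
  })

  shared <- .stage("shared", {
    cfg <- shared_config(threshold = config$threshold,
                         one_sided = config$one_sided)
    res <- shared_asv_summary(pre$rel, pre$metadata, cfg, inputs$taxonomy)
    .write_tsv(res$events, file.path(out, "shared_events.tsv"))
    .write_tsv(res$summary, file.path(out, "shared_summary.tsv"))
    traj_keys <- unique(res$events[, c("asv_id", "pair_id")])
    traj <- do.call(rbind, lapply(seq_len(nrow(traj_keys)), function(i) {
      tr <- asv_trajectory(pre$rel, pre$metadata, traj_keys$asv_id[i],
                           traj_keys$pair_id[i])
      cbind(asv_id = traj_keys$asv_id[i], pair_id = traj_keys$pair_id[i], tr)
    }))
    if (is.null(traj)) {
      traj <- data.frame(asv_id = character(), pair_id = character(),
                         timepoint = character(), stringsAsFactors = FALSE)
    }
    .write_tsv(traj, file.path(out, "trajectories.tsv"))
    c(res, list(trajectories = traj))
  })

  ancom <- .stage("ancom", {
    genus_counts <- collapse_to_genus(pre$table, inputs$taxonomy)
    res <- ancom_w(genus_counts, pre$metadata[rownames(genus_counts), "host"],
                   alpha = config$ancom_alpha,
                   cutoff_fraction = config$ancom_cutoff)
    .write_tsv(res, file.path(out, "ancom.tsv"))
    res
  })

  report <- .stage("report", {
    on_disk <- inputs$paths[file.exists(inputs$paths)]
    lines <- c(
      "# pairshare pipeline report",
      sprintf("seed\t%d", config$seed),
      sprintf("threshold\t%g", config$threshold),
      sprintf("n_perm\t%d", config$n_perm),
      sprintf("normalized_unifrac\t%s", config$normalized_unifrac),
      sprintf("input_md5\t%s\t%s", names(on_disk),
              unname(tools::md5sum(on_disk))),
      sprintf("n_samples\t%d", nrow(pre$table)),
      sprintf("n_asvs_observed\t%d", total_asv_count(pre$table)),
      sprintf("n_shared_events\t%d", nrow(shared$events)),
      sprintf("permanova_host_F\t%.6g", div$permanova$pseudo_F),
      sprintf("permanova_host_p\t%.5f", div$permanova$p_value),
      sprintf("ancom_detected\t%s",
              paste(ancom$taxon[ancom$detected], collapse = ",")))
    writeLines(lines, file.path(out, "report.txt"))
    lines
  })

  invisible(list(inputs = inputs, preprocess = pre, diversity = div,
                 shared = shared, ancom = ancom, report = report,
                 out_dir = out))
}
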