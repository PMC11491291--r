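# Synthetic paired-host cohort generator.
#
# Emulates the structure of a paired human-dog longitudinal 16S survey:
# two host types with largely distinct genus pools, a small number of
# genera abundant in both, multiple cohabiting pairs sampled at matched
# time points, and rare "transfer" events in which one ASV appears above
# the shared-ASV detection threshold in both members of a pair from an
# onset time point onward.  Because every transfer is logged, downstream
# detection can be scored against ground truth.

.human_genera <- c("Bifidobacterium", "Bacteroides", "Faecalibacterium",
                   "Fusicatenibacter", "Prevotella", "Roseburia",
                   "Anaerostipes", "Agathobacter", "Dorea", "Alistipes",
                   "Parabacteroides", "Akkermansia")
.dog_genera <- c("Peptoclostridium", "Fusobacterium",
                 "Ruminococcus_gnavus_group", "Megamonas", "Sutterella",
                 "Collinsella", "Lactobacillus", "Turicibacter",
                 "Allobaculum", "Catenibacterium", "Helicobacter",
                 "Clostridium_sensu_stricto_1")
.shared_genera <- c("Blautia", "Streptococcus", "Enterococcus",
                    "Escherichia_Shigella")

.take_names <- function(pool, n, prefix) {
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, sprintf("%s_genus_%02d", prefix, seq_len(n - length(pool))))
}

#' Configuration for a synthetic paired-host cohort
#'
#' Defaults mirror the cohabitation study design the generator emulates:
#' 28 human-dog pairs sampled at four time points (pre-adoption, second
#' week, first month, third month), around 20,000 reads per sample, host
#' communities drawn from mostly disjoint genus pools with two genera
#' abundant in both hosts.
#'
#' @param n_pairs Number of cohabiting pairs (default 28).
#' @param timepoints Ordered time-point labels (default
#'   [default_timepoints()]).
#' @param hosts Two host labels; the first is "host 1" in outputs.
#' @param n_genera Genera per host community, including shared genera
#'   (default 10).
#' @param asvs_per_genus ASVs per genus (default 5).
#' @param overlap_genera Number of genera abundant in both hosts
#'   (default 2, emulating e.g. Blautia and Streptococcus).
#' @param overlap_boost Multiplier on the base weight of shared genera so
#'   that they rank among the abundant genera of both hosts (default 3).
#' @param depth Sequencing depth: reads per sample (default 20000).
#' @param genus_sigma Log-normal sd of between-genus base weights
#'   (default 1).
#' @param asv_sigma Log-normal sd of within-genus ASV weights (default 1).
#' @param lognormal_sigma Per-sample log-normal jitter sd applied to the
#'   host base profile before renormalisation (default 0.3).
#' @param n_transfers Number of injected transfer events (default 5).
#' @param transfer_abundance Length-2 range from which each event's
#'   injected relative abundance is drawn uniformly (default 0.02-0.08;
#'   must exceed the downstream detection threshold for recovery to be
#'   well-posed).
#' @param transfer_decay If `TRUE` a transferred ASV is present only at
#'   its onset time point; if `FALSE` (default) it persists at the
#'   injected level at all later time points.
#' @param seed Master seed; all stochastic draws derive from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 28,
                          timepoints = default_timepoints(),
                          hosts = c("human", "dog"),
                          n_genera = 10,
                          asvs_per_genus = 5,
                          overlap_genera = 2,
                          overlap_boost = 3,
                          depth = 20000,
                          genus_sigma = 1,
                          asv_sigma = 1,
                          lognormal_sigma = 0.3,
                          n_transfers = 5,
                          transfer_abundance = c(0.02, 0.08),
                          transfer_decay = FALSE,
                          seed = 1) {
  stopifnot(n_pairs >= 1, depth >= 1, length(hosts) == 2,
            length(timepoints) >= 1, n_genera >= 1, asvs_per_genus >= 1,
            overlap_genera >= 0, overlap_genera <= n_genera,
            length(transfer_abundance) == 2,
            transfer_abundance[1] <= transfer_abundance[2],
            transfer_abundance[1] > 0, transfer_abundance[2] < 1,
            n_transfers >= 0)
  if (n_transfers > 0 && n_genera == overlap_genera) {
    stop("transfer events need at least one host-exclusive genus")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a random rooted phylogeny with monophyletic ASV pools
#'
#' Each pool (e.g. the human-exclusive, dog-exclusive and shared ASV sets)
#' becomes a monophyletic clade; within a clade the topology is a random
#' bifurcating tree.  Branch lengths are i.i.d. exponential with mean 0.1,
#' so host-exclusive communities sit on disjoint subtrees and weighted
#' UniFrac separates hosts.
#'
#' @param asv_pools Named list of character vectors of ASV ids (tips);
#'   pools may not overlap.  A pool with a single member attaches directly
#'   under the root.
#' @param seed Optional seed.
#' @param branch_mean Mean of the exponential branch-length distribution.
#' @return An [ape::phylo] object with `length(unlist(asv_pools))` tips.
#' @export
generate_tree <- function(asv_pools, seed = NULL, branch_mean = 0.1) {
  asv_pools <- Filter(length, asv_pools)
  tips <- unlist(asv_pools, use.names = FALSE)
  if (length(tips) < 2) stop("need at least 2 tips to build a tree")
  if (anyDuplicated(tips)) stop("ASV pools overlap")
  .with_seed(seed, {
    clade <- function(members) {
      if (length(members) == 1) {
        return(sprintf("%s:%.17g", members, stats::rexp(1, 1 / branch_mean)))
      }
      members <- sample(members)
      k <- sample.int(length(members) - 1, 1)
      sprintf("(%s,%s):%.17g", clade(members[seq_len(k)]),
              clade(members[-seq_len(k)]), stats::rexp(1, 1 / branch_mean))
    }
    children <- vapply(asv_pools, clade, character(1))
    newick <- if (length(children) == 1) {
      sprintf("%s;", children)
    } else {
      sprintf("(%s);", paste(children, collapse = ","))
    }
    ape::read.tree(text = newick)
  })
}

# internal: draw per-host base profiles over the full ASV set
.base_profiles <- function(cfg, asv_host, asv_genus, genera) {
  hosts <- cfg$hosts
  profiles <- matrix(0, nrow = 2, ncol = length(asv_host),
                     dimnames = list(hosts, names(asv_host)))
  for (h in 1:2) {
    own <- asv_host %in% c(hosts[h], "both")
    own_genera <- unique(asv_genus[own])
    gw <- stats::setNames(stats::rlnorm(length(own_genera), 0, cfg$genus_sigma),
                          own_genera)
    shared <- intersect(own_genera, genera$shared)
    gw[shared] <- gw[shared] * cfg$overlap_boost
    aw <- stats::rlnorm(sum(own), 0, cfg$asv_sigma)
    w <- gw[asv_genus[own]] * aw
    profiles[h, own] <- w / sum(w)
  }
  profiles
}

# internal: draw the transfer-event log
.draw_transfers <- function(cfg, asv_host) {
  if (cfg$n_transfers == 0 || length(cfg$timepoints) < 2) {
    return(data.frame(asv_id = character(), pair_id = character(),
                      donor_host = character(), onset_timepoint = character(),
                      injected_relative_abundance = numeric(),
                      stringsAsFactors = FALSE))
  }
  pairs <- sprintf("Pair_%02d", seq_len(cfg$n_pairs))
  donors <- sample(cfg$hosts, cfg$n_transfers, replace = TRUE)
  candidates <- lapply(cfg$hosts, function(h) names(asv_host)[asv_host == h])
  names(candidates) <- cfg$hosts
  asvs <- character(cfg$n_transfers)
  for (i in seq_len(cfg$n_transfers)) {
    avail <- setdiff(candidates[[donors[i]]], asvs)
    if (length(avail) == 0) stop("not enough host-exclusive ASVs for transfers")
    asvs[i] <- avail[sample.int(length(avail), 1)]
  }
  onsets <- sample(cfg$timepoints[-1], cfg$n_transfers, replace = TRUE)
  data.frame(asv_id = asvs,
             pair_id = sample(pairs, cfg$n_transfers, replace = TRUE),
             donor_host = donors,
             onset_timepoint = onsets,
             injected_relative_abundance = stats::runif(
               cfg$n_transfers, cfg$transfer_abundance[1],
               cfg$transfer_abundance[2]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic paired-host cohort with known transfer events
#'
#' Builds host-specific log-normal genus/ASV profiles, injects the
#' configured transfer events into the expected proportions of both
#' members of the affected pair from the onset time point onward
#' (renormalising the remainder), and draws read counts multinomially at
#' the configured depth.  The same seed always yields byte-identical
#' outputs.
#'
#' Stream splitting: the master seed seeds R's RNG once, from which four
#' stage seeds (profiles, transfers, tree, counts) are drawn; each stage
#' then reseeds independently.  Adding draws to one stage therefore never
#' perturbs another.
#'
#' @param config A [cohort_config()].
#' @return A list of class `paired_cohort` with elements `table`
#'   (feature table), `metadata`, `taxonomy`, `tree`, `truth` and
#'   `config`.  `truth` holds the transfer-event log (`events`), the
#'   host assignment of every ASV (`asv_host`), the genus pools, and the
#'   noiseless expected proportion matrix (`expected`) — the
#'   infinite-depth limit against which detection can be scored.
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "cohort_config"))
  .with_seed(cfg$seed, {
    stage_seeds <- sample.int(.Machine$integer.max, 4)

    n_excl <- cfg$n_genera - cfg$overlap_genera
    genera <- list(
      host1 = .take_names(.human_genera, n_excl, cfg$hosts[1]),
      host2 = .take_names(.dog_genera, n_excl, cfg$hosts[2]),
      shared = .take_names(.shared_genera, cfg$overlap_genera, "shared"))
    all_genera <- c(genera$host1, genera$host2, genera$shared)
    genus_host <- rep(c(cfg$hosts[1], cfg$hosts[2], "both"),
                      times = lengths(genera))
    asv_genus <- rep(all_genera, each = cfg$asvs_per_genus)
    asv_ids <- sprintf("ASV_%04d", seq_along(asv_genus))
    names(asv_genus) <- asv_ids
    asv_host <- stats::setNames(rep(genus_host, each = cfg$asvs_per_genus),
                                asv_ids)

    set.seed(stage_seeds[1])
    profiles <- .base_profiles(cfg, asv_host, asv_genus, genera)

    set.seed(stage_seeds[2])
    events <- .draw_transfers(cfg, asv_host)

    set.seed(stage_seeds[3])
    pools <- list(names(asv_host)[asv_host == cfg$hosts[1]],
                  names(asv_host)[asv_host == cfg$hosts[2]],
                  names(asv_host)[asv_host == "both"])
    names(pools) <- c(cfg$hosts, "shared")
    tree <- generate_tree(pools)

    pairs <- sprintf("Pair_%02d", seq_len(cfg$n_pairs))
    grid <- expand.grid(timepoint = cfg$timepoints, pair_id = pairs,
                        host = cfg$hosts, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, c("host", "pair_id", "timepoint")]
    sample_ids <- paste(grid$host, grid$pair_id, grid$timepoint, sep = "_")

    tp_rank <- stats::setNames(seq_along(cfg$timepoints), cfg$timepoints)
    set.seed(stage_seeds[4])
    expected <- matrix(0, nrow = length(sample_ids), ncol = length(asv_ids),
                       dimnames = list(sample_ids, asv_ids))
    counts <- expected
    for (i in seq_along(sample_ids)) {
      base <- profiles[grid$host[i], ]
      jitter <- stats::rlnorm(length(base), 0, cfg$lognormal_sigma)
      p <- base * jitter
      p <- p / sum(p)
      if (nrow(events) > 0) {
        active <- events$pair_id == grid$pair_id[i] &
          (if (cfg$transfer_decay) {
            events$onset_timepoint == grid$timepoint[i]
          } else {
            tp_rank[events$onset_timepoint] <= tp_rank[grid$timepoint[i]]
          })
        if (any(active)) {
          inj <- events[active, , drop = FALSE]
          q <- tapply(inj$injected_relative_abundance, inj$asv_id, max)
          if (sum(q) >= 1) {
            stop("infeasible config: injected abundances sum to >= 1 in sample ",
                 sample_ids[i])
          }
          p[names(q)] <- 0
          p <- p / sum(p) * (1 - sum(q))
          p[names(q)] <- q
        }
      }
      expected[i, ] <- p
      counts[i, ] <- stats::rmultinom(1, cfg$depth, p)
    }

    metadata <- sample_metadata(
      data.frame(sample_id = sample_ids, grid, stringsAsFactors = FALSE),
      timepoints = cfg$timepoints)
    taxonomy <- parse_lineage(asv_ids, sprintf(
      "d__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__%s_family;g__%s",
      asv_genus, asv_genus))

    structure(list(
      table = feature_table(counts),
      metadata = metadata,
      taxonomy = taxonomy,
      tree = tree,
      truth = list(events = events, asv_host = asv_host,
                   genus_pools = genera, expected = expected),
      config = cfg), class = "paired_cohort")
  })
}

#' Write the four cohort input files plus the truth log
#'
#' Emits `feature_table.tsv`, `metadata.tsv`, `taxonomy.tsv`,
#' `tree.nwk` and `truth.tsv` into a directory, the on-disk form consumed
#' by [run_pipeline()] and the command-line interface.
#'
#' @param cohort A `paired_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    feature_table = file.path(dir, "feature_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.tsv"))
  write_feature_table(cohort$table, paths["feature_table"])
  write_metadata(cohort$metadata, paths["metadata"])
  write_taxonomy(cohort$taxonomy, paths["taxonomy"])
  write_tree(cohort$tree, paths["tree"])
  utils::write.table(cohort$truth$events, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
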