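# Shared fixtures and independent oracles used across the test files.
# All fixtures are generated in code under fixed seeds; nothing is read
# from disk.

# random count table, samples x ASVs
random_table <- function(n_samples = 4, n_asvs = 6, max_count = 50,
                         sparsity = 0.3) {
  counts <- matrix(rpois(n_samples * n_asvs, max_count / 2),
                   nrow = n_samples,
                   dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                   sprintf("ASV%03d", seq_len(n_asvs))))
  counts[matrix(runif(length(counts)) < sparsity, nrow = n_samples)] <- 0
  keep <- rowSums(counts) > 0
  counts[!keep, 1] <- 1L
  feature_table(counts)
}

# random relative-abundance matrix + complete paired metadata
random_paired_fixture <- function(n_pairs = 4, n_asvs = 10,
                                  timepoints = default_timepoints(),
                                  dropout = 0) {
  grid <- expand.grid(host = c("human", "dog"),
                      pair_id = sprintf("P%02d", seq_len(n_pairs)),
                      timepoint = timepoints, stringsAsFactors = FALSE)
  if (dropout > 0) grid <- grid[runif(nrow(grid)) > dropout, , drop = FALSE]
  grid$sample_id <- paste(grid$host, grid$pair_id, grid$timepoint, sep = "_")
  md <- sample_metadata(grid, timepoints = timepoints)
  rel <- matrix(rexp(nrow(grid) * n_asvs)^2, nrow = nrow(grid),
                dimnames = list(grid$sample_id,
                                sprintf("ASV%03d", seq_len(n_asvs))))
  rel <- rel / rowSums(rel)
  list(rel = rel, metadata = md)
}

# independent weighted-UniFrac oracle: explicit branch enumeration with
# recursive descendant-tip collection (no post-order accumulation)
oracle_unifrac <- function(a, b, tree) {
  n_tip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  total <- 0
  for (k in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc_tips(tree$edge[k, 2])]
    pa <- sum(a[intersect(tips, names(a))])
    pb <- sum(b[intersect(tips, names(b))])
    total <- total + tree$edge.length[k] * abs(pa - pb)
  }
  total
}

# brute-force shared-ASV oracle: double loop over every (ASV, pair,
# timepoint) combination with direct table lookups
oracle_shared_events <- function(rel, metadata, theta = 0.01) {
  hosts <- sort(unique(metadata$host))
  out <- list()
  for (asv in colnames(rel)) {
    for (pr in unique(metadata$pair_id)) {
      for (tp in levels(metadata$timepoint)) {
        s1 <- metadata$sample_id[metadata$pair_id == pr &
                                   metadata$timepoint == tp &
                                   metadata$host == hosts[1]]
        s2 <- metadata$sample_id[metadata$pair_id == pr &
                                   metadata$timepoint == tp &
                                   metadata$host == hosts[2]]
        if (length(s1) != 1 || length(s2) != 1) next
        if (rel[s1, asv] > theta && rel[s2, asv] > theta) {
          out[[length(out) + 1]] <- paste(asv, pr, tp)
        }
      }
    }
  }
  sort(unlist(out))
}

# a small random tree over given tip labels (single pool)
random_tip_tree <- function(tips, seed = NULL) {
  generate_tree(list(all = tips), seed = seed)
}
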