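# Weighted UniFrac.
#
# Raw weighted UniFrac between communities A and B is
#   d(A, B) = sum over branches b of  l_b * | P_A(b) - P_B(b) |,
# where l_b is the branch length and P_X(b) the fraction of community X's
# reads on tips descending from b.  Equivalently, with M the tips x
# branches incidence matrix, the branch-mass matrix is P = rel %*% M and
# d is the l-weighted Manhattan distance between rows of P; that matrix
# form is what distance_matrix() uses, so all pairwise distances cost one
# sparse-style accumulation plus a Manhattan distance.
#
# The normalised variant divides by sum_i (p_A,i + p_B,i) * h_i, the
# abundance-weighted root-to-tip depths, scaling distances into [0, 1].

# internal: per-branch descendant mass for each sample, plus root-to-tip
# depths.  Returns list(mass = samples x edges matrix, lengths, tipdepth).
.branch_mass <- function(rel, tree) {
  tips <- tree$tip.label
  extra <- colnames(rel)[colSums(rel) > 0 & !(colnames(rel) %in% tips)]
  if (length(extra) > 0) {
    stop("ASV(s) with non-zero abundance absent from tree: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  # accumulate node mass bottom-up in reverse post-order
  node_mass <- matrix(0, nrow = nrow(rel), ncol = n_node)
  present <- intersect(tips, colnames(rel))
  node_mass[, match(present, tips)] <- rel[, present, drop = FALSE]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    node_mass[, parent] <- node_mass[, parent] + node_mass[, child]
  }
  mass <- node_mass[, tree$edge[, 2], drop = FALSE]
  rownames(mass) <- rownames(rel)

  depth <- ape::node.depth.edgelength(tree)
  list(mass = mass, lengths = tree$edge.length,
       tipdepth = stats::setNames(depth[seq_len(n_tip)], tips))
}

#' Weighted UniFrac distance between two communities
#'
#' @param a,b Relative-abundance vectors named by ASV id (each summing
#'   to 1); every ASV with non-zero abundance must be a tip of `tree`.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param normalized If `TRUE`, divide by the abundance-weighted
#'   root-to-tip depth sum, scaling the distance into `[0, 1]`; the
#'   default is the raw (non-normalised) form.
#' @return Non-negative distance.
#' @export
weighted_unifrac <- function(a, b, tree, normalized = FALSE) {
  rel <- rbind(a, b)
  if (is.null(colnames(rel))) stop("abundance vectors must be named by ASV id")
  bm <- .branch_mass(rel, tree)
  d <- sum(bm$lengths * abs(bm$mass[1, ] - bm$mass[2, ]))
  if (normalized) {
    tips <- intersect(names(bm$tipdepth), colnames(rel))
    denom <- sum((rel[1, tips] + rel[2, tips]) * bm$tipdepth[tips])
    d <- if (denom > 0) d / denom else 0
  }
  d
}

#' All pairwise weighted UniFrac distances
#'
#' @param rel Relative-abundance matrix (samples x ASVs, rows sum to 1).
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param normalized Use the normalised variant (see
#'   [weighted_unifrac()]).
#' @return Symmetric distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
distance_matrix <- function(rel, tree, normalized = FALSE) {
  .check_rel_abund(rel)
  bm <- .branch_mass(rel, tree)
  weighted <- sweep(bm$mass, 2, bm$lengths, "*")
  d <- as.matrix(stats::dist(weighted, method = "manhattan"))
  if (normalized) {
    tips <- intersect(names(bm$tipdepth), colnames(rel))
    depth_mass <- drop(rel[, tips, drop = FALSE] %*% bm$tipdepth[tips])
    denom <- outer(depth_mass, depth_mass, "+")
    nz <- denom > 0
    d[nz] <- d[nz] / denom[nz]
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(rel), rownames(rel))
  d
}
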