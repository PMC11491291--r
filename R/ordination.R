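# Ordination (classical PCoA) and the PERMANOVA permutation test.

#' Principal coordinate analysis (classical metric MDS)
#'
#' Double-centres the squared distance matrix and eigendecomposes it
#' (via [stats::cmdscale()]); coordinates are eigenvectors scaled by the
#' square root of their eigenvalues.  Axes with non-positive eigenvalues
#' carry no coordinates but their eigenvalues are reported, so the
#' presence of negative eigenvalues (non-Euclidean distances) is
#' visible.
#'
#' @param dm Symmetric distance matrix with zero diagonal.
#' @return List with `coordinates` (samples x retained axes, columns
#'   `PC1`, `PC2`, ...), `eigenvalues` (all, decreasing), and
#'   `proportion_explained` (relative to the positive eigenvalue sum).
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(dm)
  res <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1,
                                          eig = TRUE))
  eig <- res$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)
  coords <- res$points[, seq_len(min(sum(pos), ncol(res$points))),
                       drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  rownames(coords) <- rownames(dm)
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = ifelse(eig > 0, eig / sum(eig[eig > 0]), 0))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor pseudo-F from distance sums of squares:
#' SS_total = sum_{i<j} d_ij^2 / N; SS_within = sum over groups g of
#' sum_{i<j in g} d_ij^2 / n_g; SS_between = SS_total - SS_within;
#' F = (SS_between / (g - 1)) / (SS_within / (N - g)).  Significance is
#' assessed by permuting group labels; the p-value uses the +1/+1
#' estimator p = (#{F_perm >= F_obs} + 1) / (n_perm + 1), whose smallest
#' achievable value with 5000 permutations is 1/5001 = 0.00020 (to five
#' decimals).
#'
#' @param dm Symmetric distance matrix.
#' @param labels Group label per sample (in `dm` row order).
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Optional seed for the permutation stream.
#' @return List of class `permanova` with `pseudo_F`, `p_value`,
#'   `n_permutations`, `group_labels`, and the sums of squares.
#' @export
permanova <- function(dm, labels, n_perm = 5000, seed = NULL) {
  dm <- as.matrix(dm)
  labels <- as.factor(labels)
  n <- nrow(dm)
  if (length(labels) != n) stop("one label per sample required")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("PERMANOVA needs at least two groups")
  if (any(sizes < 2)) {
    stop("every group needs at least 2 samples (offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  }
  d2 <- dm^2
  g <- length(sizes)
  ss_total <- sum(d2[upper.tri(d2)]) / n

  # SS_within for a label vector, via one quadratic form per group
  ss_within <- function(lab) {
    s <- 0
    for (lev in levels(labels)) {
      z <- as.numeric(lab == lev)
      s <- s + drop(crossprod(z, d2 %*% z)) / (2 * sum(z))
    }
    s
  }
  f_stat <- function(ssw) ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))

  f_obs <- f_stat(ss_within(labels))
  count <- 0L
  .with_seed(seed, {
    for (i in seq_len(n_perm)) {
      f_perm <- f_stat(ss_within(labels[sample.int(n)]))
      if (f_perm >= f_obs) count <- count + 1L
    }
  })
  structure(list(pseudo_F = f_obs,
                 p_value = (count + 1) / (n_perm + 1),
                 n_permutations = n_perm,
                 group_labels = levels(labels),
                 ss_total = ss_total,
                 ss_between = ss_total - ss_within(labels)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations) on groups: %s\n",
              x$n_permutations, paste(x$group_labels, collapse = ", ")))
  cat(sprintf("  pseudo-F = %.4f, p = %.5f\n", x$pseudo_F, x$p_value))
  invisible(x)
}
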