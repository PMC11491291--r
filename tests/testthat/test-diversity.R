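test_that("Shannon diversity matches closed forms and entropy bounds", {
  expect_equal(shannon(c(10, 10, 10, 10)), 2)
  expect_equal(shannon(42), 0)
  expect_equal(shannon(c(1, 1, 2)), 1.5)
  expect_equal(shannon(c(1, 1, 2), base = exp(1)), 1.5 * log(2))
  expect_error(shannon(c(0, 0)), "all-zero")
  set.seed(8)
  for (i in 1:10) {
    x <- rpois(6, 20) + 1
    h <- shannon(x)
    expect_gte(h, 0)
    expect_lte(h, log2(sum(x > 0)) + 1e-12)
    expect_equal(h, vegan::diversity(x, index = "shannon", base = 2))
  }
})

test_that("weighted UniFrac matches closed forms", {
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  a <- c(t1 = 1, t2 = 0, t3 = 0, t4 = 0)
  b <- c(t1 = 0, t2 = 1, t3 = 0, t4 = 0)
  expect_equal(weighted_unifrac(a, b, star), 2)
  expect_equal(weighted_unifrac(a, a, star), 0)
  # normalised variant of disjoint unit-depth samples is 1
  expect_equal(weighted_unifrac(a, b, star, normalized = TRUE), 1)
})

test_that("weighted UniFrac equals an independent branch-enumeration oracle", {
  set.seed(33)
  for (i in 1:10) {
    tips <- sprintf("t%d", 1:6)
    tree <- random_tip_tree(tips)
    a <- rexp(6); a <- a / sum(a); names(a) <- tips
    b <- rexp(6); b <- b / sum(b); names(b) <- tips
    expect_equal(weighted_unifrac(a, b, tree), oracle_unifrac(a, b, tree),
                 tolerance = 1e-12)
  }
})

test_that("raw weighted UniFrac agrees with the phyloseq reference", {
  skip_if_not_installed("phyloseq")
  set.seed(12)
  tips <- sprintf("t%d", 1:8)
  tree <- random_tip_tree(tips)
  rel <- matrix(rexp(4 * 8), nrow = 4,
                dimnames = list(paste0("s", 1:4), tips))
  rel <- rel / rowSums(rel)
  dm <- distance_matrix(rel, tree)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(rel, taxa_are_rows = FALSE),
    phyloseq::phy_tree(tree))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                     normalized = FALSE))
  expect_equal(dm, ref[rownames(dm), colnames(dm)], tolerance = 1e-10)
})

test_that("the distance matrix is consistent, metric, and validated", {
  set.seed(44)
  tips <- sprintf("t%d", 1:8)
  tree <- random_tip_tree(tips)
  rel <- matrix(rexp(30 * 8), nrow = 30,
                dimnames = list(paste0("s", 1:30), tips))
  rel <- rel / rowSums(rel)
  rel[2, ] <- rel[1, ]  # duplicate community
  dm <- distance_matrix(rel, tree)
  expect_equal(dm["s1", "s2"], 0)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  # pairwise calls agree with the matrix route
  for (pair in list(c(1, 3), c(5, 17), c(20, 30))) {
    expect_equal(dm[pair[1], pair[2]],
                 weighted_unifrac(rel[pair[1], ], rel[pair[2], ], tree),
                 tolerance = 1e-12)
  }
  # triangle inequality over 200 random triples
  for (i in 1:200) {
    ijk <- sample(30, 3)
    expect_lte(dm[ijk[1], ijk[2]],
               dm[ijk[1], ijk[3]] + dm[ijk[3], ijk[2]] + 1e-12)
  }
  # an abundant ASV missing from the tree is an error
  rel2 <- cbind(rel * 0.9, extra = 0.1)
  expect_error(distance_matrix(rel2, tree), "absent from tree")
})

test_that("PCoA reproduces Euclidean configurations and flags asymmetry", {
  # two points at distance d
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  res <- pcoa(d)
  expect_equal(ncol(res$coordinates), 1)
  expect_equal(unname(abs(diff(res$coordinates[, 1]))), 3)

  # three collinear points embed on one axis
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  res3 <- pcoa(d3)
  emb <- as.matrix(dist(res3$coordinates[, 1]))
  expect_equal(unname(emb), unname(d3), tolerance = 1e-10)
  expect_lt(res3$eigenvalues[2] / res3$eigenvalues[1], 1e-10)

  # exactly Euclidean distances are reproduced to 1e-8
  set.seed(6)
  pts <- matrix(rnorm(20), ncol = 2)
  dE <- as.matrix(dist(pts))
  dimnames(dE) <- list(paste0("p", 1:10), paste0("p", 1:10))
  resE <- pcoa(dE)
  expect_equal(as.matrix(dist(resE$coordinates)), dE,
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(diff(res3$eigenvalues) <= 1e-9))

  bad <- dE; bad[1, 2] <- bad[1, 2] + 1
  expect_error(pcoa(bad), "symmetric")
})

test_that("PERMANOVA pseudo-F matches hand-computed sums of squares", {
  d <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d["s1", "s2"] <- d["s2", "s1"] <- 1
  d["s3", "s4"] <- d["s4", "s3"] <- 2
  d["s1", "s3"] <- d["s3", "s1"] <- 5
  d["s1", "s4"] <- d["s4", "s1"] <- 6
  d["s2", "s3"] <- d["s3", "s2"] <- 7
  d["s2", "s4"] <- d["s4", "s2"] <- 4
  labels <- c("g1", "g1", "g2", "g2")
  # by hand: SS_total = (1+4+25+36+49+16)/4; SS_within = 1/2 + 4/2
  ss_total <- 131 / 4
  ss_within <- 0.5 + 2
  f_hand <- ((ss_total - ss_within) / 1) / (ss_within / 2)
  res <- permanova(d, labels, n_perm = 200, seed = 1)
  expect_equal(res$pseudo_F, f_hand)
  expect_gte(res$p_value, 1 / 201)

  # cross-check the statistic against vegan's adonis2
  set.seed(91)
  pts <- matrix(rnorm(40), ncol = 2)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("s", 1:20), paste0("s", 1:20))
  grp <- rep(c("a", "b"), each = 10)
  ours <- permanova(dm, grp, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(dm) ~ grp, permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)

  expect_error(permanova(dm, rep("a", 20)), "two groups")
  expect_error(permanova(dm, c("b", rep("a", 19))), "at least 2")
})

test_that("PERMANOVA p-values are uniform under a true null", {
  set.seed(7)
  pvals <- replicate(500, {
    pts <- matrix(rnorm(60), ncol = 5)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(paste0("s", 1:12), paste0("s", 1:12))
    permanova(dm, sample(rep(c("a", "b"), each = 6)), n_perm = 99)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Mann-Whitney switches between exact and approximate correctly", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)  # 2/20 assignments as extreme
  expect_equal(res$method, "exact")
  # symmetry in the two samples
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$p_value, 0.1)
  # identical samples: p = 1 under the tie-corrected approximation
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$method, "normal approximation")
  expect_gt(same$p_value, 0.95)
  # large samples use the approximation even without ties
  big <- mann_whitney_u(seq(0.1, 0.9, length.out = 9), seq(1, 9) + 0.05)
  expect_equal(big$method, "normal approximation")
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Benjamini-Hochberg q-values follow the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(9)
  p <- runif(25)
  q <- bh_fdr(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_true(all(q <= 1 & q >= p - 1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("within-pair distances pull the right entries and flag gaps", {
  set.seed(10)
  fx <- random_paired_fixture(n_pairs = 3, n_asvs = 6)
  tree <- random_tip_tree(colnames(fx$rel))
  dm <- distance_matrix(fx$rel, tree)
  pd <- pair_distances(dm, fx$metadata, "month1")
  expect_equal(length(pd$distances), 3)
  for (pr in names(pd$distances)) {
    expect_equal(pd$distances[[pr]],
                 dm[paste0("human_", pr, "_month1"),
                    paste0("dog_", pr, "_month1")])
  }
  # remove one dog sample: that pair is skipped and reported
  md2 <- fx$metadata[fx$metadata$sample_id != "dog_P02_month1", ]
  expect_message(pd2 <- pair_distances(dm, md2, "month1"), "P02")
  expect_equal(sort(names(pd2$distances)), c("P01", "P03"))
  expect_equal(pd2$incomplete, "P02")
})

test_that("subject shifts detect a planted dog-only perturbation", {
  n_pairs <- 20
  tips <- sprintf("t%d", 1:6)
  star <- ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), ");"))
  grid <- expand.grid(host = c("human", "dog"),
                      pair_id = sprintf("P%02d", 1:n_pairs),
                      timepoint = c("pre", "month1"),
                      stringsAsFactors = FALSE)
  grid$sample_id <- paste(grid$host, grid$pair_id, grid$timepoint, sep = "_")
  md <- sample_metadata(grid, timepoints = c("pre", "month1"))
  set.seed(14)
  base <- c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05)
  rel <- t(vapply(seq_len(nrow(grid)), function(i) {
    p <- base * exp(rnorm(6, 0, 0.05))
    if (grid$host[i] == "dog" && grid$timepoint[i] == "month1") {
      p <- rev(base) * exp(rnorm(6, 0, 0.05))  # strong community shift
    }
    p / sum(p)
  }, numeric(6)))
  dimnames(rel) <- list(grid$sample_id, tips)
  dm <- distance_matrix(rel, star)
  dog_shift <- subject_shift(dm, md, "dog", c("pre", "month1"))
  human_shift <- subject_shift(dm, md, "human", c("pre", "month1"))
  expect_equal(length(dog_shift), n_pairs)
  expect_lt(mann_whitney_u(dog_shift, human_shift)$p_value, 0.05)
  expect_gt(min(dog_shift), max(human_shift))

  # identical communities shift by zero; missing t1 drops the individual
  rel2 <- rel
  rel2["human_P01_month1", ] <- rel2["human_P01_pre", ]
  dm2 <- distance_matrix(rel2, star)
  expect_equal(unname(subject_shift(dm2, md, "human",
                                    c("pre", "month1"))["P01"]), 0)
  md3 <- md[md$sample_id != "dog_P01_pre", ]
  expect_false("P01" %in% names(subject_shift(dm, md3, "dog",
                                              c("pre", "month1"))))
})
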