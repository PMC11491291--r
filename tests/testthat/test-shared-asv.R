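test_that("presence sets apply a strict threshold by default", {
  rel <- matrix(c(0.5, 0.009, 0.491), nrow = 1,
                dimnames = list("s1", c("a", "b", "c")))
  expect_equal(presence_set(rel, "s1"), c("a", "c"))
  # exactly the threshold is excluded under "more than"
  rel2 <- matrix(c(0.01, 0.99), nrow = 1, dimnames = list("s1", c("a", "b")))
  expect_equal(presence_set(rel2, "s1"), "b")
  expect_equal(presence_set(rel2, "s1", shared_config(strict = FALSE)),
               c("a", "b"))
  expect_error(presence_set(rel, "nope"), "unknown sample")
  expect_error(shared_config(threshold = 0), "between 0 and 1")
  expect_error(shared_config(threshold = 1), "between 0 and 1")
})

test_that("pair sharing is the intersection of the members' presence sets", {
  tp <- default_timepoints()
  md <- sample_metadata(data.frame(
    sample_id = c("h1", "d1"), host = c("human", "dog"),
    pair_id = "P01", timepoint = "month1", stringsAsFactors = FALSE))
  rel <- rbind(
    h1 = c(a = 0.5, b = 0.3, c = 0.005, d = 0.195),
    d1 = c(a = 0.002, b = 0.4, c = 0.4, d = 0.198))
  res <- shared_asvs_for_pair(rel, md, "P01", "month1")
  expect_equal(res$asv_ids, c("b", "d"))
  expect_equal(res$status, "complete")
  # disjoint presence sets: empty but complete
  rel2 <- rbind(h1 = c(a = 0.99, b = 0.005, c = 0.005),
                d1 = c(a = 0.005, b = 0.99, c = 0.005))
  res2 <- shared_asvs_for_pair(rel2, md, "P01", "month1")
  expect_equal(length(res2$asv_ids), 0)
  expect_equal(res2$status, "complete")
  # a pair not sampled at the timepoint is incomplete, not empty
  res3 <- shared_asvs_for_pair(rel, md, "P01", "pre")
  expect_equal(res3$status, "incomplete")
})

test_that("detection equals the brute-force double loop on random fixtures", {
  set.seed(77)
  for (i in 1:10) {
    fx <- random_paired_fixture(n_pairs = sample(2:8, 1),
                                n_asvs = sample(5:30, 1),
                                dropout = 0.15)
    res <- shared_asv_summary(fx$rel, fx$metadata)
    got <- sort(paste(res$events$asv_id, res$events$pair_id,
                      res$events$timepoint))
    expect_identical(got, oracle_shared_events(fx$rel, fx$metadata))
    # summary counts distinct sharing pairs
    if (nrow(res$summary) > 0) {
      for (r in seq_len(nrow(res$summary))) {
        n <- sum(res$events$asv_id == res$summary$asv_id[r] &
                   res$events$timepoint == res$summary$timepoint[r])
        expect_equal(res$summary$n_pairs[r], n)
      }
    }
  }
})

test_that("raising the threshold never adds a shared event", {
  set.seed(55)
  fx <- random_paired_fixture(n_pairs = 5, n_asvs = 12)
  lo <- shared_asv_summary(fx$rel, fx$metadata, shared_config(0.01))
  hi <- shared_asv_summary(fx$rel, fx$metadata, shared_config(0.05))
  key <- function(ev) paste(ev$asv_id, ev$pair_id, ev$timepoint)
  expect_true(all(key(hi$events) %in% key(lo$events)))
})

test_that("event rows carry both members' abundances and the genus", {
  md <- sample_metadata(data.frame(
    sample_id = c("h1", "d1"), host = c("human", "dog"),
    pair_id = "P01", timepoint = "month1", stringsAsFactors = FALSE))
  rel <- rbind(h1 = c(a = 0.7, b = 0.3), d1 = c(a = 0.2, b = 0.8))
  tax <- parse_lineage(c("a", "b"),
                       c("d__B;p__F;c__C;o__O;f__F;g__Blautia",
                         "d__B;p__F;c__C;o__O;f__F;g__Streptococcus"))
  res <- shared_asv_summary(rel, md, taxonomy = tax)
  expect_equal(nrow(res$events), 2)
  idx <- match("a", res$events$asv_id)
  # host1/host2 follow the sorted host labels (dog, human)
  expect_equal(res$events$rel_abund_host1[idx], 0.2)
  expect_equal(res$events$rel_abund_host2[idx], 0.7)
  expect_equal(res$events$genus[idx], "Blautia")
  expect_equal(res$hosts, c("dog", "human"))
})

test_that("incomplete pairs are reported, never silently zero", {
  set.seed(31)
  fx <- random_paired_fixture(n_pairs = 3)
  md <- fx$metadata[fx$metadata$sample_id != "dog_P02_month1", ]
  res <- shared_asv_summary(fx$rel, md)
  expect_true(any(res$incomplete$pair_id == "P02" &
                    res$incomplete$timepoint == "month1"))
})

test_that("trajectories mirror direct table lookups and mark missingness", {
  set.seed(41)
  fx <- random_paired_fixture(n_pairs = 2)
  tr <- asv_trajectory(fx$rel, fx$metadata, "ASV001", "P01")
  expect_equal(tr$timepoint, default_timepoints())
  for (i in seq_len(nrow(tr))) {
    expect_equal(tr$human[i],
                 fx$rel[paste0("human_P01_", tr$timepoint[i]), "ASV001"])
  }
  md <- fx$metadata[fx$metadata$sample_id != "dog_P01_pre", ]
  tr2 <- asv_trajectory(fx$rel, md, "ASV001", "P01")
  expect_true(is.na(tr2$dog[tr2$timepoint == "pre"]))
  expect_error(asv_trajectory(fx$rel, fx$metadata, "nope", "P01"),
               "unknown ASV")
  expect_error(asv_trajectory(fx$rel, fx$metadata, "ASV001", "nope"),
               "unknown pair")
})

test_that("an injected persistent transfer shows the expected trajectory", {
  co <- generate_cohort(cohort_config(n_pairs = 6, n_genera = 5,
                                      asvs_per_genus = 3, overlap_genera = 1,
                                      n_transfers = 3, seed = 19))
  tr_events <- co$truth$events
  tp <- co$config$timepoints
  for (i in seq_len(nrow(tr_events))) {
    traj <- asv_trajectory(co$truth$expected, co$metadata,
                           tr_events$asv_id[i], tr_events$pair_id[i])
    onset <- match(tr_events$onset_timepoint[i], tp)
    recipient <- setdiff(co$config$hosts,
                         co$truth$asv_host[tr_events$asv_id[i]])
    after <- traj[[recipient]][seq(onset, length(tp))]
    before <- traj[[recipient]][seq_len(onset - 1)]
    expect_true(all(after > 0.01))
    expect_true(all(before == 0))
  }
})

test_that("total ASV count ignores all-zero columns and never grows on filtering", {
  ft <- feature_table(matrix(c(1, 0, 2, 0, 0, 0), nrow = 2,
                             dimnames = list(c("s1", "s2"),
                                             c("a", "b", "c"))))
  expect_equal(total_asv_count(ft), 2)
  tax <- parse_lineage(c("a", "b", "c"),
                       c("d__B;p__F;c__C;o__O;f__Mitochondria",
                         "d__B;p__F;c__C;o__O;f__F;g__G",
                         "d__B;p__F;c__C;o__O;f__F;g__H"))
  expect_lte(total_asv_count(exclude_taxa(ft, tax)), total_asv_count(ft))
  co <- generate_cohort(cohort_config(n_pairs = 3, n_genera = 4,
                                      asvs_per_genus = 2, overlap_genera = 1,
                                      n_transfers = 0, seed = 4))
  expect_equal(sum(colSums(co$truth$expected) > 0), ncol(co$table))
  expect_lte(total_asv_count(co$table), ncol(co$table))
})
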