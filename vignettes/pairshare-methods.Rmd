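---
title: "pairshare: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pairshare: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairshare)
```

`pairshare` analyses paired-host longitudinal amplicon surveys: two
host species (say humans and dogs) living in pairs, each pair sampled
at matched time points, with the question of whether exact sequence
variants move between the members of a pair.  This vignette explains
each statistical component, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
design decisions taken where more than one reasonable convention
exists.

## The shared-ASV rule

The core call is deliberately simple.  Let `p[s, a]` be the relative
abundance of ASV `a` in sample `s` (counts divided by the sample
total, computed *after* taxonomy-based exclusion).  ASV `a` is shared
within pair `k` at time point `t` when

```
p[s1, a] > θ   and   p[s2, a] > θ
```

where `s1`, `s2` are the two members' samples at `t` and θ is the
*p-percentage* threshold, default 0.01.  Three conventions are fixed
here and exposed as options:

* **Strict inequality.** "More than 1%" is read as `>`, so an
  abundance of exactly θ does not count (`strict = FALSE` flips this).
  The threshold exists to screen out low-abundance noise — reads that
  could plausibly arise from index hopping, contamination or
  mis-assignment — so the boundary case is treated conservatively.
* **Both members must pass.** Requiring the threshold in only one
  member (with mere presence in the other) is available as
  `one_sided = TRUE`, but the symmetric rule is the default: it is the
  conservative reading and makes the call independent of which host is
  assumed to be the donor.
* **Matched time points only.** Cross-time-point carryover (an ASV
  abundant in the dog at month 1 and in the human at month 3) is
  visible in `asv_trajectory()` output but is never counted as a
  shared event by the detector.

A pair not sampled completely at a time point yields a record flagged
`incomplete`, which downstream summaries report separately — with
longitudinal dropout, a silent zero would be indistinguishable from a
genuinely empty intersection.

No prevalence or frequency filter is applied beyond the θ rule itself.

## Diversity components

**Shannon diversity** uses base-2 logarithms (bits) by default, the
common convention of amplicon pipelines; `base = exp(1)` gives nats.
The index is the entropy of the within-sample relative-abundance
vector, so `0 ≤ H ≤ log2(k)` for `k` observed ASVs, with the maximum
attained exactly at evenness — both bounds are property-tested.

**Weighted UniFrac** is implemented in its raw (non-normalised) form

```
d(A, B) = Σ_b  l_b · | P_A(b) − P_B(b) |
```

with `l_b` the branch length and `P_X(b)` the fraction of community
X's reads on tips descending from branch `b`.  The matrix routine
computes branch masses for all samples in one post-order accumulation
and takes branch-length-weighted Manhattan distances between rows,
which is algebraically identical to the per-pair sum; the tests verify
it against an independent branch-enumeration oracle and against
`phyloseq::UniFrac`.  Raw weighted UniFrac is the default because it
is the default of the pipeline family these surveys typically use; the
`normalized = TRUE` variant divides by the abundance-weighted
root-to-tip depth sum `Σ_i (p_A,i + p_B,i) h_i`, scaling into [0, 1].
An ASV with non-zero abundance but no tip in the tree is an error, not
a silent drop.

**PCoA** is classical metric scaling: double-centre `−½ J D² J`,
eigendecompose, scale eigenvectors by the square root of their
eigenvalues.  Negative eigenvalues (non-Euclidean distance matrices)
carry no coordinates but are reported, so their magnitude can be
inspected.  On exactly Euclidean inputs the embedding reproduces the
distances to 1e−8, which is asserted in the tests.

**PERMANOVA** uses the one-factor pseudo-F from distance sums of
squares (`SS_total = Σ_{i<j} d²_ij / N`, `SS_within` summed per group
with the analogous `1/n_g` scaling) and a label-permutation null with
the +1/+1 estimator `p = (#{F* ≥ F} + 1)/(B + 1)`.  The estimator
never returns 0; with the conventional `B = 5000` its floor is
`1/5001 ≈ 0.00020`, which is what a completely host-separated cohort
reports.  Type-I calibration (rejection rate 0.05 ± 0.02 under a
permuted-label null) and uniformity of the null p-value distribution
are both tested by simulation.

**Mann–Whitney U** is exact by enumeration when both groups have ≤ 8
observations and no ties (the crossover is configurable), otherwise
the normal approximation with tie and continuity correction.
**Benjamini–Hochberg** q-values are computed per declared family of
comparisons — e.g. the set of time-point contrasts of one figure panel
— rather than globally; family membership is whatever set of p-values
the caller passes in one `bh_fdr()` call.

## ANCOM

Differential abundance between the two hosts uses the ANCOM W
statistic.  For each taxon `i`, every additive log-ratio
`log((c_i + 1)/(c_j + 1))`, `j ≠ i`, is compared between hosts with a
two-sided Mann–Whitney test; BH correction is applied across taxon
`i`'s `m − 1` tests; `W_i` counts the rejections at α = 0.05; taxon
`i` is flagged when `W_i ≥ 0.7 (m − 1)`.  Pseudocount 1, per-taxon
(not global) BH and the 0.7 cutoff follow the reference implementation
family of ANCOM; all three are arguments.  The pipeline applies ANCOM
to genus-collapsed counts over all samples — the taxonomic level at
which host-associated genera are naturally described — and this is an
explicit assumption rather than a mathematical necessity; `ancom_w()`
accepts any count matrix, so ASV-level or per-time-point runs are one
call away.  Because log-ratios are scale-free, W is invariant to
per-sample depth rescaling up to pseudocount effects (tested at large
counts), and under a permuted-label null the detection rate stays
below α (tested at 200 replicates).

## The synthetic cohort generator

No public per-sample truth exists for microbial transfer between
cohabiting hosts, so validation rests on simulation with known ground
truth.  The generator emulates the *structure* of such a survey:

* 28 pairs × 4 time points (`pre`, `week2`, `month1`, `month3`) × 2
  hosts, all configurable; sample depth 20,000 reads by default.
* Each host community draws from 10 genera × 5 ASVs.  Genus pools are
  host-exclusive except `overlap_genera = 2` genera present — and,
  via a ×3 base-weight boost, abundant — in both hosts, mirroring the
  observation that a couple of genera (e.g. *Blautia*,
  *Streptococcus*) dominate both the human and dog gut while most do
  not.  Synthetic genus names reuse familiar gut taxa for
  readability; they carry no biological content.
* Expected proportions are fixed log-normal host profiles
  (between-genus σ = 1, within-genus σ = 1) jittered per sample by a
  log-normal factor (σ = 0.3) and renormalised.  This Dirichlet-free
  construction keeps effect sizes explicit and makes the
  infinite-depth limit (`truth$expected`) available in closed form.
* Counts are multinomial at the configured depth, so generated rows
  sum to the depth exactly.
* The phylogeny places each host-exclusive pool and the shared pool
  in separate monophyletic clades with i.i.d. exponential branch
  lengths (mean 0.1), so host communities occupy disjoint subtrees
  and weighted UniFrac separates hosts by construction.

**Transfer events** are the recovery target.  Each event picks an ASV
from the donor host's exclusive pool, a pair, an onset time point
(never `pre`) and an injected relative abundance drawn uniformly from
0.02–0.08.  From the onset onward (persistent by default;
`transfer_decay = TRUE` restricts to the onset visit) the ASV's
expected proportion is set to the injected level **in both members of
the pair**, with the remainder of the profile renormalised.  Injecting
into both members is a deliberate choice: the detector requires the
threshold in both members, so an event injected only into the
recipient — leaving the donor's side at whatever its base profile
happens to give, possibly below θ — would not define a recoverable
truth.  The generator models the state *after* a successful
transfer (donor carries the strain abundantly, recipient has acquired
it), not the transmission process itself; the `donor_host` field is
bookkeeping, not an asymmetry of the injection.  A configuration whose
active injections in one sample sum to ≥ 1 is rejected as infeasible.

Reproducibility uses a documented stream-splitting scheme: the master
seed seeds R's generator once, four stage seeds (profiles, transfers,
tree, counts) are drawn from it, and each stage reseeds independently,
so extending one stage never perturbs the draws of another.  All
seed-taking functions restore the caller's RNG state.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: compositional correlations
beyond shared genus membership, PCR/chimera artefacts and index
hopping (the very noise θ exists to guard against), within-ASV strain
variation, gradual colonisation dynamics, longitudinal autocorrelation
beyond transfer persistence, and sample dropout (real surveys lose
samples; the generator emits complete grids, while the analysis
functions tolerate incompleteness).  Recovery rates measured here are
therefore upper bounds for field data.

## Numerical and interface choices

* Taxonomy exclusion matches patterns case-insensitively as
  substrings anywhere in the lineage; "unassigned" means no lineage
  entry or a domain-only lineage.  Defaults drop mitochondria,
  chloroplasts and unassigned ASVs.
* Rarefaction subsamples without replacement (multivariate
  hypergeometric, via `vegan::rrarefy`); samples below the target
  depth are dropped with a warning, never partially rarefied.  Curve
  evaluation defines depth 0 as diversity 0 and omits depths beyond a
  sample's total.
* Top-k genus summaries pick the k genera with the highest mean
  relative abundance across the host's samples, ties broken
  alphabetically; quartiles use R's default (type 7) definition.
* Table orientation: both ASVs-in-rows (QIIME export convention, the
  default) and samples-in-rows TSVs are accepted and written; the
  in-memory form is always samples × ASVs.  Newick branch lengths are
  written with 17 significant digits so round trips are exact; a
  branch with no length in the input is set to 0 with a warning
  rather than invented.
* How `pre` samples pair up is the caller's design decision:
  `pair_distances()` accepts any complete (pair, time point)
  combination, including pre-cohabitation visits where the "pair" is
  only prospective.

## Validation problem sizes

The test suite validates against independent oracles at sizes chosen
to make the checks sharp but cheap: brute-force shared-ASV
equivalence on 50 random fixtures (up to 50 ASVs × 20 pairs × 4 time
points), UniFrac branch-enumeration oracles on 6–8-tip trees,
PERMANOVA calibration at 500 null replicates of 20 samples with 199
permutations, ANCOM null calibration at 200 replicates of 10 taxa,
and transfer recovery over 100 simulated cohorts at depth 50,000 with
injected abundance ≥ 2% against θ = 1% (sensitivity ≥ 95% at onset,
zero host-exclusive false events in the noiseless limit).  The
permutation-floor check runs the full 224-sample, 5,000-permutation
PERMANOVA.

## Known limitations

Directionality (which host donated the strain) is out of scope — the
detector is symmetric and abundance asymmetries are only descriptive.
Sharing across *different* time points is reported but never counted.
ANCOM is the classical W form, not the bias-corrected (ANCOM-BC)
model, and handles exactly two groups.  Unweighted UniFrac and
non-phylogenetic beta-diversity metrics are deliberately absent from
the main chain.
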