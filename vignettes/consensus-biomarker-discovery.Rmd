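---
title: "Consensus biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus biomarker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

netmark implements a two-cycle strategy for finding non-invasive cancer
biomarkers shared between a solid tumor and the patient's circulating
immune cells (PBMCs). This vignette is the package's account of the
underlying models, the tunable parameters that matter, what the synthetic
data generator does and does not emulate, and the numerical decisions made
where the design was genuinely open.

## The two-cycle model

**Cycle 1 — topological reweighting of a cancer-signature network.** A
pan-cancer signature gene set is consumed as an undirected
protein-protein interaction (PPI) edge list. Two node statistics are
computed: the simple-graph degree, and Brandes betweenness centrality in
its classic convention — unnormalized counts over unordered source–target
pairs, endpoints excluded, computed per connected component. A
least-squares fit of log frequency on log degree summarizes how fat-tailed
the degree distribution is; a high R² is the usual signature of a
hub-bearing, scale-free-like network. The *central* gene set is the union
of

* **hubs** — by default the top-k nodes by degree (k configurable; a fixed
  degree threshold is also supported because published analyses sometimes
  quote one), ties broken deterministically by degree then symbol; and
* **high-betweenness genes** — nodes at or above the inclusive top-20%
  betweenness cutoff.

Two selection details were genuinely open and are worth stating. First,
the top-quantile cutoff is *tie-inclusive*: every node tied with the
cutoff value is selected, so the set cannot depend on sort stability.
Second, the quantile is computed over *mediating* nodes only (betweenness
> 0). In hub-dominated networks most nodes lie on no shortest path and
have betweenness exactly zero; a tie-inclusive cutoff taken over the full
node set would then degenerate to selecting every node (consider a star:
all leaves tie at zero). Restricting to positive betweenness keeps "top
20% by betweenness" meaningful, and settles in the same stroke how
isolated nodes are treated.

**Cycle 2 — differential-expression consensus.** Each compartment (tumor,
PBMC) contributes a case/control log2 expression matrix. Per gene, the
log2 fold change is the case-minus-control mean difference and the P value
a two-sided Welch t-test; Benjamini–Hochberg adjustment is applied across
genes, and a gene is significant when |logFC| > 0.5 (strict) **and**
adjusted P < 0.05 jointly. Welch's t is the single point of substitution
for the moderated-t statistics that microarray suites use; it is
self-contained, assumption-light at the 20-per-arm scale the pipeline
targets, and exactly testable against closed-form arithmetic. Shared DEGs
are genes significant in both compartments with agreeing direction
(direction agreement is the default because a biomarker measurable in
blood should move the same way as in the tumor); when a compartment has
several datasets they are combined by significance-in-all before the
cross-compartment intersection. The **consensus biomarker set** is the
intersection of the shared DEGs with the cycle-1 central genes, and every
membership decision is recorded in a provenance table.

## Co-expression module inference

The consensus gene is characterized by an ARACNE-style mutual-information
network over a dedicated expression matrix:

1. **MI estimator.** Plug-in MI on a B×B contingency table of
   equal-frequency bins, B = ⌊√n⌋ by default, in nats, with ties broken by
   stable first-occurrence rank (deterministic without auxiliary
   randomness). The estimator has a closed-form anchor — any bijection
   scores exactly log B — which makes it verifiable to machine precision.
   The original ARACNE's Gaussian-kernel MI is a documented substitution
   point, not reimplemented. Note the plug-in estimator's positive bias,
   approximately (B−1)²/2n nats on independent data: with B fixed it
   vanishes as n grows; under the default B = ⌊√n⌋ it does not, which is
   why the significance threshold below is estimated at the same n and B
   as the data rather than taken from an asymptotic null.
2. **Significance threshold.** The (1−α) quantile (α = 0.05) of a
   permutation null: sample labels of one member of each of up to
   `max_pairs` random gene pairs are permuted `n_permutations` times and
   the null MIs pooled. This is assumption-free and calibratable by
   simulation, unlike an analytic null fit.
3. **DPI pruning.** For every triangle (i, j, k), edge (i, j) is marked
   when MI(i,j) < min(MI(i,k), MI(j,k))·(1−ε); marks are computed against
   the original weights and applied only after all triangles are scanned,
   so the pruned set is independent of edge order. Default ε = 0.1, inside
   the 0–0.2 range conventional for DPI tolerance.
4. **Module extraction.** The module is the seed gene plus its first
   neighbors in the pruned graph. This is deliberately the simplest
   delimitation consistent with "the genes co-expressed with the seed";
   community detection would add a second, harder-to-validate model.

Module enrichment uses the one-sided Fisher exact test — identically the
hypergeometric upper tail P(X ≥ k) — against a GMT library, BH-adjusted
across terms, filtered at adjusted P < 0.05 and ranked by adjusted P then
overlap size (the dual criterion mirrors common enrichment practice of
preferring large overlaps among comparably significant terms). The
background universe defaults to the union of the library's genes, the only
background derivable from the library itself; it is configurable because
enrichment P values are meaningless to compare across different universes.

## Survival and qPCR models

**Survival.** Subjects are dichotomized at the median expression of the
gene under study (ties to the low stratum, deterministically; the median
split is the field-standard cut when no optimized threshold is published).
Kaplan–Meier product-limit curves are estimated per stratum, with an
optional follow-up horizon (3 or 5 years) applied as administrative
censoring before estimation. Strata are compared by the log-rank test, and
the hazard ratio is summarized from the log-rank table as
(O₁/E₁)/(O₂/E₂) — the observed/expected form is self-contained, matches
the univariate single-gene use case, and a Cox fit over the same data is
available through the survival package as an external cross-check.

**qPCR.** Classic comparative ΔΔCt with amplification efficiency fixed at
2: ΔCt = Ct(target) − Ct(housekeeping) per sample, ΔΔCt referenced to the
calibrator group's mean ΔCt, fold = 2^(−ΔΔCt). Groups are summarized by
the geometric mean of folds — identically 2^(−mean ΔΔCt) — because folds
are log-scale quantities; an arithmetic mean would systematically inflate
group folds. Group comparison is Kruskal–Wallis with tie correction. The
calibrator is configurable; the bundled three-group demo (healthy /
primary / metastatic) expresses both contrasts relative to primary-stage
samples, planting shifts of −log₂(2.6) cycles (healthy) and −log₂(24.8)
cycles (metastatic) relative to primary.

## What the synthetic generator emulates — and what it does not

Every input is generated with planted ground truth by `synth_config()` and
the `make_*` generators, each drawing from its own RNG stream derived from
(seed, generator name) so adding a call never perturbs earlier outputs.

| component | model | key defaults |
|---|---|---|
| expression | gene baseline ~ N(8, 2) log2 units; measurement noise N(0, σ); planted DEGs shifted ±logFC in cases | 20/20 per arm, logFC = 2, σ = 0.1, 5% planted |
| network | Barabási–Albert preferential attachment, 2 edges/new node | 6 recorded hubs |
| co-expression | module genes share a latent factor z ~ N(0,1): value = baseline + loading·z + noise | module 12, loading 0.9 |
| survival | exponential times, hazard h₀·exp(β·1[expr > median]); uniform administrative censoring on [0, 3/h₀] for a `censor_rate` fraction | β = ln 2, h₀ = 0.2/yr, 20% censoring, n = 200 |
| qPCR | housekeeping Ct ~ N(20, 0.5); target = housekeeping + group shift + N(0, 0.25) | 8/group, shifts 0 / +1.379 / −3.253 |

The latent-factor module model was chosen over a specified covariance
matrix because it makes membership unambiguous — a gene either loads on z
or it does not — so recovery can be scored by Jaccard index without an
arbitrary correlation cutoff. The DEG noise scale σ = 0.1 with logFC = 2
describes a strong, clean planted effect: passing recovery tests under
these conditions demonstrates that the machinery is correct, *not* that
the pipeline would achieve the same sensitivity on real microarrays, where
effect sizes are smaller, variances gene-dependent and heavy-tailed, and
probe effects, batch structure and normalization artifacts — all
deliberately outside the generator — dominate the error budget. The same
caveat applies to the end-to-end demo: its planted consensus gene is
recovered essentially always because the generator satisfies every
assumption the pipeline makes; real GEO analyses will not.

The demo aliases its planted genes to CCNB2 (consensus: top hub and
shared up-regulated DEG) and PGK1 (shared DEG, topologically peripheral)
— cosmetic labels that exercise the realistic outcome where the shared
set strictly contains the consensus set.

## Numerical choices and degenerate inputs

* Both-groups-constant genes: equal means give p = 1, unequal p = 0
  (Welch's t is undefined there; these limits preserve the obvious
  ordering).
* Power-law R² with a zero-variance log-frequency response is defined as
  0 (a flat histogram carries no evidence of a fat tail); fewer than three
  distinct positive degrees is an error, not a number.
* A degree threshold that selects no hubs yields an empty hub set with a
  warning — fractional thresholds on integer degrees (e.g. 14.29) can
  legitimately select nothing on a given network.
* MI on a constant vector is an error (its equal-frequency binning is
  undefined), as is stratifying survival on constant expression.
* Kaplan–Meier with all subjects censored returns an empty event table,
  i.e. S ≡ 1; a log-rank comparison with zero total events is an error.
* Ct tables: folds are invariant to any per-sample shift applied to both
  Ct columns; this invariance is asserted in the tests, not assumed.

## Problem sizes used by the tests and acceptance script

The bundled checks run, per component: 200 random graphs of ≤7 nodes
against a shortest-path-enumeration betweenness oracle; 500
hypergeometric-tail and 500 BH step-up oracle instances; 200 weighted
graphs of ≤6 nodes against a brute-force DPI oracle; exhaustive
Kruskal–Wallis permutation nulls for every group layout of total n ≤ 8
(compared via mid-P, the continuity correction appropriate for a discrete
null); a 2000-gene null matrix for DEG calibration; 20 replicates each for
hub, chain-pruning (n = 500 samples) and module recovery (30 genes × 300
samples); 200 replicates for hazard-ratio recovery (400 subjects each);
and 40 end-to-end demo replicates (100-gene universe, 30-gene
co-expression matrix, 20 permutations). These sizes keep the full suite in
the low minutes on one core while leaving each check's sampling error well
below its decision margin.

## Known limitations

* Welch's t has no variance moderation; at 2–3 samples per arm it will be
  underpowered relative to empirical-Bayes approaches.
* The binned MI estimator needs tens of samples before its permutation
  threshold separates modules cleanly; below ~30 samples expect sparse
  inferred networks.
* The O/E hazard-ratio summary is mildly biased toward the null relative
  to a Cox estimate (the acceptance simulations at true HR = 2 recover a
  mean near 1.9); it is a ranking/reporting device, not an inferential
  estimator with confidence intervals.
* First-neighborhood modules cannot represent overlapping or hierarchical
  module structure.
* The pipeline consumes post-normalized log2 expression; it performs no
  normalization, batch correction or probe-to-gene mapping beyond
  collapsing duplicate symbols to the highest-mean row.
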