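---
title: "Methods and modelling choices in micromet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in micromet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

micromet analyses cohorts stratified into ordered disease stages — here
written HC < SCAD < MI (healthy control, stable coronary artery disease,
myocardial infarction) — that have been profiled on two omics layers: a
shotgun-metagenomic layer summarised as species and KEGG-Orthology (KO)
abundance tables, and an untargeted serum-metabolomics layer of feature
intensities. The package takes these tables plus per-sample clinical
phenotypes (Gensini, Syntax, cTnI, TIMI and the like) and produces the
standard chain of results for this study design: differential species,
module-level functional shifts, co-abundance metabotypes, and a tiered-FDR
association map between the layers and the clinic. This vignette explains
each method, the tunable parameters and their defaults, the synthetic
cohort used for validation, and the numerical decisions that make the
pipeline deterministic.

## Statistical primitives

All hypothesis tests used by the pipeline live in one module and return a
uniform record (statistic, two-sided p, direction, method). The direction
convention is fixed throughout: +1 means the later-ordered (more severe)
group is elevated, so positive signs read as "up with disease".

* **Wilcoxon rank-sum.** The workhorse two-group test for abundances and
  intensities. For tie-free samples with combined n ≤ 12 the exact
  permutation distribution of the Mann–Whitney U is enumerated; otherwise
  a normal approximation with tie-corrected variance and continuity
  correction is used. The crossover point is where enumeration is cheap
  and the approximation is still imperfect.
* **Welch t-test.** Applied to log intensities in the metabolite
  cross-comparison, where an approximately Gaussian location model on the
  log scale is defensible; never applied to raw compositional abundances.
* **Kruskal–Wallis** (tie-corrected H, chi-squared reference) and
  **Jonckheere–Terpstra** for the three ordered stages. JT sums
  Mann–Whitney counts over ordered group pairs; with total n ≤ 12 the
  exact two-sided p is obtained by full enumeration of label arrangements,
  above that by a normal approximation with the tie-adjusted variance and
  continuity correction. Two-sided exact p-values double the smaller tail
  and cap at 1.
* **Pearson chi-squared without continuity correction** for r × c
  categorical tables, with **Fisher's exact test** substituted only for
  2 × 2 tables containing an expected count below 5. This combination
  reproduces the printed p-values of the cohort's baseline table from its
  categorical counts (see `tests/testthat/test-acceptance.R`), including
  rows containing zero cells, which is the evidence that the upstream
  analysis used plain chi-squared there.
* **Fold change** is the ratio of case over reference group means with an
  additive pseudocount (default: half the smallest non-zero value of the
  table at hand). Means rather than medians, matching the usual
  intensity-data convention; the gates are strict inequalities on the
  unrounded ratio, so 0.8333… does not pass a "< 0.83" gate and exactly
  1.2 does not pass "> 1.2".
* **Benjamini–Hochberg** q-values are computed by the definitional
  step-up rule; `NA` p-values are carried through without inflating the
  family size.

## Species screen and diversity

Species tables are converted to relative abundances (columns closed to
one) and filtered at a strict prevalence gate: a feature must be non-zero
in *more than* `prevalence_min` (default 5%) of samples; a feature at
exactly the boundary is dropped. The differential screen tests each
remaining species by Wilcoxon between a reference and a case group
(pooling stages is supported, e.g. HC vs SCAD+MI) and gates on raw
p < 0.01 together with fold change > 1.2 or < 0.83. The gate deliberately
uses raw p, not q — that is the published operating point of this screen —
and BH q-values are attached for transparency. Because the test is
rank-based and the fold change is taken on closed compositions, the screen
is invariant to per-sample scaling of the input.

Alpha diversity is Shannon (natural log) and Gini–Simpson on the
normalized vector, both invariant to positive rescaling, so the choice
between counts and relative abundances is immaterial. Between-sample
structure uses Bray–Curtis dissimilarity, principal coordinates
(eigendecomposition of the Gower double-centred squared-distance matrix),
perMANOVA, and distance-based redundancy analysis constrained on the stage
labels. Three numerical decisions:

* Negative PCoA eigenvalues — expected, since Bray–Curtis is
  non-Euclidean — are truncated and reported separately rather than
  Lingoes/Cailliez-corrected; proportions explained are computed over the
  positive spectrum only.
* perMANOVA p uses the `(1 + exceedances)/(1 + n_perm)` convention
  (default 9999 permutations), so p is never exactly zero; permuted
  pseudo-F values within a relative 1e-9 of the observed value count as
  exceedances so float noise cannot deflate p.
* dbRDA is implemented as the regression of the positive-eigenvalue PCoA
  embedding on stage indicators. On Euclidean inputs its constrained
  inertia equals the perMANOVA among-group sum of squares exactly, which
  the tests verify to 1e-6.

## KEGG-module reporter scores

Per-KO Wilcoxon tests (on the prevalence-filtered KO table) are
aggregated to modules by the reporter-feature construction: each KO
contributes a signed inverse-normal score `z = qnorm(1 − p/2) · sign`,
a module of k tested KOs scores `Z_raw = Σz/√k`, and the corrected score
standardizes `Z_raw` against the mean and standard deviation of the same
statistic over `background_draws` (default 1000) random size-k sets drawn
without replacement from all tested KOs. A module is called at
`|score| > 1.6`, i.e. roughly 95% normal confidence per tail. Choices
worth stating:

* The aggregation uses **raw** p-values; q-values are reported but not
  aggregated (stacking two multiplicity corrections would double-penalise).
* p-values are floored at 1e-15 before the inverse normal so a complete
  separation cannot produce an infinite z.
* The background is drawn from random KO sets rather than permuted sample
  labels. This matters: on a cohort with genuine signal, affected KOs
  inflate the background spread, which automatically tightens the false
  flags on unaffected modules. Sample-label permutation is a defensible
  alternative; random KO sets are the default because they condition on
  the observed per-KO statistics.
* KO z-scores are put in a canonical (sorted-identifier) order before the
  seeded draws, so module and row order cannot change the result; with a
  fixed `random_seed` scores are bit-reproducible.

For sample-level correlation analyses (the association grid below),
module activity is summarised per sample as the sum of the module's KO
relative abundances — reporter scores are group contrasts and have no
per-sample value.

## Metabotyping

Metabolite features enter a two-branch cross-comparison selection:

* **Set A (pairwise):** over all pairwise stage comparisons, a feature
  passes if in at least one comparison the Wilcoxon q-value and the
  (log-scale Welch) t-test q-value are both below 0.05 **and** the fold
  change clears the 1.2/0.83 gate in that same comparison. Each test
  family is BH-adjusted separately within each comparison; requiring the
  three conditions jointly within a single comparison is the stricter of
  the readings available and is the one implemented.
* **Set B (trend):** Jonckheere–Terpstra or Kruskal–Wallis p < 0.05
  across the ordered stages.

The selection is the union of the branches minus a user-supplied
exclusion list (drug-derived features are a chemistry call, not a
statistics call, so they enter as an input). Selected features are
clustered into metabotypes on a signed weighted co-abundance network:
Pearson correlation r of log-transformed, standardized intensities, mapped
to adjacency `((1 + r)/2)^β` with β = 14 — the signed-network operating
point; a signed network is retained because β = 14 is characteristic of
signed topologies and anti-correlated features should *not* co-cluster.
The topological overlap measure

TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)

turns shared neighbourhoods into similarity, `1 − TOM` feeds an
average-linkage dendrogram, and clusters are extracted by a deterministic
dynamic height cut: the cut height is the merge-height quantile mapped
from `deepSplit` (0.64, 0.73, 0.82, 0.91, 0.95 for levels 0–4; default 4),
branches below `min_cluster_size` (default 5 — small enough to keep
chemically narrow clusters, large enough that an eigen-feature is
meaningful) are left unassigned with label 0, and surviving clusters are
renamed M01, M02, … by decreasing size. Higher `deepSplit` admits looser
merges below the cut, so more branches survive the size gate; on
structured data the assigned-cluster count is non-decreasing across the
five levels, which the tests check. This static-quantile cut is a
deliberate, fully specifiable approximation of adaptive branch
decomposition: it is deterministic, needs no per-branch heuristics, and
recovers planted factor structure exactly in the regimes the tests cover.
Each cluster is summarised by an eigen-feature — PC1 of the standardized
within-cluster matrix, sign-oriented so that its mean correlation with
members is positive.

The scale-free fit index (R² of log-binned connectivity frequency against
connectivity) is exposed for β diagnostics but is not used to re-fit β at
run time: β is a configuration constant, not a fitted quantity.

## Association map

Two association surfaces are produced. First, phenotype associations:
module activities and metabotype eigen-features against each clinical
phenotype — Mann–Whitney for two-group contrasts, Spearman for continuous
phenotypes — BH-adjusted per family with a significance gate at FDR < 0.1.
Second, the module × metabotype grid: Spearman correlations with a
**single** BH family across every cell of the grid. Cells are annotated
with a tier ladder: q < 0.001 strong, q < 0.05 moderate, q < 0.1 weak,
otherwise ns. The published annotation legend this ladder descends from is
internally inconsistent (its middle band is stated as an empty interval);
the ladder here is the only ordering of the three printed thresholds that
is coherent, and it is applied with half-open boundaries so every cell has
exactly one tier. Missing phenotype values are excluded pairwise; cells
with fewer than four complete pairs are reported as missing rather than
tested.

## The synthetic cohort

Because the original cohort's raw data are external, validation runs on a
generator with planted, recoverable truth. Its defaults are the study
conditions, not tuning knobs:

* 36/64/46 samples across HC/SCAD/MI; 100 species, 400 KOs, 20 modules of
  8 KOs, 200 metabolite features in 5 latent clusters.
* Species: per-species log-normal baselines (meanlog sd 1.5, per-sample
  log noise sd 1) — the heavy-tailed profile shape typical of gut
  microbiomes — closed to compositions after 10 planted species (60% up,
  40% down) are multiplied by a 4-fold effect in MI and its square root
  in SCAD, making planted effects stage-monotone.
* KOs: induced as a sparse binary species-carrier matrix (3 carriers per
  KO) times the absolute species abundances, with log-normal noise (sd
  0.3). KOs of the 4 planted modules are carried by planted species of the
  matching direction; KOs of unplanted modules draw carriers from
  non-differential species so module-level signal is attributable to the
  plan.
* Metabolites: feature = 0.8 × latent cluster factor + Gaussian noise
  (sd 0.6) on the log scale, exponentiated to positive intensities.
  Cluster factors receive stage-monotone mean shifts (±1.2, ±0.8, 0.5 per
  stage step across the five clusters) — alternating signs keep shifted
  clusters mutually anti- or un-correlated so the clustering problem stays
  identifiable.
* Phenotypes are stage-monotone with noise; their magnitudes are
  arbitrary and only their ordering is meaningful.
* The species, KO, metabolite and phenotype streams use independent
  sub-seeds of the master seed, so regenerating one layer never perturbs
  another.

What the generator does **not** emulate: sequencing depth and read-level
noise, compositional zero-inflation beyond what log-normal closure
produces, inter-species ecological correlation, batch effects, LC–MS
drift, or drug-induced metabolite structure. Recovery results on this
cohort therefore demonstrate the pipeline's internal correctness — that
each stage finds exactly what was planted at realistic effect sizes — not
field performance on real cohorts.

## Validation problem sizes

The shipped test suite validates, among other things: the printed
baseline-table chi-squared p-values to three decimals; type-I error of
Wilcoxon/Kruskal–Wallis/JT at α = 0.05 within (0.04, 0.06) over 10,000
simulated nulls each, and of perMANOVA (999 permutations, n = 60) over
500 nulls; reporter recovery of every planted module with correct sign
and a ≤ 5% average false-flag rate over 50 seeds; metabotype recovery at
adjusted Rand index ≥ 0.8 over 20 seeds; agreement of JT with exhaustive
enumeration, BH with the brute-force step-up rule, TOM with hand-computed
cases, and PCoA with Euclidean geometry; and bit-identical outputs of two
equal-seed pipeline runs. These sizes were chosen to make the binomial
noise of each simulated rate small against its acceptance band.

## Known limitations

* The dynamic cut is a static quantile cut per `deepSplit` level, not the
  full adaptive/hybrid branch decomposition; very unbalanced dendrograms
  may split differently than the adaptive algorithm would.
* Reporter scores assume per-KO tests are roughly independent within
  modules; strongly co-abundant KOs share carriers and the effective k is
  smaller than the nominal one. The random-set background absorbs part of
  this, not all of it.
* dbRDA operates on the truncated positive-eigenvalue embedding; with
  strongly non-Euclidean distance matrices the constrained proportion
  refers to the truncated inertia.
* The cross-comparison set B is defined on the declared ordered group
  list; the package does not guess additional sub-stages beyond the three
  configured ones.
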