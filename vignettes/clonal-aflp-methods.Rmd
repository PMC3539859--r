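---
title: "Methods: dominant-marker population genetics of clonal, self-incompatible plants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker population genetics of clonal, self-incompatible plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflpop)
```

`aflpop` analyses dominant (band presence/absence) marker data from
plants that combine self-incompatibility with clonal propagation. This
vignette is the package's own account of its methods: the statistical
models, the defaults and why they were chosen, what the simulator does
and does not emulate, and the numerical decisions a maintainer would want
written down.

## 1. Error rate and clone calling

Dominant fingerprints are noisy, so clone identification needs an
explicit error model. The package estimates the per-dataset genotyping
error rate from replicate pairs — two independent extractions and
scorings of the same individual — as

$$ e = \frac{\text{mismatches over all pairs}}{\text{pairs} \times
\text{loci}} . $$

Two deliberate conventions:

* **Denominator = full locus count.** Mismatches are only countable at
  loci scored in both pair members, but the denominator keeps the full
  locus count. This reproduces the printed arithmetic of published
  error rates exactly and makes the estimate conservative (missing
  cells can only lower it). The alternative (scored-loci denominator)
  would change `error_rate(123, 9, 294)` only in its third decimal for
  realistic missingness.
* **Strict inequality for clone edges.** Samples `i, j` are linked when
  their pairwise mismatch fraction `d(i, j)` — computed over jointly
  scored loci (pairwise deletion) — is strictly below `e` ("below the
  error rate"). Pairs with no jointly scored locus get a missing
  distance and never form edges.

Clonal lineages are the connected components of the link graph, i.e. a
single-linkage closure. Clonehood as observed is not perfectly
transitive: `d(a,b) < e` and `d(b,c) < e` do not force `d(a,c) < e`.
Because no principled tie-break exists for dominant data, the package
keeps the closure and *flags* every non-transitive triple in the output
(`call_clones()$triples`) so the analyst can inspect borderline
lineages instead of silently accepting or breaking them.

A sample is *clonal* when its lineage has ≥ 2 members anywhere in the
data set. A lineage spanning several populations is counted once
globally; its members count toward each population's clonal tally. This
is the convention that makes "54 clonal samples in 10 lineages across 14
populations" style summaries consistent.

## 2. Diversity statistics

Per group, `fragment_classes()` counts loci that are polymorphic (band
present and absent among scored members), fixed (present in every
scored member) and private (present in the group and nowhere else), by a
direct per-fragment scan. `%` polymorphic is relative to the full locus
count.

Nei's gene diversity is computed on **band-phenotype frequencies**:

$$ H_j = \frac{1}{L} \sum_l \frac{n_l}{n_l - 1}\left(1 - p_l^2 -
q_l^2\right), $$

with `p_l` the presence fraction among the `n_l` scored members. We do
not back-transform to allele frequencies by default: the
Hardy–Weinberg assumption behind the square-root transform is exactly
what clonal reproduction violates. The pure-recessive variant
(`allele_freq = "sqrt"`) is available for comparison. Note the
`n/(n-1)` correction can exceed the two-state ceiling of 0.5 at tiny
`n` (it reaches 1.0 at `n = 2, p = 0.5`); this is a property of the
unbiased estimator, not a bug, and is asserted in the tests.

The SD and variance of `H_j` come from a seeded bootstrap over loci
(default 1000 replicates): loci are the unit of resampling because the
locus sample, not the individual sample, dominates the uncertainty of a
mean-over-loci statistic, and because published tables report
`Var = SD²` without naming an estimator.

Rare fragments (`rare_fragments()`) are classified by area:
area-specific when present in only one area, rare when their presence
frequency is below the threshold (default 0.15) in every area where
they occur.

## 3. Ordination and rank tests

`nei_li_dist()` implements d = 1 − 2n₁₁/(2n₁₁ + n₁₀ + n₀₁) over
jointly scored loci; a pair with no bands on either side has no defined
similarity and is reported missing with a warning. `band_pcoa()` is
classical scaling (double-centred −d²/2, eigendecomposition, axes
scaled by √λ). Percent variance is reported over the positive
eigenvalues only; negative eigenvalues — expected for non-Euclidean
Dice distances — are counted and reported, and no Lingoes/Cailliez
correction is applied by default because such corrections shrink the
leading percent-variance figures without changing the configuration.
`correction = "cailliez"` is available.

Group separation on axes uses Mann–Whitney U (two groups) or
Kruskal–Wallis H (more), with average-rank ties and the normal
approximation without continuity correction; tests run per axis
(default axes 1–3) because a single reported U cannot be attributed to
a specific axis set after the fact. These call `stats::wilcox.test()` /
`stats::kruskal.test()`; the tests cross-check U against exhaustive
pair counting and a permutation null.

## 4. AMOVA

`amova()` is the distance-based decomposition: squared pairwise
distances are band **mismatch counts** (the squared Euclidean distance
between 0/1 vectors), the standard choice for dominant data; a flag
substitutes squared Nei & Li distances. Sums of squares follow

$$ SS_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}, \qquad
SS_{within} = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d^2_{ij}, $$

with the two-level extension partitioning among-group / among-population
within group / within population. Variance components use the expected
mean squares with unequal sizes (coefficients n₀ or n₁–n₃);
φ_ST = (σ²_a + σ²_b)/σ²_total, φ_CT = σ²_a/σ²_total,
φ_SC = σ²_b/(σ²_b + σ²_c). Negative components are reported as
estimated; for the percent display they are truncated at zero (flag to
disable), since variance percentages below zero have no display
meaning. Permutation p-values permute sample labels at the tested level
(whole populations among groups for φ_CT) with
p = (#{φ\* ≥ φ} + 1)/(n_perm + 1).

## 5. Crossing groups and mate availability

The inference rule is binary: an unordered population pair is
*compatible* when pooled crossings produced at least one seed,
*incompatible* when at least one flower was tested and no seed ever
formed. Capsules without seeds do **not** count as compatibility —
parthenocarpic capsules occur — and one seed suffices, because the
quantity of seeds feeds the trait analyses, not the partition.
Reciprocal directions are pooled by default (no paternal effect is
assumed; a flag keeps directions separate). The minimum flower count
before declaring incompatibility defaults to 1 and is configurable.

Crossing groups are connected components of the incompatibility graph.
Compatible pairs that end up inside one component contradict the
shared-S-allele interpretation and are listed as conflicts rather than
silently dropped. Populations with no tested crossings (e.g. plants
that never flowered) stay `"unknown"` and are excluded from mate
availability, which is the fraction of grouped population pairs lying
in different groups.

## 6. Traits and correlations

Pollen per flower is the mean of ten aliquot counts times the dilution
factor (default 1000). The P/O ratio divides by the ovule count of the
same flower. Seed size is analysed as the per-capsule mean width (mm):
seeds within a capsule share a maternal environment, so the capsule is
the independent unit. Viability uses the closed three-class vocabulary
viable/abnormal/dead; every reported fraction carries its
numerator/denominator.

The correlation suite runs the fixed list of trait-diversity pairs
(pollen against polymorphic/private/fixed fragments, H_j and clonal
percentage; mutant fraction against pollen and fragment counts; H_j
against clonal and non-clonal proportions; ovules against mutant
fraction) as Spearman correlations with average-rank ties. Raw p-values
are reported alongside a Holm-adjusted column: the suite involves ~11
non-independent tests, and showing both lets the reader apply either
convention. Genetic-vs-geographic distance uses haversine great-circle
kilometres between population coordinate means and a Mantel-style
matrix permutation (rows and columns permuted jointly), because
distance pairs sharing a population are not independent — a plain
Spearman p would be anti-conservative.

The package deliberately replaces mixed-model (REML), nested-ANOVA and
binomial-GLM fits with these rank tests: the area/population trait
comparisons it makes are distributional-assumption-free and match the
rest of the pipeline.

## 7. The simulator

`simulate_dataset()` is a forward model of self-incompatible clonal
colonization, and `default_scenario()` pins its defaults to the study
design the package targets: 20 introduced populations along a ~150 km
transect (93 samples), 3 native populations (15 samples), 294 loci, 9
replicate pairs, five crossing groups of sizes 13/3/1/1/1 with one
never-flowering population, and 10 planted clonal lineages holding 54
of the 93 introduced samples, one spanning 8 populations.

Model components and default rationale:

* **Locus classes.** 4 fixed loci; 45 native-only loci (40 drawn rare,
  frequency U(0.03, 0.13), 5 common) so that ~89% of native-specific
  fragments are rare at the 0.15 threshold; 121 shared loci (25 rare in
  both areas); 124 loci segregating in the introduced founder pool.
  Counts sum to 294.
* **Introductions.** Six founder events with independent band profiles
  drawn per locus from the class carry-probabilities, assigned to
  contiguous transect blocks — this is what creates isolation by
  distance in the introduced range. Genets within an introduction
  diverge from its profile by symmetric flips at rate δ = 0.06 at the
  variable loci (giving genet-vs-genet mismatch ≈ 0.10, comfortably
  above any plausible clone threshold).
* **Clonal propagation.** Lineage members accumulate somatic flips at
  μ = 10⁻⁴ per locus per generation over a propagation depth drawn per
  sample; with depths of tens of generations this keeps within-lineage
  divergence near 0.005 — visible but far below the threshold (total
  within-lineage mismatch ≈ 0.025 against a threshold near 0.046).
* **Scoring.** Every sample is scored once with flip rate ε = 0.01;
  replicate rows are re-scorings of the same true genotype with
  ε_rep = 0.037. The expected replicate mismatch is then
  ε(1−ε_rep) + ε_rep(1−ε) ≈ 0.0463, the published error-rate regime.
  The two rates differ on purpose: a replicate involves re-extraction
  and so carries more noise than the shared scoring pass. This is also
  what makes threshold clone calling *work* — if replicate noise
  equalled within-dataset noise, within-clone mismatch would
  concentrate exactly at the threshold and the rule would shatter
  lineages; the asymmetry is a modelling statement about where
  replicate error comes from, and the estimator itself is validated
  separately against the closed form 2ε(1−ε) with both rates equal.
* **Incompatibility.** A population pair sets no seed iff their
  unordered S-genotypes are identical; any allele difference makes
  them compatible. This is exactly the inference rule the crossing
  module implements, so recovering the planted partition is a
  consistency check of the whole chain, not a tautology of one
  function. The true SI mechanism (gametophytic vs sporophytic, partial
  compatibility) is out of scope.
* **The ratchet.** One latent per-sample load counter
  (Poisson, rate 0.15 per clonal generation) feeds every trait model:
  pollen = 8000 × 0.95^load grains, mutant-flower probability
  logit⁻¹(−3 + 0.3·load), seeds per capsule, seed width, viability and
  germination all decay in load. Because propagation depth scales with
  a population's planted clonality, the trait-diversity correlation
  structure (pollen ~ diversity positive, mutant ~ pollen negative,
  ...) is planted through a single mechanism, and setting the decay
  parameters to zero abolishes it — both directions are tested.

The marker matrix carries the 108 primary samples plus the 9 replicate
rows (117 × 294); `drop_replicates()` restricts to primary samples, and
all statistics except the error rate run on the primary rows.

**What the simulator does not emulate:** native-range regional
structure (native samples are exchangeable within the native pool),
coalescent history, pollinator movement, selection on markers, partial
self-compatibility, and locus-specific scoring error. Passing the
recovery tests therefore shows the pipeline is correct under the stated
generative model, not that real AFLP data meet that model.

`expected_amova_target()` computes the among-area variance percentage
the generator implies analytically: sums of squares are linear in the
pairwise squared distances, so their expectation follows exactly from
the expected per-pair mismatch counts, which in turn have closed forms
in the class frequency moments, the flip rates and the
introduction/lineage structure. The end-to-end test requires the
realized percentage to fall within ±10 points of this computed target
(it lands ~20% with the defaults); no hand-picked number is involved.

## 8. Numerical choices, problem sizes, limitations

* Missing band cells are the literal string `NA` on disk
  (configurable) and are excluded pairwise from every statistic;
  validation rejects anything outside {0, 1, missing} naming the
  offending cell, and never coerces.
* Lineage and crossing-group labels are assigned by decreasing size
  (ties by first sample/population), making outputs order-invariant;
  order invariance is tested.
* The two-row-per-individual exporter for external Bayesian clustering
  tools codes the second (unobservable) allele as `-9`; this coding is
  a documented convention of the exporter, not a reproduction of any
  specific tool's historical input.
* Test and validation problem sizes were chosen to exercise the
  asymptotics without waste: 50 random AMOVA instances against the
  double-loop oracle, 500 null replicates for the permutation size
  checks at 99 permutations each, five master seeds for end-to-end
  recovery, 20 runs for the ratchet-off falsification.
* Known limitations: the error-rate threshold rule has no uncertainty
  attached (no confidence band on `e` is propagated into clone calls);
  H_j bootstrap ignores sampling of individuals; AMOVA assumes
  exchangeable samples under permutation within the tested level; the
  crossing inference cannot separate shared-S incompatibility from
  general sterility of a population pair.
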