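# aflpop

Population genetics of clonal, self-incompatible plants from dominant
(AFLP-style) presence/absence markers.

## The problem

Self-incompatible plants that colonize a new range from a handful of
founders face a double bind: with few S-allele classes around, most
potential mates are cross-incompatible, sexual reproduction collapses,
and the species persists by vegetative (clonal) propagation. Lineages
that stop recombining then accumulate deleterious mutations (Muller's
ratchet), which should show up as degraded reproductive traits — fewer
pollen grains, more malformed (androecium-mutant) flowers, lower seed
viability — precisely in the most clonal, least genetically diverse
populations. `aflpop` implements the full analysis chain needed to test
this scenario from dominant marker fingerprints, crossing experiments and
reproductive trait records, plus a forward simulator of the colonization
process with known ground truth so every stage of the pipeline can be
validated.

## What it computes

* **Genotyping error rate and clone calling.** The error rate of a
  dominant-marker run is estimated from replicate re-extractions as
  *e* = mismatches / (pairs × loci). Two samples belong to one clonal
  lineage when their pairwise mismatch fraction (over jointly scored
  loci) is strictly below *e*; lineages are the connected components of
  that graph, and non-transitive triples are flagged rather than broken.
* **Diversity tables.** Per group: polymorphic, fixed and private
  fragment counts, and Nei's gene diversity
  *H*<sub>j</sub> = mean over loci of (n/(n−1))(1 − p² − q²) on
  band-phenotype frequencies, with a seeded bootstrap over loci for its
  SD/variance. Rare-fragment classification by area at a frequency
  threshold.
* **Ordination.** Nei & Li (Dice) distances
  d = 1 − 2n₁₁/(2n₁₁ + n₁₀ + n₀₁), classical-scaling PCoA with percent
  variance over positive eigenvalues, and Mann–Whitney/Kruskal–Wallis
  tests of group separation per axis.
* **AMOVA.** Distance-based hierarchical analysis of molecular variance
  (squared Euclidean = band mismatch counts) with one- or two-level
  designs, unequal-size variance components, φ-statistics
  (φ_ST, φ_CT, φ_SC) and label-permutation p-values.
* **Crossing groups and mate availability.** Populations that never set
  seed when crossed with each other share S-alleles: crossing groups are
  connected components of the incompatibility graph; compatible pairs
  inside a component are reported as conflicts; mate availability is the
  fraction of population pairs lying in different groups.
* **Reproductive traits and correlations.** Mutant-flower frequencies,
  pollen totals from diluted aliquot counts (mean × dilution), P/O
  ratios, seed/viability/germination summaries, a Spearman suite linking
  traits to genetic indices (Holm-adjusted alongside raw p), and a
  Mantel-style permutation test for isolation by distance.
* **Simulator.** `default_scenario()` encodes a colonization of 20
  transect populations (93 samples) plus 3 native populations (15
  samples) scored at 294 loci with 9 replicate pairs, five planted
  crossing groups (13/3/1/1/1, one population never flowering), 10
  planted clonal lineages holding 54 of 93 introduced samples, and a
  latent mutation load that degrades traits with clonal age.

## Worked example

```r
library(aflpop)

cfg <- default_scenario()
sim <- simulate_dataset(cfg, seed = 1)
report <- run_full_analysis(sim$marker, sim$samples, sim$crosses,
                            sim$traits, n_perm = 999, seed = 1)
print(report)
```

```
dominant-marker pipeline report
replicate error rate: 120 mismatches / (9 pairs x 294 loci) = 0.0454 (4.54%)
clone partition: 108 samples, 64 lineages (10 multi-member holding 54 samples), threshold 0.0454
  2 non-transitive triple(s) flagged
PCoA: 108 samples, 56 positive axes (51 negative eigenvalues)
  first 3 axes: 26.90, 15.48, 10.95% of variance (total 53.32%)
AMOVA among areas: 22.61% (phi_ST = 0.226, p = 0.0010)
crossing groups: 19 populations in 5 groups (sizes 13/3/1/1/1); 1 unknown
mate availability: 0.526
genetic~geographic Mantel: r = 0.458, p = 0.0010 (190 pairs)
```

Reading this: the nine replicate re-scorings give an error rate of 4.54%,
and clone calling at that threshold recovers exactly the 10 planted
multi-member lineages holding 54 of the 108 samples. The crossing
records recover the five planted S-classes exactly, with the
never-flowering population left unknown; 52.6% of population pairs are
cross-compatible. The strongest trait–diversity correlations are the
planted ratchet signals:

```r
head(report$correlations[order(report$correlations$p_value), ], 3)
#>             var_x           var_y          r      p_value       p_holm  n
#> 5          pollen clonal_fraction -0.8273048 1.122311e-06 1.234542e-05 23
#> 6 mutant_fraction          pollen -0.7166953 1.193507e-04 1.193507e-03 23
#> 9              hj clonal_fraction -0.5021811 1.461252e-02 1.315126e-01 23
```

More clonal populations produce fewer pollen grains, mutant-rich
populations produce less pollen, and gene diversity falls with clonality.

## Command line

A thin dispatcher over the same functions ships in `inst/cli/aflpop.R`:

```sh
Rscript inst/cli/aflpop.R simulate --seed 3 --out-dir data
Rscript inst/cli/aflpop.R clones --markers data/markers.tsv \
    --samples data/samples.csv --out-dir out
Rscript inst/cli/aflpop.R amova --markers data/markers.tsv \
    --samples data/samples.csv --levels area,population --out-dir out
```

Subcommands: `simulate`, `clones`, `diversity`, `pcoa`, `amova`,
`crossing`, `traits`, `correlate`, `report`. Every stochastic subcommand
takes `--seed`; logs go to standard error.

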