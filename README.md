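# ccpevol

Detecting natural selection in evolving composite cross populations
(CCPs) of predominantly selfing crops.

A composite cross population is created by inter-crossing a set of
parent varieties, pooling the progeny, and re-sowing the harvest every
generation. Grown this way over years, the population evolves; the
question for evolutionary plant breeding is **which allele-frequency
changes exceed genetic drift, and whether the selected alleles act
through measurable phenotypes** such as plant height or heading date.
`ccpevol` is for population geneticists and breeding researchers who
track such populations with modest marker panels (multi-allelic SSRs
plus gene-diagnostic SNPs) sampled at a few generations and locations.

## What it computes

Starting from parental genotypes, a crossing scheme with per-cross seed
counts, descendant genotype samples, and (optionally) phenotypes:

* **Virtual founding population** — each cross (i, j) contributes
  `n_ij = round(s_ij / Σ s_ij · 10,000)` copies of its F1 heterozygote
  genotype, reconstructing the founding gene pool from the seed-count
  records.
* **Marker recoding** — non-parental alleles removed; each SSR locus
  collapsed to {most frequent allele in the founders, OTHER}, one
  recode map applied to every sample.
* **Gene diversity** — Nei's `He = 1 − Σ p_k²` per locus, averaged
  over loci, with percentile bootstrap-over-loci intervals (5,000
  resamples).
* **Differentiation** — Weir–Cockerham's θ (variance components a, b,
  c for diploid data with observed heterozygotes); multilocus θ is the
  ratio of sums `Σa / Σ(a+b+c)`; overall, pairwise and grouped
  contrasts (e.g. organic vs conventional management).
* **Outlier scan** — an FDIST-style neutral null: 20,000 loci
  forward-simulated in a 100-deme island model calibrated so the
  expected θ matches the observed neutral value; empirical p-values
  conditional on heterozygosity (±0.05 window); a locus is flagged when
  `p < 0.05` and its θ exceeds the multilocus average.
* **Effective population size** — `Ne = t / (4 · ln(1/(1 − F_ST)))` on
  the unflagged loci (CI mapped from the F_ST interval), plus the
  temporal method `Ne = t / (2(Fc − 1/(2S0) − 1/(2St)))` with
  `Fc = (x−y)² / ((x+y)/2 − xy)` averaged over loci.
* **Drift bands** — the 95% interval for a frequency after t
  generations of drift,
  `p_FND ± 1.96·sqrt(p_FND(1−p_FND)(1−(1−1/(2Ne))^t))`, evaluated for
  bracketing sizes Ne ∈ {150, 250}; loci outside the band in the same
  direction at every location are the signature of consistent
  selection.
* **Phenotypic effects** — per-locus additive allele effects (half the
  homozygote-class difference) from mixed-stand single plants
  (`y = μ + allele + (1|trial) + (1|allele:trial)`, Satterthwaite
  F-tests) and from pure-stand variety trials (LS-means then one-way
  regression), correlated with the frequency changes over loci
  (Pearson r, t-test on L − 2 df).

A forward-time CCP simulator (selfing rate 0.98, imposed effective
size, optional per-locus selection, additive trait models) generates
complete synthetic datasets with known truth; it backs the package's
parameter-recovery tests and is exported for power studies.

## Worked example

Simulate four locations evolving for ten generations with directional
selection (s = 0.12) on the wild-type allele of a height gene, then run
the inference chain:

```r
library(ccpevol)

p <- sim_params(n_parents = 12, n_crosses = 30, census_size = 2000,
                target_Ne = 200, n_loci_ssr = 10, n_loci_snp = 4,
                sample_sizes = c("3" = 100, "6" = 150, "10" = 200),
                selection_coefficients = c("Rht-B1" = 0.12),
                trait_model = list(height = list(mu = 100,
                  effects = c("Rht-B1" = 4, "Rht-D1" = 5),
                  residual_sd = 8, trial_sd = 5, interaction_sd = 2)))
parents <- make_parents(p, seed = 10)
scheme  <- make_crossing_scheme(p, seed = 2)
sim     <- simulate_generations(parents, scheme, p, seed = 3)
fnd     <- build_virtual_fnd(scheme, parents, virtual_pop_size = 10000)
gt      <- collapse_to_biallelic(sim$genotypes, fnd)
fnd_c   <- collapse_to_biallelic(fnd, attr(gt, "recode_map"))

fst10 <- fst_wc(gt, generation = 10, n_bootstrap = 1000, seed = 4)
print(fst10)
#> <differentiation_result> overall [MET vs MOR vs SOF vs WAF]:
#>   theta = 0.0188 [0.0094, 0.0307] (14 loci)
print(ne_from_fst(fst10, t = 8))
#> <ne_estimate> fst_pairs: Ne = 105 (64-211)

flags <- flag_selection(allele_frequencies(gt),
                        allele_frequencies(fnd_c),
                        ne_values = c(150, 250))
print(attr(flags, "consistent"))
#>            locus_id  ne direction n_populations
#> Rht-B1.150   Rht-B1 150     above             4
#> Rht-B1.250   Rht-B1 250     above             4

traits <- simulate_phenotypes(sim, p, seed = 5)
print(mixed_stand_effect(traits, gt, "Rht-B1", "height"))
#> <effect_estimate> Rht-B1 on height (mixed): a = 3.059 (se 0.586),
#>   F = 27.27, p = 2.34e-07, n = 692 [allele x trial variance ~ 0; term dropped]
```

Reading the output: differentiation among the four locations is low
(θ ≈ 0.019), yet the selected locus sits **above** the 95% drift band
in all four populations for both bracketing effective sizes — the
pattern of consistent, location-independent selection. The estimated
additive height effect of its frequent allele (3.1 ± 0.6 cm per copy)
recovers the simulated 4 cm within two standard errors. (The F_ST-based
Ne of ~105 against a simulated 200 reflects a documented factor-of-two
convention mismatch in the published inversion formula; see the
methods vignette — the temporal estimator is the calibrated one.)

`run_pipeline()` chains all stages (including the outlier scan and the
association grids) and writes every table as TSV plus a machine-
readable `run_log.json`; `inst/scripts/ccp-pipeline.R` wraps
`simulate` and `report` for shell use.

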