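---
title: "Detecting natural selection in evolving composite cross populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting natural selection in evolving composite cross populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccpevol)
```

## The problem

A composite cross population (CCP) is a segregating crop population
created by inter-crossing a set of parent varieties and pooling the
progeny. Re-sown from its own harvest every season, such a population
evolves: genotypes that leave more offspring rise in frequency. For a
predominantly selfing cereal like winter wheat this is a nearly ideal
natural-selection experiment — there is no migration, mutation is
negligible on the time scale of interest, and the founding gene pool is
known exactly from the parents and the crossing records.

`ccpevol` implements the full inference chain needed to decide, from
marker genotypes sampled at a few generations, **whether allele-frequency
changes exceed what genetic drift can explain, and whether the selected
alleles act through measurable phenotypes**:

1. reconstruct the founding gene pool (*virtual founding population*),
2. recode multi-allelic SSR markers to biallelic form,
3. summarise diversity (Nei's gene diversity) and differentiation
   (Weir–Cockerham's $F_{ST}$) with bootstrap-over-loci intervals,
4. screen loci for differential selection with a heterozygosity-
   conditional $F_{ST}$ outlier scan against a simulated island-model
   null,
5. estimate the effective population size $N_e$ (an $F_{ST}$-based and a
   temporal estimator),
6. classify per-locus frequency changes against drift-null confidence
   bands, and
7. estimate additive allele effects on phenotypes in mixed and pure
   stands and correlate them with the frequency changes.

A forward-time simulator of CCPs with known truth (drift intensity,
selection coefficients, trait architecture) is part of the package and
backs every statistical claim with parameter-recovery tests.

## The virtual founding population

No seed of the original pooled population is assumed to survive. Its
genotypic composition is reconstructed from the parental genotypes and
the recorded number of F2 seeds each cross contributed: cross $(i,j)$
contributes

$$n_{ij} = \mathrm{round}\!\left(\frac{s_{ij}}{\sum s_{ij}}\, N_{virt}\right)$$

copies of its F1 heterozygote multilocus genotype to a virtual population
of nominal size $N_{virt} = 10{,}000$. Rounding is half-to-even and the
total is deliberately *not* re-normalised, so it may differ from
$N_{virt}$ by at most half the number of crosses — a transparent,
reproducible convention. Heterozygous parental calls are rejected by
default (parents are fixed inbred lines); an override uses the
first-listed allele. Expected allele frequencies are identical whether
the founders are represented as F1 heterozygotes or as segregating F2
seed, which is why the F1 representation is used.

## Marker recoding

Alleles observed in descendant samples but absent from every parent must
come from mutation, migration (pollen or seed contamination) or
genotyping error; they are removed record-wise at the affected locus
only. Each multi-allelic SSR locus is then collapsed to two alleles: the
most frequent allele in the virtual founding population versus the pool
of all others (`OTHER`). The recode map is derived from the founders
*once* and applied unchanged to every population and generation, so
frequencies remain comparable across time. Ties for the most frequent
allele (never observed in practice, but possible) are broken
lexicographically and logged in the recode map. SNP loci pass through
unchanged but receive a designated frequent-in-founder allele, giving
every locus a single reference allele for frequencies, drift bands and
effect signs.

## Diversity and differentiation

Gene diversity is the uncorrected $H_e = 1 - \sum_k p_k^2$, the expected
heterozygosity under Hardy–Weinberg equilibrium; the small-sample factor
$2n/(2n-1)$ is available behind the `correct` flag since some reference
implementations apply it. With hundreds of gene copies per sample the
difference is negligible; defaulting to the uncorrected form keeps the
identity with HWE heterozygosity exact.

Differentiation uses Weir and Cockerham's variance-components estimator
$\theta$ for diploid data with observed heterozygote counts — important
here because a selfing crop is far from HWE within populations, and the
$a$/$b$/$c$ decomposition absorbs the heterozygote deficit. Per-locus
estimates may be negative and are retained (truncation would bias
multilocus summaries); the multilocus estimate is the ratio of summed
components $\sum a / \sum(a+b+c)$, never the mean of per-locus ratios.
Confidence intervals are percentile bootstraps over loci (default 5,000
resamples) using the ratio-of-sums statistic; the percentile method is
assumption-free and reproducible under a fixed seed.

## The outlier scan

Drift alone produces $F_{ST}$ scatter, and its spread depends on
heterozygosity, so outlier detection must condition on $H_e$. The null
is generated by forward simulation of a finite island model (default
100 demes of 100 diploids) whose migration rate is calibrated through
the deme-count-corrected island relation

$$m = \frac{1/\theta^\ast - 1}{4 N \,(d/(d-1))^2}$$

so the expected equilibrium $\theta$ equals the target $\theta^\ast$
(the observed neutral multilocus value in the pipeline). Each of the
(default) 20,000 simulated loci starts from an ancestral frequency
uniform on (0.02, 0.98), runs 50 warm-up generations of drift plus
migration, and is then *sampled* exactly like the real data (genotype
counts in the sampled demes) and summarised with the same estimators.
A target so small that it would require $m > 0.5$ is a parameter error.
Calibration-to-target is the contract; the exact deme size and warm-up
are configurable and documented rather than hidden.

P-values are empirical and conditional: for a locus with observed
$(H_e, \theta)$, the p-value is the fraction of null loci within
$\pm 0.05$ of its $H_e$ (a sliding window, widened stepwise and logged
when it holds fewer than 100 null points) whose $\theta$ is at least as
large, computed with the $(r+1)/(n+1)$ convention so it is never exactly
zero. A locus is flagged as under differential selection when $p < 0.05$
*and* its $\theta$ exceeds the multilocus average; unflagged loci feed
the $N_e$ estimators, which assume neutrality. The simulated null
assumes random mating within demes; the observed heterozygote deficit of
a selfer enters through the estimator, not the null — a known
approximation shared with the standard implementations of this scan.

## Effective population size and drift bands

Two estimators are provided. The $F_{ST}$-based estimator inverts

$$N_e = \frac{t}{4\,\ln\!\frac{1}{1 - F_{ST}}}$$

with $t$ the generations of independent drift (8 for populations
separated at generation 2 and genotyped at generation 10); interval
bounds map through the same function with reversed order (larger
$F_{ST}$, smaller $N_e$). The temporal estimator uses the standardised
variance of frequency change between two sampled generations,
$F_c = (x-y)^2 / \left[(x+y)/2 - xy\right]$ averaged over loci, with the
sampling-plan-II correction
$N_e = t / \left[2\,(F_c - 1/(2S_0) - 1/(2S_t))\right]$; when the drift
signal does not exceed the sampling-noise correction the estimate is
undefined and the function says so rather than returning a negative
size.

**A calibration caveat that matters.** The $F_{ST}$ inversion above
assumes $E[F_{ST}] \approx t/(4N_e)$, but the Weir–Cockerham estimator
among populations that diverged $t$ generations ago is
ancestor-referenced, with $E[\hat\theta] = 1-(1-\tfrac{1}{2N_e})^t
\approx t/(2N_e)$ — verified in this package's test suite by direct
binomial-drift simulation. The two conventions differ by a factor of
two, so on simulated data with known truth the
$\hat\theta$-plus-inversion chain recovers roughly *half* the true
$N_e$, while the temporal estimator recovers it unbiasedly. Both
estimators are reported; treat their disagreement as expected behaviour
of the inherited formula rather than a data anomaly, and prefer the
temporal estimate when an absolute drift intensity is needed. The
inversion formula itself is kept in its published form because its
output is the convention the drift-band thresholds (below) are chosen
against.

Given $N_e$, the frequency of the reference allele after $t$ generations
of pure drift from founder frequency $p_{FND}$ is approximately normal
with variance $p_{FND}(1-p_{FND})\left[1-(1-\tfrac{1}{2N_e})^t\right]$;
the 95% band is $p_{FND} \pm 1.96\sqrt{\cdot}$, clipped to $[0,1]$. The
band is evaluated for a *pair* of bracketing sizes (default
$N_e \in \{150, 250\}$) rather than a single point estimate, so the
sensitivity of every call to the assumed drift intensity is visible. A
locus outside the band in the same direction in every population is the
signature of consistent (management-independent) selection; the
classification table carries a consistency summary. Note the variance
term appears under a square root: the half-width has frequency units.
Wright–Fisher simulation at $2N_e = 300$ gene copies confirms 95 ± 1%
empirical coverage.

## Additive allele effects

Mixed-stand effects come from single plants measured inside the
segregating population. For one locus and one trait the model is

$$y = \mu + m_j + t_k + (mt)_{jk} + e$$

with fixed homozygote allele class $m_j$ (heterozygotes are excluded at
the tested locus only), random trial, allele-by-trial and residual
terms; the class contrast is tested by an F-test with Satterthwaite
denominator degrees of freedom, and the additive effect of the reference
allele is half the fitted class difference. Singular fits (zero
estimated variance components, common with four trials) drop the
offending term and refit, down to an ordinary one-way model; the
reduction is recorded on the estimate.

Pure-stand effects use the parent varieties in replicated multi-trial
plots: stage one estimates variety LS-means (equal trial weights) from a
mixed model with random trial, block-in-trial and variety-by-trial
terms; stage two regresses the LS-means on the allele class. The
contrast between mixed- and pure-stand effect profiles is the lens for
individual-versus-population trade-offs: a trait can pay in competition
inside a mixture yet cost yield in a pure stand.

Frequency changes $\Delta p$ (founder to final generation, per location
and as the across-location mean — the "overall" column averages the
final-generation frequencies across locations before differencing) are
correlated with the effects over loci by Pearson's $r$, tested with
$t = r\sqrt{(L-2)/(1-r^2)}$ on $L-2$ degrees of freedom; grids carry
`*`, `**`, `***` at 0.05, 0.01, 0.001. Effect signs, $\Delta p$ signs
and the reference-allele designation are one convention: flipping the
designation at every locus flips all signs coherently and leaves every
correlation unchanged (tested end-to-end). Flipping a single locus
legitimately changes a centred correlation — it reflects one point
through the origin — which is why the designation is fixed once, in the
founders, and never per sample.

## The simulator: what it emulates and what it does not

Defaults mirror the motivating field design: 20 fully homozygous
parents; 93 crosses with strongly unequal F2 seed counts (mean 957,
range 37–2,569, drawn from a scaled Beta matched to that mean and
range); 20 SSR loci with 4 alleles each plus 8 biallelic functional loci
(labelled by the wheat height/phenology genes they emulate, wild-type
allele `wt`); four locations sharing the population up to generation 2
and evolving independently to generation 10; samples of 150/300/500
individuals at generations 3/6/10; selfing rate 0.98 (wheat outcrosses
a few percent; the exact trial value is unreported, so this is a
configurable default, not a measured one); census about 32,000 plants
but an effective size near 200.

Drift intensity is *imposed*, not emergent: each generation draws
$N_e^{target}(1+F)$ reproducing individuals, where $F$ is the
population's current inbreeding coefficient, so the number of
effectively independent transmitted gene copies is $2N_e^{target}$
regardless of the selfing rate. (Without the $1+F$ adjustment a selfed
population of $N$ reproducers carries only about $N$ independent copies
and drifts twice as fast as intended.) The test suite verifies the
realized variance of frequency change against the Wright–Fisher formula
within 10%. Selection enters through per-locus coefficients as
fecundity weights $\propto \exp(\sum s \cdot \mathrm{dosage})$ on the
reproducer draw; outcross partners are uniform; there is no mutation, no
migration, no linkage and no explicit light-competition mechanics —
phenotypic selection is emulated only through those per-locus
coefficients, so passing tests demonstrate statistical calibration, not
realism of the competitive dynamics. Phenotypes are additive (dosage of
the wild-type-labelled allele) plus random trial, block and interaction
effects and Gaussian residuals, for both single plants in mixed stands
and variety plots in pure stands.

## Numerical and design choices

* All randomness flows from one root seed (`run_config(rng_seed = )`),
  split deterministically per stage; a repeated run writes
  byte-identical machine-readable outputs.
* Missing genotype calls are complete-case per locus (excluded from
  numerator and denominator of every frequency).
* Loci monomorphic across the populations being compared are excluded
  from $\theta$ with a warning (their components are 0/0).
* Loci fixed identically in both samples of a temporal comparison are
  excluded from $F_c$ (0/0), with a message.
* $N_e$ values are reported at full precision and rounded only in
  printed summaries.
* Problem sizes in the test suite (census 800–4,000, 10–28 loci, 15–50
  replicates) are chosen to give each statistical check a comfortable
  signal-to-noise margin at interactive runtimes; the pipeline defaults
  remain the full-size design.

## Known limitations

* The island-model null assumes random mating within demes; for a
  selfer the conditional p-values are approximate (shared with the
  standard tools for this scan).
* The $F_{ST}$-based $N_e$ inherits the factor-of-two convention
  mismatch discussed above; the temporal estimator is the calibrated
  one.
* No linkage: SSR loci on the same chromosome arm as a selected gene
  will hitchhike in real data but drift freely in the simulator.
* Temporal sampling is plan II (samples drawn from the population
  whose size is being estimated) with the standard Nei–Tajima $F_c$;
  other plans/variants are not implemented.
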