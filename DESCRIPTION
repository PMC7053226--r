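Package: ccpevol
Title: Natural-Selection Scans for Evolving Composite Cross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting natural selection in evolving
    composite cross populations (CCPs) of predominantly selfing crops.
    Builds a virtual founding population from parental genotypes and a
    crossing scheme, recodes multi-allelic SSR markers to biallelic form,
    and estimates gene diversity (Nei's expected heterozygosity), Weir and
    Cockerham's F_ST with bootstrap-over-loci confidence intervals,
    effective population size (F_ST-based and temporal methods), and
    drift-null confidence bands for per-locus allele-frequency change.
    Includes an FDIST-style F_ST outlier scan against a simulated
    finite-island neutral null, mixed-model estimation of additive allele
    effects in mixed and pure crop stands, and a forward-time simulator of
    composite cross populations with known-truth drift and selection for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
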