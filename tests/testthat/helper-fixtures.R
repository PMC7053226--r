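# Fixtures built in code: small panels, genotype tables and simulation
# settings shared across test files.

tiny_panel <- function() {
  locus_panel(c("locA", "locB"), c("SSR", "SNP"),
              list(c("150", "152", "154"), c("wt", "mut")))
}

# records for a few individuals at the tiny panel
tiny_records <- function() {
  data.frame(
    individual_id = rep(c("i1", "i2"), each = 2),
    population = "P1", generation = 3L, location = "X",
    locus_id = rep(c("locA", "locB"), 2),
    allele_a = c("150", "wt", "152", "mut"),
    allele_b = c("152", "wt", "152", "mut"),
    stringsAsFactors = FALSE)
}

# genotype table with given per-population genotype counts at one
# biallelic locus: counts = list(P1 = c(AA, Aa, aa), ...)
counts_table <- function(counts, locus = "loc1",
                         alleles = c("A", "a")) {
  rows <- list()
  for (pop in names(counts)) {
    k <- counts[[pop]]
    gt <- c(rep(list(c(alleles[1], alleles[1])), k[1]),
            rep(list(c(alleles[1], alleles[2])), k[2]),
            rep(list(c(alleles[2], alleles[2])), k[3]))
    for (i in seq_along(gt))
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = sprintf("%s_%03d", pop, i), population = pop,
        generation = 1L, location = pop, locus_id = locus,
        allele_a = gt[[i]][1], allele_b = gt[[i]][2],
        stringsAsFactors = FALSE)
  }
  panel <- locus_panel(locus, "SNP", list(alleles),
                       frequent_allele = alleles[1])
  genotype_table(do.call(rbind, rows), panel)
}

# Independent textbook oracle for Weir-Cockerham theta: mean-squares
# (ANOVA) formulation, algebra written separately from the package's
# variance-components path. n, p, h as in the estimator.
wc_theta_oracle <- function(n, p, h) {
  r <- length(n)
  S1 <- sum(n)
  nc <- (S1 - sum(n^2) / S1) / (r - 1)
  pbar <- sum(n * p) / S1
  MSP <- sum(2 * n * (p - pbar)^2) / (r - 1)
  MSI <- sum(2 * n * p * (1 - p) - n * h / 2) / (S1 - r)
  MSG <- sum(n * h / 2) / S1
  (MSP - MSI) / (MSP + (nc - 1) * MSI + nc * MSG)
}

# Multi-population dataset drifted t generations from a common ancestral
# pool (binomial Wright-Fisher, HWE genotype sampling): the quick null
# generator for estimator calibration tests.
drifted_dataset <- function(n_pops = 4, ne = 200, t = 8, n_loci = 20,
                            n = 150, p0 = NULL, seed = NULL,
                            fis = 0) {
  if (!is.null(seed)) set.seed(seed)
  p0 <- p0 %||% stats::runif(n_loci, 0.15, 0.85)
  loci <- sprintf("loc%02d", seq_len(n_loci))
  rows <- list()
  for (ipop in seq_len(n_pops)) {
    p <- p0
    for (g in seq_len(t)) p <- stats::rbinom(n_loci, 2 * ne, p) / (2 * ne)
    pop <- sprintf("pop%d", ipop)
    for (j in seq_len(n_loci)) {
      pAA <- p[j]^2 + fis * p[j] * (1 - p[j])
      pAa <- 2 * p[j] * (1 - p[j]) * (1 - fis)
      g3 <- stats::rmultinom(1, n, c(pAA, pAa, 1 - pAA - pAa))[, 1]
      a1 <- c(rep("A", g3[1] + g3[2]), rep("a", g3[3]))
      a2 <- c(rep("A", g3[1]), rep("a", g3[2] + g3[3]))
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = sprintf("%s_%03d", pop, seq_len(n)),
        population = pop, generation = t, location = pop,
        locus_id = loci[j], allele_a = a1, allele_b = a2,
        stringsAsFactors = FALSE)
    }
  }
  panel <- locus_panel(loci, "SNP", rep(list(c("A", "a")), n_loci),
                       frequent_allele = "A")
  genotype_table(do.call(rbind, rows), panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small, fast simulator settings used in several files; any sim_params
# argument can be overridden
small_sim_params <- function(...) {
  args <- list(n_parents = 10, n_crosses = 20, census_size = 1200,
               target_Ne = 150, n_loci_ssr = 8, n_loci_snp = 4,
               sample_sizes = c("3" = 80, "6" = 80, "10" = 120),
               trait_model = list(
                 height = list(mu = 100,
                               effects = c("Rht-B1" = 4, "Rht-D1" = 5),
                               residual_sd = 8, trial_sd = 5,
                               interaction_sd = 2),
                 heading_date = list(mu = 152, effects = c("Ppd-A1" = 2),
                                     residual_sd = 4, trial_sd = 3,
                                     interaction_sd = 1)))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_params, args)
}
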