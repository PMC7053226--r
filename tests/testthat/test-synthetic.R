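test_that("parents are homozygous, segregating and reproducible", {
  p <- small_sim_params()
  par <- make_parents(p, seed = 1)
  r <- par$records
  expect_true(all(r$allele_a == r$allele_b))
  expect_equal(length(unique(r$individual_id)), p$n_parents)
  # every locus segregates
  n_alleles <- tapply(r$allele_a, r$locus_id, function(a)
    length(unique(a)))
  expect_true(all(n_alleles >= 2))
  # determinism
  expect_identical(make_parents(p, seed = 1)$records, r)

  # 2 parents, 1 SNP locus: forced segregation
  p2 <- sim_params(n_parents = 2, n_crosses = 1, n_loci_ssr = 0,
                   n_loci_snp = 1, census_size = 100, target_Ne = 50,
                   sample_sizes = c("3" = 10), n_generations = 3,
                   trait_model = list())
  par2 <- make_parents(p2, seed = 3)
  expect_equal(sort(unique(par2$records$allele_a)), c("mut", "wt"))
})

test_that("crossing schemes respect the seed-count distribution", {
  p <- sim_params(trait_model = list())        # full default design
  sch <- make_crossing_scheme(p, seed = 2)
  expect_equal(nrow(sch), 93)
  expect_true(all(sch$seed_count >= 37 & sch$seed_count <= 2569))
  expect_lt(abs(mean(sch$seed_count) - 957) / 957, 0.1)
  expect_false(any(duplicated(paste(sch$parent_i, sch$parent_j))))

  # exhaustive case: every pair of 20 parents once
  p_all <- sim_params(n_crosses = 190, trait_model = list())
  sch_all <- make_crossing_scheme(p_all, seed = 3)
  expect_equal(nrow(sch_all), choose(20, 2))

  # degenerate distribution
  p_deg <- sim_params(seed_count_mean = 100, seed_count_min = 100,
                      seed_count_max = 100, trait_model = list())
  expect_true(all(make_crossing_scheme(p_deg, seed = 4)$seed_count == 100))

  expect_error(sim_params(n_parents = 5, n_crosses = 11), "pairs")
})

test_that("selfing halves heterozygosity per generation in expectation", {
  # selfing_rate = 1, no selection, Ne = census: pure selfing decay
  p <- sim_params(n_parents = 6, n_crosses = 6, census_size = 150,
                  target_Ne = 150, selfing_rate = 1, n_loci_ssr = 4,
                  n_loci_snp = 0, n_locations = 1, n_generations = 4,
                  separation_generation = 2, sample_sizes = c("4" = 10),
                  trait_model = list())
  par <- make_parents(p, seed = 5)
  sch <- make_crossing_scheme(p, seed = 6)
  set.seed(77)
  ratios <- replicate(120, {
    sim <- simulate_generations(par, sch, p,
                                seed = sample.int(1e8, 1))
    tr <- sim$truth
    # heterozygosity proxy from truth: 1 - sum(freq^2) is the expected
    # het; realized observed het must be tracked through genotypes
    g <- sim$genotypes$records
    mean(g$allele_a != g$allele_b)
  })
  # F2 of a biallelic cross starts at Hobs = 0.5 (generation 1), then
  # halving for 3 generations: expected ~ 0.5 / 8 at sampled gen 4
  # (allowing founder-mixture dilution, compare on a broad band)
  h <- mean(ratios)
  expect_gt(h, 0.02)
  expect_lt(h, 0.12)
})

test_that("neutral drift matches the Wright-Fisher variance formula", {
  # many replicate populations via independently evolving locations
  p <- sim_params(n_parents = 10, n_crosses = 20, census_size = 800,
                  target_Ne = 100, n_loci_ssr = 6, n_loci_snp = 0,
                  n_locations = 60, n_generations = 5,
                  separation_generation = 2, sample_sizes = c("5" = 5),
                  trait_model = list())
  par <- make_parents(p, seed = 7)
  sch <- make_crossing_scheme(p, seed = 8)
  sim <- simulate_generations(par, sch, p, seed = 9)
  tr <- sim$truth
  sh <- tr[tr$location == "shared" & tr$generation == 2, ]
  fin <- tr[tr$location != "shared" & tr$generation == 5, ]
  t_drift <- 3
  ratios <- c()
  for (l in unique(sh$locus_id)) for (al in unique(
    sh$allele[sh$locus_id == l])) {
    p2 <- sh$freq[sh$locus_id == l & sh$allele == al]
    if (p2 < 0.1 || p2 > 0.9) next
    p5 <- fin$freq[fin$locus_id == l & fin$allele == al]
    expv <- p2 * (1 - p2) * (1 - (1 - 1 / 200)^t_drift)
    ratios <- c(ratios, mean((p5 - p2)^2) / expv)
  }
  expect_gt(length(ratios), 2)
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("positive selection raises the favoured allele frequency", {
  # census much larger than the reproducer count, so fecundity-weighted
  # sampling can express the selection differential
  base <- function(s) sim_params(
    n_parents = 8, n_crosses = 12, census_size = 2400, target_Ne = 100,
    n_loci_ssr = 2, n_loci_snp = 1, n_locations = 30, n_generations = 6,
    separation_generation = 2, sample_sizes = c("6" = 5),
    selection_coefficients = if (s > 0) c("Rht-B1" = s) else numeric(),
    trait_model = list())
  run_mean_final <- function(s, seed) {
    p <- base(s)
    par <- make_parents(p, seed = 100)
    sch <- make_crossing_scheme(p, seed = 101)
    sim <- simulate_generations(par, sch, p, seed = seed)
    tr <- sim$truth
    fin <- tr[tr$location != "shared" & tr$generation == 6 &
                tr$locus_id == "Rht-B1" & tr$allele == "wt", ]
    sh <- tr[tr$location == "shared" & tr$generation == 2 &
               tr$locus_id == "Rht-B1" & tr$allele == "wt", ]
    c(mean(fin$freq), sh$freq)
  }
  sel <- run_mean_final(0.3, 11)
  neu <- run_mean_final(0, 12)
  # selection: mean final frequency exceeds the shared starting value
  expect_gt(sel[1], sel[2] + 0.02)
  # neutrality: no systematic displacement
  expect_lt(abs(neu[1] - neu[2]), 0.05)
})

test_that("no allele absent from the parents ever appears", {
  p <- small_sim_params()
  par <- make_parents(p, seed = 13)
  sch <- make_crossing_scheme(p, seed = 14)
  sim <- simulate_generations(par, sch, p, seed = 15)
  out <- filter_nonparental_alleles(sim$genotypes, par)
  expect_equal(sum(out$report$n_removed), 0L)
  expect_true(all(sim$truth$freq >= 0 & sim$truth$freq <= 1))
})

test_that("phenotype generator honours the additive model exactly", {
  p <- small_sim_params()
  par <- make_parents(p, seed = 16)
  sch <- make_crossing_scheme(p, seed = 17)
  sim <- simulate_generations(par, sch, p, seed = 18)

  # zero effects, zero noise: all values equal mu
  p0 <- p
  p0$trait_model <- list(flat = list(mu = 42, effects = numeric(),
                                     residual_sd = 0, trial_sd = 0,
                                     interaction_sd = 0))
  tr0 <- simulate_phenotypes(sim, p0, seed = 19)
  expect_true(all(abs(tr0$value - 42) < 1e-12))

  # one locus, effect 5 per favoured copy, no noise: class means differ
  # by 10 between the homozygote classes
  p1 <- p
  p1$trait_model <- list(h = list(mu = 100, effects = c("Rht-B1" = 5),
                                  residual_sd = 0, trial_sd = 0,
                                  interaction_sd = 0))
  tr1 <- simulate_phenotypes(sim, p1, seed = 20)
  mix <- tr1[tr1$stand == "mixed_single_plant", ]
  g <- sim$genotypes$records
  g <- g[g$locus_id == "Rht-B1" & g$individual_id %in% mix$unit_id, ]
  hom_wt <- g$individual_id[g$allele_a == "wt" & g$allele_b == "wt"]
  hom_mut <- g$individual_id[g$allele_a == "mut" & g$allele_b == "mut"]
  expect_equal(mean(mix$value[mix$unit_id %in% hom_wt]) -
                 mean(mix$value[mix$unit_id %in% hom_mut]), 10,
               tolerance = 1e-9)

  # unknown effect locus is an error
  p_bad <- p
  p_bad$trait_model <- list(h = list(mu = 0, effects = c(nope = 1),
                                     residual_sd = 1, trial_sd = 1))
  expect_error(simulate_phenotypes(sim, p_bad, seed = 21), "missing locus")
})

test_that("noisy class-mean differences recover the simulated effect", {
  p <- small_sim_params(sample_sizes = c("10" = 500), census_size = 1500)
  p$trait_model <- list(h = list(mu = 100, effects = c("Rht-B1" = 5),
                                 residual_sd = 1, trial_sd = 0,
                                 interaction_sd = 0))
  par <- make_parents(p, seed = 22)
  sch <- make_crossing_scheme(p, seed = 23)
  sim <- simulate_generations(par, sch, p, seed = 24)
  tr <- simulate_phenotypes(sim, p, seed = 25)
  mix <- tr[tr$stand == "mixed_single_plant", ]
  g <- sim$genotypes$records
  g <- g[g$locus_id == "Rht-B1" & g$individual_id %in% mix$unit_id, ]
  hom_wt <- g$individual_id[g$allele_a == "wt" & g$allele_b == "wt"]
  hom_mut <- g$individual_id[g$allele_a == "mut" & g$allele_b == "mut"]
  a <- mix$value[mix$unit_id %in% hom_wt]
  b <- mix$value[mix$unit_id %in% hom_mut]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs((mean(a) - mean(b)) - 10), 3 * se + 1e-9)
})
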