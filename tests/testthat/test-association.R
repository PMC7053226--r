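# genotypes + traits for a hand-built two-class, multi-trial design
balanced_fixture <- function(n_per_class = 6, trials = c("T1", "T2"),
                             mean_other = 80, mean_freq = 90,
                             noise_sd = 0, seed = 1) {
  set.seed(seed)
  ids_f <- sprintf("f%02d", seq_len(n_per_class))
  ids_o <- sprintf("o%02d", seq_len(n_per_class))
  panel <- locus_panel("loc1", "SNP", list(c("A", "a")),
                       frequent_allele = "A")
  rec <- data.frame(
    individual_id = c(ids_f, ids_o), population = "P", generation = 6L,
    location = "X", locus_id = "loc1",
    allele_a = rep(c("A", "a"), each = n_per_class),
    allele_b = rep(c("A", "a"), each = n_per_class),
    stringsAsFactors = FALSE)
  gt <- genotype_table(rec, panel)
  rows <- expand.grid(unit_id = c(ids_f, ids_o), trial = trials,
                      stringsAsFactors = FALSE)
  rows$stand <- "mixed_single_plant"
  rows$trait <- "height"
  rows$value <- ifelse(rows$unit_id %in% ids_f, mean_freq, mean_other) +
    rnorm(nrow(rows), 0, noise_sd)
  # one observation per plant: plants replicated across trials get
  # distinct unit ids per trial in real data; keep it simple by treating
  # trial replicates as repeated measures of the class
  rows$unit_id <- paste0(rows$unit_id)
  list(gt = gt, traits = trait_table(rows))
}

test_that("mixed-stand effect is half the class difference in balanced data", {
  fx <- balanced_fixture()
  e <- mixed_stand_effect(fx$traits, fx$gt, "loc1", "height")
  expect_equal(e$additive_effect, 5, tolerance = 1e-8)
  expect_equal(e$stand, "mixed")

  # identical class means: effect 0, p near 1
  fx0 <- balanced_fixture(mean_other = 85, mean_freq = 85, noise_sd = 1,
                          seed = 2)
  e0 <- mixed_stand_effect(fx0$traits, fx0$gt, "loc1", "height")
  expect_lt(abs(e0$additive_effect), 1)
  expect_gt(e0$p_value, 0.05)

  # a missing homozygote class yields a reasoned missing estimate
  fx1 <- balanced_fixture()
  tr1 <- fx1$traits[grepl("^f", fx1$traits$unit_id), ]
  e1 <- mixed_stand_effect(trait_table(tr1), fx1$gt, "loc1", "height")
  expect_true(is.na(e1$additive_effect))
  expect_match(e1$note, "under-represented")
})

test_that("mixed-stand effect recovers simulator truth with noise", {
  p <- small_sim_params(sample_sizes = c("6" = 250, "10" = 250),
                        census_size = 1500)
  p$trait_model <- list(height = list(mu = 100, effects = c("Rht-B1" = 4),
                                      residual_sd = 5, trial_sd = 3,
                                      interaction_sd = 0.5))
  par <- make_parents(p, seed = 31)
  sch <- make_crossing_scheme(p, seed = 32)
  sim <- simulate_generations(par, sch, p, seed = 33)
  fnd <- build_virtual_fnd(sch, par, 10000)
  gt <- collapse_to_biallelic(sim$genotypes, fnd)
  tr <- simulate_phenotypes(sim, p, seed = 34)
  e <- mixed_stand_effect(tr, gt, "Rht-B1", "height")
  # effect is defined for the frequent-in-FND allele; the simulator
  # defines it for wt: sign maps accordingly
  ref <- gt$panel$frequent_allele[match("Rht-B1", gt$panel$locus_id)]
  truth <- if (ref == "wt") 4 else -4
  expect_lt(abs(e$additive_effect - truth), 3 * e$se)
  expect_lt(e$p_value, 0.01)
  expect_gt(e$df_den, 1)
})

test_that("pure-stand effect is exact on noiseless variety data", {
  p <- small_sim_params()
  p$trait_model <- list(h = list(mu = 50, effects = c("Rht-D1" = 2),
                                 residual_sd = 0, trial_sd = 0,
                                 interaction_sd = 0))
  par <- make_parents(p, seed = 41)
  sch <- make_crossing_scheme(p, seed = 42)
  sim <- simulate_generations(par, sch, p, seed = 43)
  tr <- simulate_phenotypes(sim, p, seed = 44)
  fnd <- build_virtual_fnd(sch, par, 10000)
  parc <- collapse_to_biallelic(par, attr(
    collapse_to_biallelic(sim$genotypes, fnd), "recode_map"))
  e <- pure_stand_effect(tr, parc, "Rht-D1", "h")
  ref <- parc$panel$frequent_allele[match("Rht-D1", parc$panel$locus_id)]
  truth <- if (ref == "wt") 2 else -2
  expect_equal(e$additive_effect, truth, tolerance = 1e-9)

  # all varieties in one class: reasoned missing value
  pr <- parc
  pr$records$allele_a[pr$records$locus_id == "Rht-D1"] <- "wt"
  pr$records$allele_b[pr$records$locus_id == "Rht-D1"] <- "wt"
  e1 <- pure_stand_effect(tr, pr, "Rht-D1", "h")
  expect_true(is.na(e1$additive_effect))
  expect_match(e1$note, "class")
})

test_that("correlation helpers use df = L - 2 and match the t identity", {
  set.seed(51)
  L <- 28
  a <- stats::setNames(rnorm(L), sprintf("l%02d", 1:L))
  b <- 2 * a + rnorm(L, 0, 0.5)
  ct <- correlate_dp_vs_effect(a, b, "height", "overall")
  expect_equal(ct$df, 26)
  # t identity: p from t = r*sqrt(df/(1-r^2)) matches cor.test
  ref <- stats::cor.test(a, b)
  expect_equal(ct$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(ct$r, unname(ref$estimate), tolerance = 1e-12)

  expect_equal(correlate_effect_vs_effect(a, a)$r, 1)
  expect_equal(correlate_effect_vs_effect(a, -a)$r, -1)
  # proportional vectors: r = 1
  expect_equal(correlate_dp_vs_effect(a, 3 * a)$r, 1, tolerance = 1e-12)
  # zero variance is a reasoned missing value
  z <- stats::setNames(rep(1, L), names(a))
  expect_true(is.na(correlate_dp_vs_effect(a, z)$r))
})

test_that("flipping the designated frequent allele flips signs but not correlations", {
  p <- small_sim_params(sample_sizes = c("6" = 200, "10" = 200))
  par <- make_parents(p, seed = 61)
  sch <- make_crossing_scheme(p, seed = 62)
  sim <- simulate_generations(par, sch, p, seed = 63)
  fnd <- build_virtual_fnd(sch, par, 10000)
  gt <- collapse_to_biallelic(sim$genotypes, fnd)
  fnd_c <- collapse_to_biallelic(fnd, attr(gt, "recode_map"))
  tr <- simulate_phenotypes(sim, p, seed = 64)
  freqs <- allele_frequencies(gt)
  fnd_freq <- allele_frequencies(fnd_c)

  # flip the designated reference allele at every locus: delta-p and
  # effects all change sign coherently, so correlations are unchanged
  # (flipping a single locus reflects only that point through the
  # origin, which legitimately changes a centred correlation)
  flip <- function(g) {
    for (j in seq_len(nrow(g$panel))) {
      lab <- g$panel$allele_labels[[j]]
      g$panel$frequent_allele[j] <-
        setdiff(lab, g$panel$frequent_allele[j])[1]
    }
    g
  }
  gt_f <- flip(gt)
  fnd_f <- flip(fnd_c)
  freqs_f <- allele_frequencies(gt_f)
  fnd_freq_f <- allele_frequencies(fnd_f)

  flip_locus <- "Rht-B1"
  sel <- freqs$locus_id == flip_locus
  expect_equal(freqs_f$p[sel], 1 - freqs$p[sel])

  e <- mixed_stand_effect(tr, gt, flip_locus, "height")
  e_f <- mixed_stand_effect(tr, gt_f, flip_locus, "height")
  expect_equal(e_f$additive_effect, -e$additive_effect, tolerance = 1e-6)

  eff <- effects_table(tr, gt, trait_names = "height", stand = "mixed")
  eff_f <- effects_table(tr, gt_f, trait_names = "height", stand = "mixed")
  mk_dp <- function(fr, ff) {
    p10 <- fr[fr$generation == 10, ]
    dp <- tapply(p10$p, p10$locus_id, mean) -
      stats::setNames(ff$p, ff$locus_id)[names(tapply(p10$p,
                                                      p10$locus_id, mean))]
    dp
  }
  dp <- mk_dp(freqs, fnd_freq)
  dp_f <- mk_dp(freqs_f, fnd_freq_f)
  ev <- stats::setNames(eff$additive_effect, eff$locus_id)
  ev_f <- stats::setNames(eff_f$additive_effect, eff_f$locus_id)
  ok <- names(ev)[!is.na(ev) & !is.na(ev_f[names(ev)])]
  r1 <- correlate_dp_vs_effect(dp[ok], ev[ok])$r
  r2 <- correlate_dp_vs_effect(dp_f[ok], ev_f[ok])$r
  expect_equal(r1, r2, tolerance = 1e-8)
})
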