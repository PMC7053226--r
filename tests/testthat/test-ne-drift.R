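test_that("F_ST-based Ne reproduces the published worked triple", {
  expect_equal(round(ne_from_fst(0.009, 8)$point), 221)
  expect_equal(round(ne_from_fst(0.013, 8)$point), 153)
  expect_equal(round(ne_from_fst(0.006, 8)$point), 332)
})

test_that("Ne-from-F_ST round trips and is monotone", {
  for (ne in c(10, 100, 1500, 1e5, 1e6)) {
    fst <- 1 - exp(-8 / (4 * ne))
    expect_equal(ne_from_fst(fst, 8)$point, ne, tolerance = 1e-9)
  }
  f <- seq(0.001, 0.2, length.out = 30)
  est <- vapply(f, function(x) ne_from_fst(x, 8)$point, 1)
  expect_true(all(diff(est) < 0))

  expect_error(ne_from_fst(0, 8), "non-positive")
  expect_error(ne_from_fst(-0.01, 8), "non-positive")
  expect_error(ne_from_fst(1, 8), "< 1")
})

test_that("Ne interval maps from the F_ST interval with reversed bounds", {
  fake <- structure(list(fst_multilocus = 0.009, ci_low = 0.006,
                         ci_high = 0.013),
                    class = "differentiation_result")
  est <- ne_from_fst(fake, 8)
  expect_equal(round(est$point), 221)
  expect_equal(round(est$ci_low), 153)   # upper F_ST -> lower Ne
  expect_equal(round(est$ci_high), 332)
})

test_that("temporal Fc follows the standardised-variance formula", {
  x <- c(l1 = 0.5, l2 = 0.3)
  expect_equal(as.numeric(temporal_fc(x, x)), 0)
  fc <- temporal_fc(c(l1 = 0.5), c(l1 = 0.7))
  expect_equal(as.numeric(fc), 0.04 / (0.6 - 0.35))   # 0.16
  # fixed-in-both locus is excluded as 0/0
  expect_message(
    fc2 <- temporal_fc(c(l1 = 0.5, l2 = 1), c(l1 = 0.7, l2 = 1)),
    "excluded")
  expect_equal(as.numeric(fc2), 0.16)
})

test_that("temporal Ne applies the sampling-plan correction", {
  est <- ne_temporal(0.05, 8, 150, 150)
  expect_equal(est$point, 8 / (2 * (0.05 - 1 / 300 - 1 / 300)),
               tolerance = 1e-12)
  expect_equal(round(est$point, 1), 92.3)
  # infinite samples: correction vanishes
  expect_equal(ne_temporal(0.04, 8, 1e9, 1e9)$point, 100, tolerance = 1e-4)
  # drift signal at or below sampling noise is an error
  expect_error(ne_temporal(1 / 300 + 1 / 300, 8, 150, 150), "sampling noise")
})

test_that("drift band has the closed-form half width and degenerate limits", {
  b <- drift_ci(0.5, 150, 10)
  half <- 1.96 * sqrt(0.25 * (1 - (1 - 1 / 300)^10))
  expect_equal(b$band_high - b$band_low, 2 * half, tolerance = 1e-4)
  expect_equal(round(half, 3), 0.178)

  # no drift in the infinite-size limit; absorbed at 0/1
  b_inf <- drift_ci(0.3, 1e12, 10)
  expect_equal(b_inf$band_low, 0.3, tolerance = 1e-5)
  expect_equal(b_inf$band_high, 0.3, tolerance = 1e-5)
  expect_equal(unlist(drift_ci(0, 150, 10)), c(band_low = 0, band_high = 0))
  expect_equal(unlist(drift_ci(1, 150, 10)), c(band_low = 1, band_high = 1))

  # monotone: wider with t, narrower with Ne
  w <- function(ne, t) {
    b <- drift_ci(0.5, ne, t)
    b$band_high - b$band_low
  }
  expect_true(all(diff(vapply(1:10, function(t) w(200, t), 1)) > 0))
  expect_true(all(diff(vapply(c(50, 100, 200, 400),
                              function(ne) w(ne, 8), 1)) < 0))
})

test_that("selection flags classify against the drift band", {
  fnd <- data.frame(population = "FND", generation = 0L,
                    locus_id = c("l1", "l2"), p = c(0.5, 0.8),
                    n_obs = 20000L, stringsAsFactors = FALSE)
  obs <- data.frame(population = rep(c("P1", "P2"), each = 2),
                    generation = 10L, locus_id = rep(c("l1", "l2"), 2),
                    p = c(0.5, 0.8, 0.5, 0.8), n_obs = 300L,
                    stringsAsFactors = FALSE)
  fl <- flag_selection(obs, fnd, ne_values = c(150, 250))
  expect_true(all(fl$status == "inside"))
  expect_equal(nrow(fl), 2 * 2 * 2)

  # a frequency far outside the band in every population
  obs2 <- obs
  obs2$p[obs2$locus_id == "l1"] <- 0.98
  fl2 <- flag_selection(obs2, fnd, ne_values = 150)
  expect_true(all(fl2$status[fl2$locus_id == "l1"] == "above"))
  cons <- attr(fl2, "consistent")
  expect_equal(cons$locus_id, "l1")
  expect_equal(cons$direction, "above")
})

test_that("drift-band coverage matches the nominal level on neutral runs", {
  # binomial Wright-Fisher trajectories, band computed by the package
  set.seed(17)
  ne <- 150; t <- 10; p0 <- 0.5; reps <- 4000
  p <- rep(p0, reps)
  for (g in seq_len(t)) p <- rbinom(reps, 2 * ne, p) / (2 * ne)
  b <- drift_ci(p0, ne, t, 0.95)
  cov <- mean(p >= b$band_low & p <= b$band_high)
  expect_gt(cov, 0.93)
  expect_lt(cov, 0.97)
})

test_that("delta-p correlations use df = L - 2 and detect identity", {
  set.seed(23)
  L <- 28
  loci <- sprintf("l%02d", 1:L)
  fnd <- data.frame(population = "FND", generation = 0L, locus_id = loci,
                    p = runif(L, 0.2, 0.8), n_obs = 20000L,
                    stringsAsFactors = FALSE)
  shift <- runif(L, -0.1, 0.1)
  obs <- do.call(rbind, lapply(c("P1", "P2"), function(pop)
    data.frame(population = pop, generation = 10L, locus_id = loci,
               p = pmin(1, pmax(0, fnd$p + shift)), n_obs = 300L,
               stringsAsFactors = FALSE)))
  dc <- delta_p_correlation(obs, fnd)
  expect_equal(dc$r, 1, tolerance = 1e-12)
  expect_equal(dc$df, L - 2)        # 26 for the full 28-locus panel
  expect_equal(dim(attr(dc, "r_matrix")), c(2, 2))

  # independent neutral populations: |r| rarely beyond the 5% critical value
  hits <- replicate(200, {
    obs_i <- do.call(rbind, lapply(c("P1", "P2"), function(pop)
      data.frame(population = pop, generation = 10L, locus_id = loci,
                 p = pmin(1, pmax(0, fnd$p + runif(L, -0.1, 0.1))),
                 n_obs = 300L, stringsAsFactors = FALSE)))
    delta_p_correlation(obs_i, fnd)$p_value < 0.05
  })
  expect_lt(mean(hits), 0.12)
})
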