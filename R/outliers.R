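#' Simulate the neutral F_ST null distribution (finite island model)
#'
#' Forward-simulates independent neutral loci in a finite island model
#' whose migration rate is calibrated, through the island-model relation
#' corrected for the number of demes, so the expected equilibrium theta
#' equals `target_fst`:
#' `m = (1/target - 1) / (4 * deme_size * (d/(d-1))^2)`. Each locus starts
#' from an ancestral frequency drawn uniform on (0.02, 0.98), drifts with
#' migration for `n_warmup` generations, and is then sampled (genotype
#' counts under within-deme Hardy-Weinberg proportions) in
#' `n_sampled_demes` demes; expected heterozygosity of the pooled sample
#' and Weir-Cockerham theta are computed with the same estimators as the
#' observed data, giving the conditional (He, theta) null cloud.
#'
#' @param target_fst expected neutral theta, strictly inside (0, 1); must
#'   be reachable with a migration rate in (0, 0.5].
#' @param n_sims number of simulated loci (default 20000).
#' @param n_demes islands in the model (default 100).
#' @param n_sampled_demes demes genotyped per locus (default 4, matching a
#'   four-location design).
#' @param sample_size individuals sampled per deme (default 150).
#' @param deme_size diploid individuals per deme (default 100).
#' @param n_warmup drift-migration generations before sampling
#'   (default 50).
#' @param seed RNG seed.
#' @return a `null_cloud` data frame with columns `he` and `fst`;
#'   settings in `attr(x, "settings")`.
#' @export
simulate_null_fst <- function(target_fst, n_sims = 20000, n_demes = 100,
                              n_sampled_demes = 4, sample_size = 150,
                              deme_size = 100, n_warmup = 50, seed = NULL) {
  stopifnot(n_sampled_demes <= n_demes, n_sampled_demes >= 2)
  if (!is.numeric(target_fst) || target_fst <= 0 || target_fst >= 1)
    stop_ccp("simulate_null_fst: target_fst must be inside (0, 1)")
  a <- (n_demes / (n_demes - 1))^2
  m <- (1 / target_fst - 1) / (4 * deme_size * a)
  if (m <= 0 || m > 0.5)
    stop_ccp(sprintf(
      "simulate_null_fst: target_fst %.4g needs migration rate %.4g outside (0, 0.5] for %d demes of size %d",
      target_fst, m, n_demes, deme_size))
  with_seed(seed, {
    p0 <- stats::runif(n_sims, 0.02, 0.98)
    P <- matrix(p0, nrow = n_sims, ncol = n_demes)
    two_n <- 2L * deme_size
    for (g in seq_len(n_warmup)) {
      pmig <- (1 - m) * P + m * rowMeans(P)
      P <- matrix(stats::rbinom(length(pmig), two_n, pmig) / two_n,
                  nrow = n_sims)
    }
    # sample genotypes in the first n_sampled_demes demes (demes are
    # exchangeable); HWE genotype counts within demes
    k <- n_sampled_demes
    Ps <- P[, seq_len(k), drop = FALSE]
    nAA <- matrix(stats::rbinom(n_sims * k, sample_size, Ps^2),
                  nrow = n_sims)
    pq <- 2 * Ps * (1 - Ps)
    cond <- ifelse(Ps < 1, pq / (1 - Ps^2), 0)
    nAa <- matrix(stats::rbinom(n_sims * k, sample_size - nAA,
                                pmin(1, cond)), nrow = n_sims)
    phat <- (2 * nAA + nAa) / (2 * sample_size)
    hhat <- nAa / sample_size
    # Weir-Cockerham components per simulated locus (equal sample sizes)
    theta <- he <- rep(NA_real_, n_sims)
    nvec <- rep(sample_size, k)
    for (i in seq_len(n_sims)) {
      comp <- wc_components(nvec, phat[i, ], hhat[i, ])
      tot <- sum(comp)
      theta[i] <- if (is.finite(tot) && tot != 0) comp[["a"]] / tot else NA
      pbar <- mean(phat[i, ])
      he[i] <- 1 - pbar^2 - (1 - pbar)^2
    }
    out <- data.frame(he = he, fst = theta)
    attr(out, "settings") <- list(target_fst = target_fst, n_sims = n_sims,
                                  n_demes = n_demes,
                                  n_sampled_demes = n_sampled_demes,
                                  sample_size = sample_size,
                                  deme_size = deme_size,
                                  n_warmup = n_warmup, migration = m)
    class(out) <- c("null_cloud", "data.frame")
    out
  })
}

#' Heterozygosity-conditional outlier p-values for observed F_ST
#'
#' For each locus, the empirical p-value is the fraction of simulated
#' neutral loci whose pooled-sample heterozygosity lies within
#' `+/- he_window` of the observed value and whose theta is at least the
#' observed theta (with the `(r+1)/(n+1)` convention). A locus is flagged
#' as under differential selection when `p < alpha` AND its theta exceeds
#' the multilocus average — the conjunction rule used for excluding loci
#' from drift-based Ne estimation. Windows holding fewer than
#' `min_window_n` null points are widened stepwise (by `he_window`
#' increments, logged in the result's `window_used` column).
#'
#' @param observed a `differentiation_result` from [fst_wc()].
#' @param diversity named numeric vector of per-locus pooled-sample
#'   heterozygosity (e.g. `he_by_locus` of a pooled [gene_diversity()]),
#'   or a `diversity_result`.
#' @param null_cloud result of [simulate_null_fst()].
#' @param he_window half-width of the heterozygosity window
#'   (default 0.05).
#' @param alpha flagging level (default 0.05).
#' @param min_window_n minimum null points per window (default 100).
#' @return an `outlier_scan` data frame: `locus_id`, `he`, `fst`,
#'   `p_value`, `window_used`, `flagged`.
#' @export
outlier_pvalues <- function(observed, diversity, null_cloud,
                            he_window = 0.05, alpha = 0.05,
                            min_window_n = 100) {
  stopifnot(inherits(observed, "differentiation_result"), he_window > 0)
  if (inherits(diversity, "diversity_result"))
    diversity <- diversity$he_by_locus
  if (!nrow(null_cloud)) stop_ccp("outlier_pvalues: empty null cloud")
  nc <- null_cloud[is.finite(null_cloud$fst) & is.finite(null_cloud$he), ]
  loci <- observed$by_locus$locus_id
  he <- diversity[loci]
  if (anyNA(he))
    stop_ccp("outlier_pvalues: missing heterozygosity for locus ",
             paste(loci[is.na(he)], collapse = ", "))
  fst_mean <- observed$fst_multilocus
  rows <- lapply(seq_along(loci), function(i) {
    w <- he_window
    repeat {
      sel <- abs(nc$he - he[i]) <= w
      if (sum(sel) >= min_window_n || w > 1) break
      w <- w + he_window
    }
    n_in <- sum(sel)
    p <- empirical_p(sum(nc$fst[sel] >= observed$by_locus$fst[i]), n_in)
    data.frame(locus_id = loci[i], he = as.numeric(he[i]),
               fst = observed$by_locus$fst[i], p_value = p,
               window_used = w, n_null = n_in, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$p_value < alpha & out$fst > fst_mean
  attr(out, "alpha") <- alpha
  attr(out, "fst_multilocus") <- fst_mean
  class(out) <- c("outlier_scan", "data.frame")
  out
}

#' Loci retained as neutral for Ne estimation
#'
#' Returns the loci not flagged by the outlier scan; these feed the
#' drift-based effective-size estimators, which assume neutrality.
#'
#' @param scan an `outlier_scan` from [outlier_pvalues()].
#' @return character vector of locus ids.
#' @export
loci_for_ne <- function(scan) {
  stopifnot(inherits(scan, "outlier_scan"))
  keep <- scan$locus_id[!scan$flagged]
  if (!length(keep))
    stop_ccp("loci_for_ne: every locus flagged; no neutral loci left")
  keep
}
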