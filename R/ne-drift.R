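#' Effective population size from F_ST
#'
#' Under pure drift, the differentiation accumulated among replicate
#' populations separated for `t` generations satisfies
#' `F_ST = 1 - (1 - 1/(2*Ne))^t`, giving (by the usual logarithmic
#' approximation) `Ne = t / (4 * ln(1/(1 - F_ST)))`. The confidence
#' interval is obtained by applying the same map to the F_ST interval
#' bounds: the upper F_ST bound yields the lower Ne bound.
#'
#' @param fst multilocus F_ST, strictly inside (0, 1); alternatively a
#'   `differentiation_result`, whose bootstrap CI is propagated.
#' @param t generations of drift separating the populations.
#' @return an `ne_estimate`: list with `method = "fst_pairs"`, `point`,
#'   `ci_low`, `ci_high` and the inputs.
#' @export
ne_from_fst <- function(fst, t) {
  ci <- c(NA_real_, NA_real_)
  if (inherits(fst, "differentiation_result")) {
    ci <- c(fst$ci_low, fst$ci_high)
    fst <- fst$fst_multilocus
  }
  stopifnot(is.numeric(t), t >= 1)
  if (!is.finite(fst) || fst <= 0)
    stop_ccp("ne_from_fst: non-positive differentiation: Ne undefined/infinite")
  if (fst >= 1) stop_ccp("ne_from_fst: F_ST must be < 1")
  map <- function(f) t / (4 * log(1 / (1 - f)))
  structure(list(method = "fst_pairs", point = map(fst),
                 ci_low = if (is.finite(ci[2]) && ci[2] > 0 && ci[2] < 1)
                   map(ci[2]) else NA_real_,
                 ci_high = if (is.finite(ci[1]) && ci[1] > 0 && ci[1] < 1)
                   map(ci[1]) else NA_real_,
                 inputs = list(fst = fst, fst_ci = ci, t = t)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  ci <- if (is.finite(x$ci_low))
    sprintf(" (%d-%d)", round(x$ci_low), round(x$ci_high)) else ""
  cat(sprintf("<ne_estimate> %s: Ne = %d%s\n", x$method, round(x$point), ci))
  invisible(x)
}

#' Standardised temporal variance Fc between two sampled generations
#'
#' Per locus, with reference-allele frequencies `x` (earlier sample) and
#' `y` (later sample), `Fc = (x - y)^2 / ((x + y)/2 - x*y)`; the estimate
#' is the mean over loci. Loci fixed for the same allele in both samples
#' (`x = y = 0` or `1`) are 0/0 and excluded.
#'
#' @param p_early,p_late allele-frequency tables (see
#'   [allele_frequencies()]) or named numeric vectors of per-locus
#'   frequencies.
#' @param loci optional locus subset (e.g. the SSR loci only, when SNP
#'   loci are suspected to be under selection).
#' @return mean Fc (numeric scalar) with per-locus values as
#'   `attr(x, "fc_by_locus")`.
#' @export
temporal_fc <- function(p_early, p_late, loci = NULL) {
  as_vec <- function(p) {
    if (is.data.frame(p)) stats::setNames(p$p, p$locus_id) else p
  }
  x <- as_vec(p_early); y <- as_vec(p_late)
  shared <- intersect(names(x), names(y))
  if (!is.null(loci)) shared <- intersect(shared, loci)
  if (!length(shared)) stop_ccp("temporal_fc: no shared loci")
  x <- x[shared]; y <- y[shared]
  den <- (x + y) / 2 - x * y
  fc <- ifelse(den > 0, (x - y)^2 / den, NA_real_)
  excluded <- shared[is.na(fc)]
  if (length(excluded))
    message("temporal_fc: locus fixed in both samples excluded: ",
            paste(excluded, collapse = ", "))
  out <- mean(fc, na.rm = TRUE)
  attr(out, "fc_by_locus") <- fc
  out
}

#' Temporal-method effective population size
#'
#' The Nei-Tajima temporal estimator with sampling-plan-II correction:
#' `Ne = t / (2 * (Fc - 1/(2*S_early) - 1/(2*S_late)))`, where `S` are the
#' numbers of individuals genotyped in the two samples. The drift signal
#' must exceed the sampling-noise correction, otherwise Ne is undefined.
#'
#' @param fc mean standardised temporal variance (see [temporal_fc()]).
#' @param t generations between the two samples.
#' @param S_early,S_late sample sizes (individuals) of the two samples.
#' @return an `ne_estimate` with `method = "temporal"`.
#' @export
ne_temporal <- function(fc, t, S_early, S_late) {
  stopifnot(t >= 1, S_early >= 2, S_late >= 2)
  corr <- 1 / (2 * S_early) + 1 / (2 * S_late)
  den <- fc - corr
  if (!is.finite(den) || den <= 0)
    stop_ccp("ne_temporal: drift signal below sampling noise ",
             sprintf("(Fc = %.4g <= correction %.4g)", fc, corr))
  structure(list(method = "temporal", point = t / (2 * den),
                 ci_low = NA_real_, ci_high = NA_real_,
                 inputs = list(fc = as.numeric(fc), t = t,
                               S_early = S_early, S_late = S_late)),
            class = "ne_estimate")
}

#' Drift-null confidence band for an allele frequency
#'
#' After `t` generations of pure drift at effective size `Ne`, the
#' frequency of an allele starting at `p_FND` has variance
#' `p_FND*(1-p_FND)*(1-(1-1/(2*Ne))^t)`; the normal-approximation band is
#' `p_FND +/- z * sqrt(variance)` clipped to [0, 1].
#'
#' @param p_fnd founder frequency (vectorised).
#' @param ne effective population size.
#' @param t generations of drift.
#' @param ci_level band level (default 0.95, i.e. z = 1.96).
#' @return data frame with columns `band_low`, `band_high` (one row per
#'   `p_fnd`).
#' @export
drift_ci <- function(p_fnd, ne, t, ci_level = 0.95) {
  stopifnot(all(p_fnd >= 0 & p_fnd <= 1), ne > 0, t >= 1,
            ci_level > 0, ci_level < 1)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  half <- z * sqrt(p_fnd * (1 - p_fnd) * (1 - (1 - 1 / (2 * ne))^t))
  data.frame(band_low = pmax(0, p_fnd - half),
             band_high = pmin(1, p_fnd + half))
}

#' Flag allele-frequency changes exceeding the drift expectation
#'
#' For every locus x population x generation, the observed frequency of
#' the frequent-in-FND allele is classified as `below`, `inside` or
#' `above` the drift-null band around the founder frequency, for each
#' candidate effective size (the study's convention uses the bracketing
#' pair Ne = 150 and Ne = 250, so band width can be compared across
#' plausible drift intensities). A consistency summary reports loci that
#' fall outside the band in the same direction in every population at the
#' final sampled generation.
#'
#' @param freqs allele-frequency table of the descendant samples.
#' @param fnd allele-frequency table of the virtual founding population
#'   (population `"FND"`, generation 0).
#' @param ne_values numeric vector of effective sizes (default
#'   `c(150, 250)`).
#' @param ci_level band level.
#' @param t_offset generation at which drift is taken to start (FND is
#'   generation 0, so elapsed drift time is `generation - t_offset`;
#'   default 0).
#' @return a `selection_flag_table` data frame (locus, population,
#'   generation, ne, p_fnd, p_obs, band_low, band_high, status) with the
#'   consistency summary in `attr(x, "consistent")`.
#' @export
flag_selection <- function(freqs, fnd, ne_values = c(150, 250),
                           ci_level = 0.95, t_offset = 0) {
  fnd <- fnd[fnd$population == "FND", , drop = FALSE]
  if (!nrow(fnd)) stop_ccp("flag_selection: no FND frequencies supplied")
  p_fnd <- stats::setNames(fnd$p, fnd$locus_id)
  obs <- freqs[freqs$population != "FND", , drop = FALSE]
  missing_fnd <- setdiff(unique(obs$locus_id), names(p_fnd))
  if (length(missing_fnd)) {
    warning("flag_selection: locus missing in FND skipped: ",
            paste(missing_fnd, collapse = ", "), call. = FALSE)
    obs <- obs[!obs$locus_id %in% missing_fnd, , drop = FALSE]
  }
  rows <- lapply(ne_values, function(ne) {
    t <- pmax(1, obs$generation - t_offset)
    pf <- p_fnd[obs$locus_id]
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    half <- z * sqrt(pf * (1 - pf) * (1 - (1 - 1 / (2 * ne))^t))
    lo <- pmax(0, pf - half); hi <- pmin(1, pf + half)
    data.frame(locus_id = obs$locus_id, population = obs$population,
               generation = obs$generation, ne = ne, p_fnd = as.numeric(pf),
               p_obs = obs$p, band_low = lo, band_high = hi,
               status = ifelse(obs$p < lo, "below",
                               ifelse(obs$p > hi, "above", "inside")),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  gmax <- max(out$generation)
  final <- out[out$generation == gmax, ]
  cons <- lapply(split(final, list(final$locus_id, final$ne), drop = TRUE),
                 function(d) {
    if (all(d$status == "above")) dir <- "above"
    else if (all(d$status == "below")) dir <- "below"
    else return(NULL)
    data.frame(locus_id = d$locus_id[1], ne = d$ne[1], direction = dir,
               n_populations = nrow(d), stringsAsFactors = FALSE)
  })
  cons <- do.call(rbind, cons)
  attr(out, "consistent") <- cons %||%
    data.frame(locus_id = character(), ne = numeric(),
               direction = character(), n_populations = integer())
  class(out) <- c("selection_flag_table", "data.frame")
  out
}

#' Correlation of allele-frequency changes between populations
#'
#' Pearson correlation, over loci, of the per-locus frequency change
#' `delta p = p_pop - p_FND` between every pair of populations, with the
#' two-sided t-test on `L - 2` degrees of freedom. Strong positive
#' correlations indicate that selection moved the populations in the same
#' direction.
#'
#' @param freqs descendant allele-frequency table (one generation).
#' @param fnd FND allele-frequency table.
#' @param populations populations to compare; default all (non-FND).
#' @param generation generation to compare at; default the maximum.
#' @return data frame of pairs with `r`, `df`, `p_value`, `stars`;
#'   matrices in `attr(x, "r_matrix")` / `attr(x, "p_matrix")`.
#' @export
delta_p_correlation <- function(freqs, fnd, populations = NULL,
                                generation = NULL) {
  fnd <- fnd[fnd$population == "FND", ]
  p_fnd <- stats::setNames(fnd$p, fnd$locus_id)
  obs <- freqs[freqs$population != "FND", ]
  generation <- generation %||% max(obs$generation)
  obs <- obs[obs$generation == generation, ]
  populations <- populations %||% sort(unique(obs$population))
  dp <- lapply(populations, function(pop) {
    d <- obs[obs$population == pop, ]
    stats::setNames(d$p - p_fnd[d$locus_id], d$locus_id)
  })
  names(dp) <- populations
  k <- length(populations)
  rmat <- pmat <- matrix(NA_real_, k, k,
                         dimnames = list(populations, populations))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    ct <- pearson_test(dp[[i]], dp[[j]])
    rmat[i, j] <- rmat[j, i] <- ct$r
    pmat[i, j] <- pmat[j, i] <- ct$p_value
    rows[[length(rows) + 1]] <- data.frame(
      pop_a = populations[i], pop_b = populations[j], r = ct$r, L = ct$L,
      df = ct$df, p_value = ct$p_value, stars = significance_stars(ct$p_value),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "r_matrix") <- rmat
  attr(out, "p_matrix") <- pmat
  attr(out, "generation") <- generation
  out
}

# Pearson r over shared (named) loci with the t-test on L - 2 df.
pearson_test <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3)
    stop_ccp("correlation: need at least 3 shared loci")
  a <- a[shared]; b <- b[shared]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (L < 3) stop_ccp("correlation: need at least 3 complete loci")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, L = L, df = L - 2, p_value = NA_real_,
                reason = "zero variance"))
  r <- stats::cor(a, b)
  df <- L - 2
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, L = L, df = df, p_value = 2 * stats::pt(-abs(tt), df))
}
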