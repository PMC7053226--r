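#' Percentile bootstrap over loci
#'
#' Loci are resampled with replacement and the chosen statistic recomputed
#' on each resample; the interval is the percentile interval of the
#' bootstrap distribution. `statistic = "mean"` expects a numeric vector of
#' per-locus values; `statistic = "ratio_of_sums"` expects a two-column
#' matrix (numerator, denominator) and computes `sum(num)/sum(den)` — the
#' form needed for multilocus variance-component ratios such as F_ST.
#'
#' @param values numeric vector, or two-column matrix for
#'   `"ratio_of_sums"`.
#' @param statistic `"mean"` or `"ratio_of_sums"`.
#' @param n_bootstrap number of resamples (default 5000).
#' @param ci_level interval level (default 0.95).
#' @param seed optional RNG seed for reproducible intervals.
#' @return named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, statistic = c("mean", "ratio_of_sums"),
                         n_bootstrap = 5000, ci_level = 0.95, seed = NULL) {
  statistic <- match.arg(statistic)
  if (statistic == "ratio_of_sums") {
    values <- as.matrix(values)
    if (ncol(values) != 2) stop_ccp("bootstrap_ci: ratio_of_sums needs a ",
                                    "two-column (numerator, denominator) input")
    L <- nrow(values)
  } else {
    values <- as.numeric(values)
    L <- length(values)
  }
  if (L < 2) stop_ccp("bootstrap_ci: need at least 2 loci to resample")
  alpha <- (1 - ci_level) / 2
  stats <- with_seed(seed, {
    idx <- matrix(sample.int(L, L * n_bootstrap, replace = TRUE),
                  nrow = n_bootstrap)
    if (statistic == "mean") {
      rowMeans(matrix(values[idx], nrow = n_bootstrap))
    } else {
      num <- matrix(values[idx, 1], nrow = n_bootstrap)
      den <- matrix(values[idx, 2], nrow = n_bootstrap)
      rowSums(num) / rowSums(den)
    }
  })
  stats <- stats[is.finite(stats)]
  q <- stats::quantile(stats, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  c(low = q[1], high = q[2])
}

# Per-locus gene diversity He = 1 - sum(p_k^2) from allele calls.
he_by_locus <- function(genotypes) {
  r <- genotypes$records
  loci <- genotypes$panel$locus_id
  vapply(loci, function(l) {
    a <- c(r$allele_a[r$locus_id == l], r$allele_b[r$locus_id == l])
    a <- a[!is.na(a)]
    if (!length(a)) return(NA_real_)
    p <- as.numeric(table(a)) / length(a)
    1 - sum(p^2)
  }, numeric(1))
}

#' Nei's gene diversity with a locus bootstrap
#'
#' Gene diversity (expected heterozygosity under Hardy-Weinberg
#' equilibrium) `He = 1 - sum(p_k^2)` is computed per locus on the
#' observed allele frequencies, averaged over loci, and given a percentile
#' confidence interval from bootstrapping over loci. The uncorrected
#' estimator is the default; `correct = TRUE` applies the small-sample
#' factor `2n/(2n-1)` per locus.
#'
#' @param genotypes a [genotype_table()].
#' @param population,generation optional filters selecting one sample.
#' @param n_bootstrap,ci_level,seed see [bootstrap_ci()].
#' @param correct apply the `2n/(2n-1)` small-sample correction.
#' @return a `diversity_result`: list with `population`, `generation`,
#'   `he_by_locus` (named vector), `he_mean`, `ci_low`, `ci_high`,
#'   `n_bootstrap`.
#' @export
gene_diversity <- function(genotypes, population = NULL, generation = NULL,
                           n_bootstrap = 5000, ci_level = 0.95, seed = NULL,
                           correct = FALSE) {
  g <- subset_genotypes(genotypes, population, generation)
  if (!nrow(g$records)) stop_ccp("gene_diversity: no records selected")
  he <- he_by_locus(g)
  if (all(is.na(he))) stop_ccp("gene_diversity: no observations at any locus")
  if (correct) {
    r <- g$records
    n2 <- vapply(names(he), function(l) {
      sum(r$locus_id == l & !is.na(r$allele_a) & !is.na(r$allele_b)) * 2
    }, numeric(1))
    he <- ifelse(n2 > 1, he * n2 / (n2 - 1), he)
  }
  he_ok <- he[!is.na(he)]
  ci <- if (n_bootstrap >= 1 && length(he_ok) >= 2)
    bootstrap_ci(he_ok, "mean", n_bootstrap, ci_level, seed)
  else c(low = NA_real_, high = NA_real_)
  structure(list(population = population %||% "all",
                 generation = generation %||% NA_integer_,
                 he_by_locus = he, he_mean = mean(he_ok),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 n_bootstrap = n_bootstrap),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> %s (g%s): He = %.3f [%.3f, %.3f] over %d loci\n",
              paste(x$population, collapse = "+"),
              paste(x$generation, collapse = "/"), x$he_mean,
              x$ci_low, x$ci_high, sum(!is.na(x$he_by_locus))))
  invisible(x)
}

#' Gene-diversity summary over all samples
#'
#' Convenience wrapper running [gene_diversity()] for every
#' population x generation sample in the table, optionally split by
#' marker type (the SSR and SNP panels track different processes and are
#' reported separately).
#'
#' @inheritParams gene_diversity
#' @param by_marker_type also compute per marker-type rows.
#' @return data frame with one row per sample (x marker set).
#' @export
diversity_table <- function(genotypes, n_bootstrap = 5000, ci_level = 0.95,
                            seed = NULL, by_marker_type = TRUE) {
  samples <- unique(genotypes$records[, c("population", "generation")])
  samples <- samples[order(samples$generation, samples$population), ]
  sets <- list(all = genotypes$panel$locus_id)
  if (by_marker_type)
    for (mt in unique(genotypes$panel$marker_type))
      sets[[mt]] <- genotypes$panel$locus_id[genotypes$panel$marker_type == mt]
  seeds <- derive_seeds(seed, nrow(samples) * length(sets))
  k <- 0L
  rows <- list()
  for (i in seq_len(nrow(samples))) for (s in names(sets)) {
    k <- k + 1L
    g <- subset_genotypes(genotypes, loci = sets[[s]])
    d <- gene_diversity(g, samples$population[i], samples$generation[i],
                        n_bootstrap, ci_level,
                        if (is.null(seed)) NULL else seeds[k])
    rows[[k]] <- data.frame(population = samples$population[i],
                            generation = samples$generation[i],
                            marker_set = s, n_loci = sum(!is.na(d$he_by_locus)),
                            he_mean = d$he_mean, ci_low = d$ci_low,
                            ci_high = d$ci_high, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
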