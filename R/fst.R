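# Weir & Cockerham (1984) variance components for one biallelic locus.
# n: individuals sampled per population (with data at this locus),
# p: frequency of the reference allele per population,
# h: observed heterozygote proportion per population.
# Returns c(a, b, c): among-population, among-individual-within-population
# and within-individual components for the reference allele.
wc_components <- function(n, p, h) {
  keep <- n > 0
  n <- n[keep]; p <- p[keep]; h <- h[keep]
  r <- length(n)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Per-population sample size, reference-allele frequency and observed
# heterozygosity for one locus of a (biallelic) genotype table.
locus_pop_summary <- function(records, locus, ref_allele, populations) {
  rec <- records[records$locus_id == locus &
                   records$population %in% populations &
                   !is.na(records$allele_a) & !is.na(records$allele_b), ,
                 drop = FALSE]
  n <- p <- h <- stats::setNames(rep(0, length(populations)), populations)
  if (nrow(rec)) {
    cnt <- rowsum(cbind(one = rep(1, nrow(rec)),
                        copies = (rec$allele_a == ref_allele) +
                                 (rec$allele_b == ref_allele),
                        het = as.numeric(rec$allele_a != rec$allele_b)),
                  rec$population)
    pres <- rownames(cnt)
    n[pres] <- cnt[, "one"]
    p[pres] <- cnt[, "copies"] / (2 * cnt[, "one"])
    h[pres] <- cnt[, "het"] / cnt[, "one"]
  }
  list(n = n, p = ifelse(n > 0, p, NA), h = ifelse(n > 0, h, NA))
}

#' Weir and Cockerham's F_ST (theta) for biallelic loci
#'
#' Estimates the among-population fixation index theta from the 1984
#' variance-components estimator for diploid data with observed
#' heterozygote counts. Per locus, the components are `a` (among
#' populations), `b` (among individuals within populations) and `c`
#' (within individuals); per-locus `theta = a/(a+b+c)` (which may be
#' negative), and the multilocus estimate is the ratio of sums
#' `sum(a)/sum(a+b+c)`, never the mean of per-locus ratios. The
#' confidence interval is a percentile bootstrap over loci of the
#' ratio-of-sums statistic.
#'
#' @param genotypes a biallelic (collapsed) [genotype_table()].
#' @param populations character vector of at least two population labels;
#'   default: all populations in the table.
#' @param loci loci to include; default: all. Loci monomorphic across the
#'   included populations are excluded with a warning.
#' @param generation optional generation filter.
#' @param n_bootstrap,ci_level,seed see [bootstrap_ci()]; `n_bootstrap = 0`
#'   skips the interval.
#' @param scope label stored on the result (`"overall"`, `"pair"`,
#'   `"group_contrast"`).
#' @return a `differentiation_result`: list with `scope`, `populations`,
#'   `by_locus` (data frame of a, b, c, fst per locus), `fst_multilocus`,
#'   `ci_low`, `ci_high`.
#' @export
fst_wc <- function(genotypes, populations = NULL, loci = NULL,
                   generation = NULL, n_bootstrap = 5000, ci_level = 0.95,
                   seed = NULL, scope = "overall") {
  g <- subset_genotypes(genotypes, generation = generation, loci = loci)
  r <- g$records
  populations <- populations %||% sort(unique(r$population))
  if (length(populations) < 2)
    stop_ccp("fst_wc: need at least two populations")
  panel <- g$panel
  small <- tapply(r$individual_id[r$population %in% populations],
                  r$population[r$population %in% populations],
                  function(x) length(unique(x)))
  if (any(small < 2))
    stop_ccp("fst_wc: population sample size < 2: ",
             paste(names(small)[small < 2], collapse = ", "))
  rows <- lapply(seq_len(nrow(panel)), function(j) {
    l <- panel$locus_id[j]
    ref <- panel$frequent_allele[j]
    if (is.na(ref)) ref <- panel$allele_labels[[j]][1]
    s <- locus_pop_summary(r, l, ref, populations)
    if (sum(s$n > 0) < 2) return(NULL)
    pr <- s$p[s$n > 0]
    if (all(pr == pr[1]) && (all(pr == 0) || all(pr == 1))) return(NULL)
    comp <- wc_components(s$n, s$p, s$h)
    data.frame(locus_id = l, a = comp[["a"]], b = comp[["b"]],
               c = comp[["c"]], stringsAsFactors = FALSE)
  })
  dropped <- panel$locus_id[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("fst_wc: monomorphic/undefined locus excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  by_locus <- do.call(rbind, rows)
  if (is.null(by_locus) || !nrow(by_locus))
    stop_ccp("fst_wc: no informative loci")
  tot <- by_locus$a + by_locus$b + by_locus$c
  by_locus$fst <- ifelse(tot != 0, by_locus$a / tot, NA_real_)
  fst_multi <- sum(by_locus$a) / sum(tot)
  ci <- c(low = NA_real_, high = NA_real_)
  if (n_bootstrap > 0 && nrow(by_locus) >= 2)
    ci <- bootstrap_ci(cbind(by_locus$a, tot), "ratio_of_sums",
                       n_bootstrap, ci_level, seed)
  structure(list(scope = scope, populations = populations,
                 by_locus = by_locus, fst_multilocus = fst_multi,
                 ci_low = ci[["low"]], ci_high = ci[["high"]]),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("<differentiation_result> %s [%s]: theta = %.4f [%.4f, %.4f] (%d loci)\n",
              x$scope, paste(x$populations, collapse = " vs "),
              x$fst_multilocus, x$ci_low, x$ci_high, nrow(x$by_locus)))
  invisible(x)
}

#' Pairwise and grouped F_ST estimates
#'
#' Computes one [fst_wc()] result per population pair and, optionally, per
#' two-group contrast (populations pooled within each group and relabelled
#' by group, e.g. organic vs conventional management).
#'
#' @param genotypes a biallelic [genotype_table()].
#' @param pairs list of length-2 character vectors; default all pairs.
#' @param contrasts optional named list of `list(group1 =, group2 =)`
#'   population groupings.
#' @inheritParams fst_wc
#' @return list of `differentiation_result`s, named `"A|B"` for pairs and
#'   by the contrast names.
#' @export
pairwise_and_grouped_fst <- function(genotypes, pairs = NULL,
                                     contrasts = NULL, loci = NULL,
                                     generation = NULL, n_bootstrap = 5000,
                                     ci_level = 0.95, seed = NULL) {
  g <- subset_genotypes(genotypes, generation = generation)
  pops <- sort(unique(g$records$population))
  if (is.null(pairs)) {
    pairs <- if (length(pops) >= 2) utils::combn(pops, 2, simplify = FALSE)
             else list()
  }
  if (!is.null(contrasts)) {
    bad <- vapply(contrasts,
                  function(ct) length(ct$group1) < 1 || length(ct$group2) < 1,
                  TRUE)
    if (any(bad)) stop_ccp("pairwise_and_grouped_fst: every contrast group ",
                           "needs at least one population")
  }
  n_jobs <- length(pairs) + length(contrasts)
  seeds <- derive_seeds(seed %||% 0, n_jobs)
  out <- list()
  k <- 0L
  for (pr in pairs) {
    k <- k + 1L
    out[[paste(pr, collapse = "|")]] <-
      fst_wc(g, populations = pr, loci = loci, n_bootstrap = n_bootstrap,
             ci_level = ci_level, seed = if (is.null(seed)) NULL else seeds[k],
             scope = "pair")
  }
  for (nm in names(contrasts)) {
    k <- k + 1L
    ct <- contrasts[[nm]]
    gg <- g
    rel <- gg$records$population
    rel[rel %in% ct$group1] <- "group1"
    rel[rel %in% ct$group2] <- "group2"
    gg$records$population <- rel
    gg$records <- gg$records[rel %in% c("group1", "group2"), , drop = FALSE]
    out[[nm]] <- fst_wc(gg, populations = c("group1", "group2"), loci = loci,
                        n_bootstrap = n_bootstrap, ci_level = ci_level,
                        seed = if (is.null(seed)) NULL else seeds[k],
                        scope = "group_contrast")
    out[[nm]]$populations <- c(paste(ct$group1, collapse = "+"),
                               paste(ct$group2, collapse = "+"))
  }
  out
}

#' Pairwise F_ST matrix (estimates above, CIs below the diagonal)
#'
#' Shapes a list of pairwise results into the conventional square matrix
#' with point estimates in the upper triangle and `(low-high)` interval
#' strings in the lower triangle.
#'
#' @param pairwise list returned by [pairwise_and_grouped_fst()] (pairs
#'   only are used).
#' @param digits digits for formatting.
#' @return character matrix with population names as dimnames.
#' @export
fst_pair_matrix <- function(pairwise, digits = 3) {
  pairwise <- pairwise[vapply(pairwise, function(x) x$scope == "pair", TRUE)]
  pops <- sort(unique(unlist(lapply(pairwise, `[[`, "populations"))))
  m <- matrix("", length(pops), length(pops), dimnames = list(pops, pops))
  for (x in pairwise) {
    i <- match(x$populations[1], pops); j <- match(x$populations[2], pops)
    lo <- min(i, j); hi <- max(i, j)
    m[lo, hi] <- formatC(x$fst_multilocus, digits = digits, format = "f")
    m[hi, lo] <- sprintf("(%s-%s)",
                         formatC(x$ci_low, digits = digits, format = "f"),
                         formatC(x$ci_high, digits = digits, format = "f"))
  }
  m
}
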