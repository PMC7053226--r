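#' Run the full selection-scan pipeline
#'
#' Executes the inference chain end-to-end: virtual founding population
#' from the crossing scheme and parental genotypes; removal of
#' non-parental alleles; biallelic recoding anchored on the
#' frequent-in-FND allele; allele frequencies; gene-diversity summary;
#' overall, pairwise and grouped F_ST; heterozygosity-conditional F_ST
#' outlier scan; F_ST-based and temporal effective-size estimates on the
#' neutral loci; drift-band selection flags; and (when phenotypes are
#' supplied) mixed- and pure-stand additive allele effects with the
#' frequency-change and pleiotropy correlation grids. All stochastic
#' stages draw their seeds from `config$rng_seed`, so a repeated run
#' writes byte-identical machine-readable outputs.
#'
#' @param config a [run_config()].
#' @param genotypes descendant [genotype_table()] (or path + `panel_path`).
#' @param parents parental [genotype_table()] (or path).
#' @param scheme a [crossing_scheme()] (or path).
#' @param traits optional `trait_table` (or path).
#' @param panel_path panel file path when `genotypes` is a path.
#' @param contrasts optional named list of population group contrasts for
#'   [pairwise_and_grouped_fst()].
#' @param out_dir optional directory; when given, every result table is
#'   written as a tab-separated file plus a machine-readable
#'   `run_log.json`.
#' @param reference_trait reference trait for the pleiotropy grid.
#' @return invisibly, a list of result tables: `diversity`,
#'   `fst_overall`, `fst_pairwise` (+ `fst_pair_matrix`, `fst_contrasts`),
#'   `outlier_scan`, `ne` (both methods), `drift_flags`,
#'   `allele_frequencies`, `delta_p_correlation`, and with phenotypes
#'   `effects_mixed`, `effects_pure`, `dp_effect` and `effect_effect`
#'   grids.
#' @export
run_pipeline <- function(config, genotypes, parents, scheme, traits = NULL,
                         panel_path = NULL, contrasts = NULL,
                         out_dir = NULL, reference_trait = "height") {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ccp(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e))))
  }
  if (is.character(genotypes))
    genotypes <- stage("load_genotypes",
                       load_genotypes(genotypes, panel_path))
  if (is.character(parents))
    parents <- stage("load_parents", load_genotypes(parents, panel_path))
  if (is.character(scheme))
    scheme <- stage("load_scheme", load_crossing_scheme(scheme, parents))
  if (is.character(traits)) traits <- stage("load_traits", load_traits(traits))
  seeds <- derive_seeds(config$rng_seed, 8,
                        c("diversity", "fst", "pairs", "null", "ne",
                          "assoc", "spare1", "spare2"))
  res <- list(config = config)

  fnd <- stage("founder",
               build_virtual_fnd(scheme, parents, config$virtual_pop_size))
  filt <- stage("filter", filter_nonparental_alleles(genotypes, parents))
  res$removal_report <- filt$report
  gt <- stage("collapse", collapse_to_biallelic(filt$genotypes, fnd))
  map <- attr(gt, "recode_map")
  fnd_c <- collapse_to_biallelic(fnd, map)
  parents_c <- collapse_to_biallelic(parents, map)
  freqs <- stage("frequencies", allele_frequencies(gt))
  fnd_freq <- allele_frequencies(fnd_c)
  res$allele_frequencies <- rbind(fnd_freq, freqs)

  res$diversity <- stage("diversity", diversity_table(
    gt, config$n_bootstrap, config$ci_level, seeds["diversity"]))
  gmax <- max(freqs$generation)
  res$fst_overall <- stage("fst", fst_wc(
    gt, generation = gmax, n_bootstrap = config$n_bootstrap,
    ci_level = config$ci_level, seed = seeds["fst"]))
  pw <- stage("fst_pairs", pairwise_and_grouped_fst(
    gt, contrasts = contrasts, generation = gmax,
    n_bootstrap = config$n_bootstrap, ci_level = config$ci_level,
    seed = seeds["pairs"]))
  is_pair <- vapply(pw, function(x) x$scope == "pair", TRUE)
  res$fst_pairwise <- pw[is_pair]
  res$fst_contrasts <- pw[!is_pair]
  res$fst_pair_matrix <- fst_pair_matrix(res$fst_pairwise)

  pooled_he <- stage("pooled_he", gene_diversity(
    subset_genotypes(gt, generation = gmax), n_bootstrap = 0,
    seed = NULL)$he_by_locus)
  null_cloud <- stage("null", simulate_null_fst(
    target_fst = max(res$fst_overall$fst_multilocus, 1e-4),
    n_sims = config$n_null_sims, n_demes = config$n_demes,
    n_sampled_demes = length(unique(freqs$population)),
    sample_size = max(2, round(mean(table(
      unique(gt$records[gt$records$generation == gmax,
                        c("individual_id", "population")])$population)))),
    seed = seeds["null"]))
  res$outlier_scan <- stage("outliers", outlier_pvalues(
    res$fst_overall, pooled_he, null_cloud))
  neutral <- stage("neutral_loci", loci_for_ne(res$outlier_scan))
  res$neutral_loci <- neutral

  fst_neutral <- stage("fst_neutral", fst_wc(
    gt, generation = gmax, loci = neutral,
    n_bootstrap = config$n_bootstrap, ci_level = config$ci_level,
    seed = seeds["ne"]))
  res$ne_fst <- stage("ne_fst",
                      ne_from_fst(fst_neutral, config$t_generations))
  res$ne_temporal <- stage("ne_temporal", {
    ssr <- gt$panel$locus_id[gt$panel$marker_type == "SSR"]
    gens <- sort(unique(freqs$generation))
    ests <- list()
    if (length(gens) >= 2) {
      g0 <- gens[1]; g1 <- gens[length(gens)]
      for (pop in unique(freqs$population)) {
        pe <- freqs[freqs$population == pop & freqs$generation == g0, ]
        pl <- freqs[freqs$population == pop & freqs$generation == g1, ]
        if (!nrow(pe) || !nrow(pl)) next
        fc <- suppressMessages(temporal_fc(pe, pl, loci = ssr))
        est <- tryCatch(ne_temporal(fc, g1 - g0,
                                    round(mean(pe$n_obs) / 2),
                                    round(mean(pl$n_obs) / 2)),
                        error = function(e) NULL)
        if (!is.null(est)) ests[[pop]] <- est$point
      }
    }
    if (length(ests))
      list(by_population = unlist(ests), mean = mean(unlist(ests)))
    else list(by_population = numeric(), mean = NA_real_)
  })

  res$drift_flags <- stage("driftscan", flag_selection(
    freqs, fnd_freq, ne_values = config$ne_bands,
    ci_level = config$ci_level))
  res$delta_p_correlation <- stage("dp_correlation", delta_p_correlation(
    freqs, fnd_freq, generation = gmax))

  if (!is.null(traits)) {
    res$effects_mixed <- stage("assoc_mixed",
                               effects_table(traits, gt, stand = "mixed"))
    res$effects_pure <- stage("assoc_pure",
                              effects_table(traits, parents_c,
                                            stand = "pure"))
    res$dp_effect <- stage("dp_effect_grid", dp_effect_grid(
      res$effects_mixed, freqs, fnd_freq, generation = gmax))
    res$effect_effect <- stage("effect_effect_grid", effect_effect_grid(
      res$effects_mixed, res$effects_pure, reference_trait))
  }

  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  invisible(res)
}

# Emit every result table as TSV plus a machine-readable run log.
write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_tsv(df, file.path(out_dir, name))
  w(res$diversity, "diversity.tsv")
  w(res$allele_frequencies, "allele_frequencies.tsv")
  w(res$fst_overall$by_locus, "fst_by_locus.tsv")
  pair_rows <- do.call(rbind, lapply(res$fst_pairwise, function(x)
    data.frame(pop_a = x$populations[1], pop_b = x$populations[2],
               fst = x$fst_multilocus, ci_low = x$ci_low,
               ci_high = x$ci_high, stringsAsFactors = FALSE)))
  w(pair_rows, "fst_pairwise.tsv")
  utils::write.table(res$fst_pair_matrix,
                     file.path(out_dir, "fst_pair_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  w(as.data.frame(res$outlier_scan), "outlier_scan.tsv")
  w(as.data.frame(res$drift_flags), "drift_flags.tsv")
  w(res$delta_p_correlation, "delta_p_correlation.tsv")
  ne_rows <- data.frame(
    method = c("fst_pairs", "temporal"),
    point = c(res$ne_fst$point, res$ne_temporal$mean),
    ci_low = c(res$ne_fst$ci_low, NA),
    ci_high = c(res$ne_fst$ci_high, NA), stringsAsFactors = FALSE)
  w(ne_rows, "ne_estimates.tsv")
  if (!is.null(res$effects_mixed)) {
    w(res$effects_mixed, "effects_mixed.tsv")
    w(res$effects_pure, "effects_pure.tsv")
    w(res$dp_effect$detail, "dp_effect_correlations.tsv")
    utils::write.table(res$dp_effect$grid,
                       file.path(out_dir, "dp_effect_grid.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(res$effect_effect$detail))
      w(res$effect_effect$detail, "effect_effect_correlations.tsv")
    utils::write.table(res$effect_effect$grid,
                       file.path(out_dir, "effect_effect_grid.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  log <- list(
    package = "ccpevol",
    version = as.character(utils::packageVersion("ccpevol")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    rng_seed = res$config$rng_seed,
    settings = res$config[setdiff(names(res$config), "rng_seed")],
    ne_fst = res$ne_fst$point,
    ne_temporal = res$ne_temporal$mean,
    fst_overall = res$fst_overall$fst_multilocus,
    neutral_loci = res$neutral_loci)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
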