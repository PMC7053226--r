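# All files are UTF-8, tab-delimited, with a mandatory header row; the
# missing-allele code is "NA". Heterozygotes use two allele columns; a
# single `genotype` column in "A/B" slash form is accepted on input and
# split on the first "/".

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) stop_ccp(what, ": file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a locus panel file
#'
#' Columns: `locus_id`, `marker_type`, `allele_labels` (comma-separated),
#' optional `frequent_allele` and `annotation`.
#'
#' @param path path to a tab-delimited panel file.
#' @return a [locus_panel()].
#' @export
load_panel <- function(path) {
  df <- read_tsv_strict(path, "panel")
  assert_cols(df, c("locus_id", "marker_type", "allele_labels"), "panel")
  locus_panel(df$locus_id, df$marker_type,
              strsplit(df$allele_labels, ","),
              df$frequent_allele %||% NA_character_,
              df$annotation %||% NA_character_)
}

#' @rdname load_panel
#' @param panel a [locus_panel()] to write.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(locus_id = panel$locus_id,
                   marker_type = panel$marker_type,
                   allele_labels = vapply(panel$allele_labels,
                                          paste, "", collapse = ","),
                   frequent_allele = panel$frequent_allele,
                   annotation = panel$annotation, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a genotype table
#'
#' Expects the long-format dialect: one row per individual x locus with
#' columns `individual_id`, `population`, `generation`, `location`,
#' `locus_id` and either `allele_a`/`allele_b` or a single `genotype`
#' column in `A/B` form. Allele labels not listed in the panel are accepted
#' and flagged: the returned table carries a load report (attribute
#' `novel_alleles`) enumerating them.
#'
#' @param path path to a tab-delimited genotype file.
#' @param panel_path path to the locus panel file (see [load_panel()]).
#' @return a [genotype_table()]; `attr(x, "novel_alleles")` is the load
#'   report of allele labels that had to be added to the panel.
#' @export
load_genotypes <- function(path, panel_path) {
  panel <- load_panel(panel_path)
  df <- read_tsv_strict(path, "genotype file")
  if ("genotype" %in% names(df) && !("allele_a" %in% names(df))) {
    parts <- strsplit(as.character(df$genotype), "/", fixed = TRUE)
    df$allele_a <- vapply(parts, `[`, "", 1L)
    df$allele_b <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                          "")
    df$genotype <- NULL
  }
  assert_cols(df, c("individual_id", "population", "generation", "location",
                    "locus_id", "allele_a", "allele_b"), "genotype file")
  gt <- genotype_table(df, panel, extend_labels = TRUE)
  novel <- attr(gt, "novel_alleles")
  if (nrow(novel))
    warning(sprintf("genotype file %s: %d novel allele label(s) added to panel",
                    path, nrow(novel)), call. = FALSE)
  gt
}

#' @rdname load_genotypes
#' @param genotypes a [genotype_table()] to write.
#' @export
write_genotypes <- function(genotypes, path, panel_path = NULL) {
  write_tsv(genotypes$records, path)
  if (!is.null(panel_path)) write_panel(genotypes$panel, panel_path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Holds both observation types of the design: single plants measured
#' inside the genetically mixed population (`stand = "mixed_single_plant"`,
#' joinable to the genotype table through `unit_id`) and plot means of the
#' parent varieties grown as pure stands in replicated trials
#' (`stand = "pure_plot"`, carrying `variety` and `replicate_block`).
#'
#' @param path path to a tab-delimited trait file with columns `unit_id`,
#'   `stand`, `trial`, `replicate_block`, `variety`, `trait`, `value`.
#' @return a validated `trait_table` data frame.
#' @export
load_traits <- function(path) {
  df <- read_tsv_strict(path, "trait file")
  trait_table(df)
}

#' @rdname load_traits
#' @param traits a `trait_table` to validate or write.
#' @export
trait_table <- function(traits) {
  assert_cols(traits, c("unit_id", "stand", "trial", "trait", "value"),
              "trait table")
  if (!"replicate_block" %in% names(traits))
    traits$replicate_block <- NA_character_
  if (!"variety" %in% names(traits)) traits$variety <- NA_character_
  traits <- traits[, c("unit_id", "stand", "trial", "replicate_block",
                       "variety", "trait", "value")]
  if (!all(traits$stand %in% c("mixed_single_plant", "pure_plot")))
    stop_ccp("trait table: stand must be 'mixed_single_plant' or 'pure_plot'")
  if (is.character(traits$value)) {
    v <- suppressWarnings(as.numeric(traits$value))
    bad <- which(is.na(v) & !is.na(traits$value))
    if (length(bad))
      stop_ccp(sprintf("trait table: non-numeric value '%s' in row %d",
                       traits$value[bad[1]], bad[1]))
    traits$value <- v
  }
  mixed <- traits$stand == "mixed_single_plant"
  if (any(mixed & (is.na(traits$unit_id) | traits$unit_id == "")))
    stop_ccp("trait table: mixed_single_plant rows must carry individual_id",
             " in unit_id")
  pure <- traits$stand == "pure_plot"
  if (any(pure & (is.na(traits$variety) | is.na(traits$replicate_block))))
    stop_ccp("trait table: pure_plot rows must carry variety and",
             " replicate_block")
  class(traits) <- c("trait_table", "data.frame")
  traits
}

#' @rdname load_traits
#' @export
write_traits <- function(traits, path) write_tsv(traits, path)

#' Read a crossing scheme
#'
#' Rows of `(parent_i, parent_j, seed_count)` describing how many F2 seeds
#' each successful cross contributed to the pooled founding population.
#' Crosses are unordered pairs: duplicated `(A,B)`/`(B,A)` rows are merged
#' with summed seed counts (with a warning).
#'
#' @param path path to a tab-delimited file.
#' @param parents optional parental [genotype_table()]; when given, every
#'   scheme parent must be genotyped.
#' @return a `crossing_scheme` data frame with attribute `total_seeds`.
#' @export
load_crossing_scheme <- function(path, parents = NULL) {
  df <- read_tsv_strict(path, "crossing scheme")
  crossing_scheme(df, parents)
}

#' @rdname load_crossing_scheme
#' @param scheme data frame with columns `parent_i`, `parent_j`,
#'   `seed_count`.
#' @export
crossing_scheme <- function(scheme, parents = NULL) {
  assert_cols(scheme, c("parent_i", "parent_j", "seed_count"),
              "crossing scheme")
  scheme$parent_i <- as.character(scheme$parent_i)
  scheme$parent_j <- as.character(scheme$parent_j)
  if (any(is.na(scheme$seed_count) | scheme$seed_count < 1 |
            scheme$seed_count != round(scheme$seed_count)))
    stop_ccp("crossing scheme: seed_count must be a positive integer")
  if (any(scheme$parent_i == scheme$parent_j))
    stop_ccp("crossing scheme: a cross must involve two distinct parents")
  # canonical unordered pair; merge duplicates with summed counts
  lo <- pmin(scheme$parent_i, scheme$parent_j)
  hi <- pmax(scheme$parent_i, scheme$parent_j)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    warning("crossing scheme: duplicated parent pair(s) merged with summed ",
            "seed counts", call. = FALSE)
    agg <- rowsum(scheme$seed_count, key)
    first <- !duplicated(key)
    scheme <- data.frame(parent_i = lo[first], parent_j = hi[first],
                         stringsAsFactors = FALSE)
    scheme$seed_count <- as.integer(agg[match(key[first], rownames(agg)), 1])
  } else {
    scheme <- data.frame(parent_i = lo, parent_j = hi,
                         seed_count = as.integer(scheme$seed_count),
                         stringsAsFactors = FALSE)
  }
  if (!is.null(parents)) {
    known <- unique(parents$records$individual_id)
    miss <- setdiff(unique(c(scheme$parent_i, scheme$parent_j)), known)
    if (length(miss))
      stop_ccp("crossing scheme: parent(s) not genotyped: ",
               paste(miss, collapse = ", "))
  }
  attr(scheme, "total_seeds") <- sum(scheme$seed_count)
  class(scheme) <- c("crossing_scheme", "data.frame")
  scheme
}

#' @rdname load_crossing_scheme
#' @export
write_crossing_scheme <- function(scheme, path)
  write_tsv(as.data.frame(scheme)[, c("parent_i", "parent_j", "seed_count")],
            path)

#' Pipeline run configuration
#'
#' Gathers the tunable quantities of the inference chain. Defaults follow
#' the study design the package targets: 5,000 locus bootstraps, a 20,000
#' simulation x 100 deme neutral null, a 10,000-individual virtual founding
#' population and 95% confidence levels.
#'
#' @param n_bootstrap locus bootstrap replicates for confidence intervals.
#' @param n_null_sims simulated loci for the F_ST outlier null.
#' @param n_demes demes in the island-model null.
#' @param ci_level confidence level, strictly inside (0, 1).
#' @param t_generations generations of drift separating the compared
#'   samples (8 for populations separated at generation 2 and genotyped at
#'   generation 10).
#' @param rng_seed root seed; every stochastic stage derives its own
#'   stream from it.
#' @param virtual_pop_size size of the virtual founding population.
#' @param ne_bands effective sizes for which drift bands are drawn.
#' @return a validated `run_config` list.
#' @export
run_config <- function(n_bootstrap = 5000, n_null_sims = 20000,
                       n_demes = 100, ci_level = 0.95, t_generations = 8,
                       rng_seed = 1, virtual_pop_size = 10000,
                       ne_bands = c(150, 250)) {
  cfg <- list(n_bootstrap = n_bootstrap, n_null_sims = n_null_sims,
              n_demes = n_demes, ci_level = ci_level,
              t_generations = t_generations, rng_seed = rng_seed,
              virtual_pop_size = virtual_pop_size, ne_bands = ne_bands)
  counts <- c("n_bootstrap", "n_null_sims", "n_demes", "t_generations",
              "virtual_pop_size")
  for (nm in counts)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 1)
      stop_ccp("run config: ", nm, " must be a positive count")
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop_ccp("run config: ci_level must be strictly inside (0, 1)")
  if (any(ne_bands <= 0)) stop_ccp("run config: ne_bands must be positive")
  structure(cfg, class = "run_config")
}
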