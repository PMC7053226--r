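#' Locus panel constructor
#'
#' A locus panel describes the marker loci of a genotyping assay: locus
#' identifiers, marker type (multi-allelic SSR or biallelic SNP), the known
#' allele labels, the designated frequent-in-founder allele (set by
#' [collapse_to_biallelic()]) and a free-text annotation (e.g. the gene the
#' marker is diagnostic for, or its wild-type allele label).
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param marker_type character vector, each `"SSR"` or `"SNP"`.
#' @param allele_labels list of character vectors (one per locus) of valid
#'   allele labels, each non-empty.
#' @param frequent_allele optional character vector; `NA` where unset. When
#'   set it must be one of the locus's `allele_labels`.
#' @param annotation optional character vector of free-text notes.
#' @return a `locus_panel` data frame with one row per locus and a list
#'   column `allele_labels`.
#' @export
locus_panel <- function(locus_id, marker_type,
                        allele_labels,
                        frequent_allele = NA_character_,
                        annotation = NA_character_) {
  locus_id <- as.character(locus_id)
  n <- length(locus_id)
  if (anyDuplicated(locus_id))
    stop_ccp("locus panel: duplicated locus_id")
  marker_type <- rep_len(as.character(marker_type), n)
  if (!all(marker_type %in% c("SSR", "SNP")))
    stop_ccp("locus panel: marker_type must be 'SSR' or 'SNP'")
  if (!is.list(allele_labels)) allele_labels <- list(allele_labels)
  allele_labels <- rep_len(allele_labels, n)
  allele_labels <- lapply(allele_labels, as.character)
  if (any(vapply(allele_labels, length, 1L) == 0L))
    stop_ccp("locus panel: allele_labels must be non-empty for every locus")
  frequent_allele <- rep_len(as.character(frequent_allele), n)
  ok <- is.na(frequent_allele) |
    mapply(function(f, l) f %in% l, frequent_allele, allele_labels)
  if (!all(ok))
    stop_ccp("locus panel: frequent_allele not among allele_labels at locus ",
             paste(locus_id[!ok], collapse = ", "))
  panel <- data.frame(locus_id = locus_id, marker_type = marker_type,
                      frequent_allele = frequent_allele,
                      annotation = rep_len(as.character(annotation), n),
                      stringsAsFactors = FALSE)
  panel$allele_labels <- allele_labels
  class(panel) <- c("locus_panel", "data.frame")
  panel
}

#' Expand a marker list into a locus panel bookkeeping table
#'
#' SSR primer pairs occasionally amplify two independent loci; such markers
#' contribute two rows to the locus panel (suffixed by the chromosome or
#' `-1`/`-2` when no chromosome is given). This mirrors the common situation
#' of an 18-marker SSR assay yielding a 20-locus panel.
#'
#' @param markers data frame with columns `marker` and `n_loci` (positive
#'   integers), optional `chromosomes` (comma-separated labels per marker).
#' @return character vector of locus identifiers, length `sum(n_loci)`.
#' @export
expand_marker_loci <- function(markers) {
  assert_cols(markers, c("marker", "n_loci"), "marker list")
  if (any(markers$n_loci < 1))
    stop_ccp("marker list: n_loci must be >= 1")
  unlist(lapply(seq_len(nrow(markers)), function(i) {
    m <- markers$marker[i]
    k <- markers$n_loci[i]
    if (k == 1L) return(m)
    chr <- if ("chromosomes" %in% names(markers) &&
               !is.na(markers$chromosomes[i]))
      strsplit(markers$chromosomes[i], ",")[[1]] else as.character(seq_len(k))
    paste0(m, "-", chr[seq_len(k)])
  }), use.names = FALSE)
}

#' Genotype table constructor
#'
#' The central container for diploid genotype calls in long format: one
#' record per individual x locus, with the two allele calls in separate
#' columns (SSR allele names may contain arbitrary characters, so no
#' separator-based encoding is used). Missing calls are `NA`.
#'
#' @param records data frame with columns `individual_id`, `population`,
#'   `generation`, `location`, `locus_id`, `allele_a`, `allele_b`.
#' @param panel a [locus_panel()].
#' @param extend_labels if `TRUE`, allele labels present in `records` but
#'   absent from the panel are appended to the panel's `allele_labels` and
#'   reported in `attr(x, "novel_alleles")`; if `FALSE` they are an error.
#' @return a `genotype_table`: list with elements `records` and `panel`.
#' @export
genotype_table <- function(records, panel, extend_labels = FALSE) {
  assert_cols(records, c("individual_id", "population", "generation",
                         "location", "locus_id", "allele_a", "allele_b"),
              "genotype table")
  records$individual_id <- as.character(records$individual_id)
  records$population <- as.character(records$population)
  records$generation <- as.integer(records$generation)
  records$location <- as.character(records$location)
  records$locus_id <- as.character(records$locus_id)
  records$allele_a <- as.character(records$allele_a)
  records$allele_b <- as.character(records$allele_b)
  if (any(!is.na(records$generation) & records$generation < 0))
    stop_ccp("genotype table: generation must be non-negative")
  if (!inherits(panel, "locus_panel"))
    stop_ccp("genotype table: panel must be a locus_panel")
  unknown <- setdiff(unique(records$locus_id), panel$locus_id)
  if (length(unknown))
    stop_ccp("genotype table: loci absent from panel: ",
             paste(unknown, collapse = ", "))
  key <- paste(records$individual_id, records$locus_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop_ccp("genotype table: duplicate (individual, locus) record(s), e.g. (",
             d$individual_id[1], ", ", d$locus_id[1], ")")
  }
  # every individual belongs to exactly one population sample
  # (a sample = population x generation x location)
  smp <- paste(records$population, records$generation, records$location,
               sep = "\r")
  n_smp <- tapply(smp, records$individual_id,
                  function(s) length(unique(s)))
  if (any(n_smp > 1))
    stop_ccp("genotype table: individual(s) assigned to more than one ",
             "population sample: ",
             paste(utils::head(names(n_smp)[n_smp > 1], 3), collapse = ", "))
  novel <- check_allele_labels(records, panel)
  if (nrow(novel)) {
    if (!extend_labels)
      stop_ccp("genotype table: allele label(s) absent from panel (e.g. '",
               novel$allele[1], "' at ", novel$locus_id[1],
               "); use extend_labels = TRUE to accept them")
    for (i in seq_len(nrow(novel))) {
      j <- match(novel$locus_id[i], panel$locus_id)
      panel$allele_labels[[j]] <- c(panel$allele_labels[[j]], novel$allele[i])
    }
  }
  out <- structure(list(records = records, panel = panel),
                   class = "genotype_table")
  attr(out, "novel_alleles") <- novel
  out
}

# data frame (locus_id, allele) of labels used in records but not in panel
check_allele_labels <- function(records, panel) {
  out <- lapply(seq_len(nrow(panel)), function(j) {
    loc <- panel$locus_id[j]
    rec <- records[records$locus_id == loc, c("allele_a", "allele_b")]
    used <- unique(c(rec$allele_a, rec$allele_b))
    used <- used[!is.na(used)]
    nov <- setdiff(used, panel$allele_labels[[j]])
    if (length(nov)) data.frame(locus_id = loc, allele = nov,
                                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(locus_id = character(),
                                      allele = character(),
                                      stringsAsFactors = FALSE)
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<genotype_table> %d records | %d individuals | %d loci (%d SSR, %d SNP)\n",
    nrow(r), length(unique(r$individual_id)), nrow(x$panel),
    sum(x$panel$marker_type == "SSR"), sum(x$panel$marker_type == "SNP")))
  pops <- unique(r[, c("population", "generation")])
  cat("  samples:", paste(sprintf("%s(g%d)", pops$population,
                                  pops$generation), collapse = " "), "\n")
  invisible(x)
}

# individuals genotyped per population sample
n_individuals <- function(x, population = NULL) {
  r <- x$records
  if (!is.null(population)) r <- r[r$population %in% population, ]
  length(unique(r$individual_id))
}

# Subset a genotype table by population / generation / loci.
subset_genotypes <- function(x, population = NULL, generation = NULL,
                             loci = NULL) {
  r <- x$records
  if (!is.null(population)) r <- r[r$population %in% population, ]
  if (!is.null(generation)) r <- r[r$generation %in% generation, ]
  p <- x$panel
  if (!is.null(loci)) {
    r <- r[r$locus_id %in% loci, ]
    p <- p[p$locus_id %in% loci, ]
    class(p) <- c("locus_panel", "data.frame")
  }
  structure(list(records = r, panel = p), class = "genotype_table")
}
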