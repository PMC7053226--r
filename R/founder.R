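#' Build the virtual founding population
#'
#' No seed of the real pooled founding population is assumed to exist; its
#' genotypic composition is reconstructed from the parental genotypes and
#' the recorded per-cross seed counts. Each cross contributes
#' `n_ij = round(s_ij / sum(s_ij) * virtual_pop_size)` copies of its F1
#' heterozygote multilocus genotype (one allele from each parent at every
#' locus), and the copies are pooled into a population labelled `FND` at
#' generation 0. Rounding is R's round-half-to-even; the total is not
#' re-normalised, so it can differ from `virtual_pop_size` by at most half
#' the number of crosses.
#'
#' @param scheme a [crossing_scheme()].
#' @param parents parental [genotype_table()]; parents must be homozygous
#'   at every locus (fixed inbred lines). Heterozygous parental calls are
#'   an error unless `het_parents = "first"`, which uses the first-listed
#'   allele.
#' @param virtual_pop_size target number of virtual founder individuals.
#' @param het_parents `"error"` (default) or `"first"`.
#' @return a [genotype_table()] of the virtual founders; the per-cross
#'   copy numbers are attached as `attr(x, "n_ij")`.
#' @export
build_virtual_fnd <- function(scheme, parents, virtual_pop_size = 10000,
                              het_parents = c("error", "first")) {
  het_parents <- match.arg(het_parents)
  stopifnot(inherits(scheme, "crossing_scheme"),
            inherits(parents, "genotype_table"))
  pr <- parents$records
  het <- !is.na(pr$allele_a) & !is.na(pr$allele_b) & pr$allele_a != pr$allele_b
  if (any(het)) {
    if (het_parents == "error")
      stop_ccp("build_virtual_fnd: heterozygous parental call(s), e.g. ",
               pr$individual_id[het][1], " at ", pr$locus_id[het][1],
               "; parents must be fixed lines (het_parents = 'first' to ",
               "override)")
    pr$allele_b[het] <- pr$allele_a[het]
  }
  loci <- parents$panel$locus_id
  # parent x locus matrix of (homozygous) allele calls
  pmat <- matrix(NA_character_, nrow = n_individuals(parents),
                 ncol = length(loci),
                 dimnames = list(unique(pr$individual_id), loci))
  pmat[cbind(match(pr$individual_id, rownames(pmat)),
             match(pr$locus_id, loci))] <- pr$allele_a
  need <- unique(c(scheme$parent_i, scheme$parent_j))
  miss <- setdiff(need, rownames(pmat))
  if (length(miss))
    stop_ccp("build_virtual_fnd: parent(s) not genotyped: ",
             paste(miss, collapse = ", "))
  sub <- pmat[need, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(is.na(sub), arr.ind = TRUE)[1, ]
    stop_ccp("build_virtual_fnd: parent ", rownames(sub)[bad[1]],
             " missing a call at locus ", loci[bad[2]])
  }
  s <- scheme$seed_count
  n_ij <- as.integer(round(s / sum(s) * virtual_pop_size))
  if (all(n_ij == 0L))
    stop_ccp("build_virtual_fnd: degenerate scheme, every n_ij rounds to 0")
  cross_of <- rep.int(seq_len(nrow(scheme)), n_ij)        # one per founder
  n_fnd <- length(cross_of)
  ids <- sprintf("fnd%06d", seq_len(n_fnd))
  rec <- data.frame(
    individual_id = rep(ids, each = length(loci)),
    population = "FND", generation = 0L, location = "",
    locus_id = rep(loci, times = n_fnd),
    allele_a = as.vector(t(pmat[scheme$parent_i[cross_of], , drop = FALSE])),
    allele_b = as.vector(t(pmat[scheme$parent_j[cross_of], , drop = FALSE])),
    stringsAsFactors = FALSE)
  out <- genotype_table(rec, parents$panel)
  attr(out, "n_ij") <- n_ij
  out
}

#' Remove non-parental alleles from a genotype dataset
#'
#' Alleles observed in descendant samples but absent from the parental
#' genotypes arise from mutation or migration; for allele-frequency
#' inference anchored on the founders they are treated as removable noise.
#' Every genotype record carrying such an allele is dropped at that locus
#' only (the individual's other loci are retained).
#'
#' @param genotypes descendant [genotype_table()].
#' @param parents parental [genotype_table()] sharing the panel.
#' @return list with `genotypes` (filtered table) and `report` (data frame
#'   of per-locus removal counts).
#' @export
filter_nonparental_alleles <- function(genotypes, parents) {
  loci <- genotypes$panel$locus_id
  pr <- parents$records
  parental <- lapply(loci, function(l) {
    a <- c(pr$allele_a[pr$locus_id == l], pr$allele_b[pr$locus_id == l])
    unique(a[!is.na(a)])
  })
  names(parental) <- loci
  r <- genotypes$records
  keepset <- parental[r$locus_id]
  ok_a <- is.na(r$allele_a) | mapply(`%in%`, r$allele_a, keepset)
  ok_b <- is.na(r$allele_b) | mapply(`%in%`, r$allele_b, keepset)
  drop <- !(ok_a & ok_b)
  report <- data.frame(locus_id = loci,
                       n_removed = as.integer(
                         table(factor(r$locus_id[drop], levels = loci))),
                       stringsAsFactors = FALSE)
  # restrict panel labels to the parental allele set
  panel <- genotypes$panel
  panel$allele_labels <- lapply(seq_along(loci), function(j)
    intersect(panel$allele_labels[[j]], parental[[j]]))
  keep_rec <- r[!drop, , drop = FALSE]
  if (!nrow(keep_rec))
    warning("filter_nonparental_alleles: no records left", call. = FALSE)
  out <- structure(list(records = keep_rec, panel = panel),
                   class = "genotype_table")
  list(genotypes = out, report = report)
}

# Frequent-in-FND allele per locus (ties broken lexicographically, logged
# in the returned data frame's `tie` column).
fnd_frequent_alleles <- function(fnd) {
  loci <- fnd$panel$locus_id
  r <- fnd$records
  out <- lapply(loci, function(l) {
    a <- c(r$allele_a[r$locus_id == l], r$allele_b[r$locus_id == l])
    a <- a[!is.na(a)]
    if (!length(a))
      stop_ccp("collapse_to_biallelic: no FND calls at locus ", l)
    tab <- table(a)
    top <- names(tab)[tab == max(tab)]
    data.frame(locus_id = l, frequent_allele = sort(top)[1],
               tie = length(top) > 1, p_fnd = max(tab) / length(a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Collapse multi-allelic SSR loci to biallelic form
#'
#' At each SSR locus the most frequent allele in the virtual founding
#' population is kept as the first allele and all other alleles are pooled
#' into a synthetic second allele `"OTHER"`. SNP loci pass through
#' unchanged, but their frequent-in-FND allele is recorded too, so every
#' locus has a designated reference allele for downstream frequency and
#' effect work. The same recoding map (derived from FND only) is applied
#' to every population and generation. Ties for the most frequent allele
#' are resolved lexicographically and logged in the recode map.
#'
#' @param genotypes [genotype_table()] to recode.
#' @param fnd virtual-founder [genotype_table()] (or a recode map data
#'   frame previously obtained from `attr(result, "recode_map")`).
#' @return recoded [genotype_table()] with `frequent_allele` set in its
#'   panel and the recode map attached as `attr(x, "recode_map")`.
#' @export
collapse_to_biallelic <- function(genotypes, fnd) {
  map <- if (inherits(fnd, "genotype_table")) fnd_frequent_alleles(fnd)
         else fnd
  assert_cols(map, c("locus_id", "frequent_allele"), "recode map")
  panel <- genotypes$panel
  r <- genotypes$records
  for (j in seq_len(nrow(panel))) {
    l <- panel$locus_id[j]
    k <- match(l, map$locus_id)
    if (is.na(k)) stop_ccp("collapse_to_biallelic: locus ", l,
                           " missing from FND recode map")
    freq <- map$frequent_allele[k]
    panel$frequent_allele[j] <- freq
    if (panel$marker_type[j] == "SSR") {
      sel <- r$locus_id == l
      pool_a <- sel & !is.na(r$allele_a) & r$allele_a != freq
      pool_b <- sel & !is.na(r$allele_b) & r$allele_b != freq
      r$allele_a[pool_a] <- "OTHER"
      r$allele_b[pool_b] <- "OTHER"
      panel$allele_labels[[j]] <- c(freq, "OTHER")
    }
  }
  out <- structure(list(records = r, panel = panel),
                   class = "genotype_table")
  attr(out, "recode_map") <- map
  out
}

#' Allele-frequency table of the designated reference allele
#'
#' Computes, per population x generation x locus, the frequency of the
#' frequent-in-FND allele by gene counting: frequent allele copies over
#' twice the number of individuals with a non-missing call (complete-case
#' per locus). Requires [collapse_to_biallelic()] to have designated the
#' reference allele at every locus.
#'
#' @param genotypes recoded [genotype_table()].
#' @return data frame with columns `population`, `generation`, `locus_id`,
#'   `p`, `n_obs` (gene copies observed).
#' @export
allele_frequencies <- function(genotypes) {
  panel <- genotypes$panel
  if (anyNA(panel$frequent_allele))
    stop_ccp("allele_frequencies: frequent_allele unset; run ",
             "collapse_to_biallelic first")
  r <- genotypes$records
  complete <- !is.na(r$allele_a) & !is.na(r$allele_b)
  r <- r[complete, , drop = FALSE]
  freq_of <- panel$frequent_allele[match(r$locus_id, panel$locus_id)]
  copies <- (r$allele_a == freq_of) + (r$allele_b == freq_of)
  key <- paste(r$population, r$generation, r$locus_id, sep = "\r")
  cnt <- rowsum(cbind(copies = copies, n = 2L), key)
  parts <- strsplit(rownames(cnt), "\r", fixed = TRUE)
  out <- data.frame(
    population = vapply(parts, `[`, "", 1L),
    generation = as.integer(vapply(parts, `[`, "", 2L)),
    locus_id = vapply(parts, `[`, "", 3L),
    p = cnt[, "copies"] / cnt[, "n"],
    n_obs = as.integer(cnt[, "n"]), stringsAsFactors = FALSE,
    row.names = NULL)
  # warn about samples where a panel locus has no data at all
  pops <- unique(r[, c("population", "generation")])
  expected <- nrow(pops) * nrow(panel)
  if (nrow(out) < expected)
    warning(sprintf(
      "allele_frequencies: %d population x locus cell(s) had no calls",
      expected - nrow(out)), call. = FALSE)
  out[order(out$population, out$generation, out$locus_id), ]
}
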