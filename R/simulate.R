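#' Simulation parameters for a composite cross population
#'
#' Defaults emulate the structure of a winter-wheat composite cross
#' experiment: 20 fully homozygous parent varieties, 93 successful crosses
#' with strongly unequal F2 seed counts (mean 957, range 37-2569), a panel
#' of 20 multi-allelic SSR loci plus 8 biallelic functional (SNP) loci, a
#' census of about 32,000 plants per location but an effective size of
#' only ~200, a selfing rate of 0.98, four locations separating at
#' generation 2 and evolving independently to generation 10, and sampling
#' for genotyping at generations 3, 6 and 10.
#'
#' @param n_parents number of homozygous parent varieties.
#' @param n_crosses number of distinct crosses.
#' @param seed_count_mean,seed_count_min,seed_count_max per-cross F2 seed
#'   count distribution.
#' @param n_loci_ssr,n_loci_snp panel composition.
#' @param alleles_per_ssr alleles per SSR locus (>= 2).
#' @param census_size plants grown per location per generation.
#' @param target_Ne effective number of reproducing individuals imposed
#'   per generation (drift intensity known by construction).
#' @param selfing_rate probability an offspring is produced by selfing.
#' @param selection_coefficients named numeric of per-locus selection
#'   coefficients `s`; fecundity is proportional to
#'   `exp(sum(s * dosage))` of the favoured allele.
#' @param favored_alleles named character giving the favoured allele per
#'   selected locus; defaults to the wild-type label `"wt"` at SNP loci
#'   and the first allele label at SSR loci.
#' @param trait_model named list per trait:
#'   `list(mu =, effects = c(locus = per-copy effect of the favoured
#'   allele), residual_sd =, trial_sd =, interaction_sd =)`.
#' @param n_locations number of locations (populations).
#' @param n_generations final generation.
#' @param separation_generation last generation shared by all locations.
#' @param sample_sizes named integer map generation -> individuals
#'   genotyped per location.
#' @param phenotyped_locations locations where single plants are
#'   phenotyped in the mixed stand (the organically managed pair in the
#'   emulated design).
#' @param phenotyped_generations generations with single-plant
#'   phenotyping.
#' @param n_trials_pure,n_reps_pure pure-stand trial structure (3 years x
#'   4 locations x 3 replicate blocks by default).
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_parents = 20, n_crosses = 93,
                       seed_count_mean = 957, seed_count_min = 37,
                       seed_count_max = 2569,
                       n_loci_ssr = 20, n_loci_snp = 8, alleles_per_ssr = 4,
                       census_size = 32000, target_Ne = 200,
                       selfing_rate = 0.98,
                       selection_coefficients = numeric(),
                       favored_alleles = character(),
                       trait_model = default_trait_model(),
                       n_locations = 4, n_generations = 10,
                       separation_generation = 2,
                       sample_sizes = c("3" = 150, "6" = 300, "10" = 500),
                       phenotyped_locations = NULL,
                       phenotyped_generations = c(6, 10),
                       n_trials_pure = 12, n_reps_pure = 3) {
  p <- as.list(environment())
  if (selfing_rate < 0 || selfing_rate > 1)
    stop_ccp("sim_params: selfing_rate must be in [0, 1]")
  if (target_Ne > census_size)
    stop_ccp("sim_params: target_Ne cannot exceed census_size")
  if (alleles_per_ssr < 2) stop_ccp("sim_params: alleles_per_ssr must be >= 2")
  if (n_crosses > n_parents * (n_parents - 1) / 2)
    stop_ccp("sim_params: n_crosses exceeds the number of distinct pairs")
  if (seed_count_mean < seed_count_min || seed_count_mean > seed_count_max)
    stop_ccp("sim_params: seed_count_mean outside [min, max]")
  if (max(as.integer(names(sample_sizes))) > n_generations)
    stop_ccp("sim_params: sample_sizes refer to generations beyond the run")
  class(p) <- "sim_params"
  p
}

# Functional genes the default SNP panel is diagnostic for; annotation
# carries the trait and the wild-type allele label.
default_snp_names <- function(n) {
  nm <- c("Rht-B1", "Rht-D1", "Ppd-A1", "Ppd-B1", "Ppd-D1", "Ppd-D1-D2",
          "Vrn-A1", "T1B.1R")
  if (n <= length(nm)) nm[seq_len(n)]
  else c(nm, sprintf("snp%02d", seq_len(n - length(nm))))
}

#' Default trait model of the simulator
#'
#' Two traits with additive genetic architecture on the functional loci:
#' plant height (cm; wild-type alleles at the height genes are taller) and
#' heading date (days; wild-type photoperiod-sensitivity alleles head
#' later). Effects are per copy of the favoured (wild-type) allele.
#'
#' @return named list usable as `trait_model` in [sim_params()].
#' @export
default_trait_model <- function() {
  list(
    height = list(mu = 100,
                  effects = c("Rht-B1" = 4, "Rht-D1" = 5, "Ppd-D1" = 2),
                  residual_sd = 8, trial_sd = 5, interaction_sd = 2),
    heading_date = list(mu = 152,
                        effects = c("Ppd-A1" = 1.5, "Ppd-B1" = 1,
                                    "Ppd-D1" = 2),
                        residual_sd = 4, trial_sd = 3, interaction_sd = 1))
}

default_locations <- function(n) {
  loc <- c("MET", "MOR", "SOF", "WAF")
  if (n <= 4) loc[seq_len(n)] else c(loc, sprintf("L%02d", seq_len(n - 4)))
}

#' Generate homozygous parental genotypes
#'
#' Draws `n_parents` fully homozygous multilocus genotypes over the panel:
#' SSR loci carry `alleles_per_ssr` fragment-size-style allele labels, SNP
#' loci carry `wt`/`mut`. Every locus is guaranteed to segregate (at least
#' two alleles present among the parents).
#'
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @return parental [genotype_table()] (population `"PARENTS"`).
#' @export
make_parents <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, {
    n <- params$n_parents
    ssr_ids <- sprintf("ssr%02d", seq_len(params$n_loci_ssr))
    snp_ids <- default_snp_names(params$n_loci_snp)
    labels <- c(
      lapply(seq_len(params$n_loci_ssr), function(j)
        as.character(seq(120 + 4 * j, by = 2,
                         length.out = params$alleles_per_ssr))),
      rep(list(c("wt", "mut")), params$n_loci_snp))
    loci <- c(ssr_ids, snp_ids)
    draw_locus <- function(lab) {
      k <- length(lab)
      repeat {
        # mildly skewed allele frequencies among parents
        w <- stats::rgamma(k, shape = 1.5)
        a <- sample(lab, n, replace = TRUE, prob = w / sum(w))
        if (length(unique(a)) >= 2) return(a)
      }
    }
    calls <- vapply(labels, draw_locus, character(n))   # n x L matrix
    ids <- sprintf("P%02d", seq_len(n))
    rec <- data.frame(
      individual_id = rep(ids, times = length(loci)),
      population = "PARENTS", generation = 0L, location = "",
      locus_id = rep(loci, each = n),
      allele_a = as.vector(calls), allele_b = as.vector(calls),
      stringsAsFactors = FALSE)
    panel <- locus_panel(
      loci,
      rep(c("SSR", "SNP"), c(params$n_loci_ssr, params$n_loci_snp)),
      labels,
      annotation = c(rep(NA_character_, params$n_loci_ssr),
                     paste0("functional gene; wild-type allele = wt")[
                       rep(1, params$n_loci_snp)]))
    genotype_table(rec, panel)
  })
}

#' Generate a crossing scheme with unequal seed counts
#'
#' Samples `n_crosses` distinct unordered parent pairs and integer F2 seed
#' counts from a scaled Beta distribution truncated to
#' `[seed_count_min, seed_count_max]`, redrawing until the empirical mean
#' is within 10% of `seed_count_mean` (the strongly right-skewed,
#' bounded shape observed for real per-cross seed yields).
#'
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @return a [crossing_scheme()].
#' @export
make_crossing_scheme <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(params$n_parents))
    all_pairs <- utils::combn(ids, 2)
    pick <- sample(ncol(all_pairs), params$n_crosses)
    lo <- params$seed_count_min; hi <- params$seed_count_max
    mu <- params$seed_count_mean
    counts <- if (lo == hi) rep(lo, params$n_crosses) else {
      f <- (mu - lo) / (hi - lo)
      for (try in 1:1000) {
        x <- round(lo + (hi - lo) *
                     stats::rbeta(params$n_crosses, 2 * f, 2 * (1 - f)))
        x <- pmin(hi, pmax(lo, x))
        if (abs(mean(x) - mu) <= 0.1 * mu) break
      }
      if (abs(mean(x) - mu) > 0.1 * mu)
        stop_ccp("make_crossing_scheme: could not match the target mean; ",
                 "check the (mean, min, max) triple")
      x
    }
    crossing_scheme(data.frame(parent_i = all_pairs[1, pick],
                               parent_j = all_pairs[2, pick],
                               seed_count = as.integer(counts),
                               stringsAsFactors = FALSE))
  })
}

# ---- internal matrix representation -----------------------------------

# genotype_table (homozygous parents) -> list(mat = parent x locus integer
# codes, labels = per-locus label list, loci, panel)
parents_to_codes <- function(parents) {
  loci <- parents$panel$locus_id
  labels <- parents$panel$allele_labels
  ids <- unique(parents$records$individual_id)
  m <- matrix(NA_integer_, length(ids), length(loci),
              dimnames = list(ids, loci))
  r <- parents$records
  code <- mapply(function(a, l) match(a, labels[[match(l, loci)]]),
                 r$allele_a, r$locus_id)
  m[cbind(match(r$individual_id, ids), match(r$locus_id, loci))] <-
    as.integer(code)
  list(mat = m, labels = labels, loci = loci, panel = parents$panel)
}

# Multilocus inbreeding coefficient F = 1 - Hobs/Hexp of the current
# population (0 = outbred, 1 = fully selfed). Drives the reproducer-count
# adjustment that keeps the effective number of transmitted gene copies
# at 2 * target_Ne whatever the selfing rate: 2n/(1+F) independent copies
# among n inbred reproducers.
inbreeding_coef <- function(A1, A2, labels) {
  hobs <- hexp <- numeric(ncol(A1))
  for (j in seq_len(ncol(A1))) {
    a <- c(A1[, j], A2[, j])
    p <- tabulate(a, nbins = length(labels[[j]])) / length(a)
    hexp[j] <- 1 - sum(p^2)
    hobs[j] <- mean(A1[, j] != A2[, j])
  }
  ok <- hexp > 1e-9
  if (!any(ok)) return(1)
  min(1, max(0, 1 - sum(hobs[ok]) / sum(hexp[ok])))
}

# One generation step: pick the reproducing individuals (fecundity-
# weighted, without replacement), then produce `census` offspring by
# selfing with probability selfing_rate, else random outcrossing among
# reproducers. `ne` is the number of reproducing individuals, already
# adjusted for inbreeding by the caller.
step_generation <- function(A1, A2, ne, census, selfing, fec) {
  n <- nrow(A1)
  repro <- if (is.null(fec)) sample.int(n, min(ne, n))
           else sample.int(n, min(ne, n), prob = fec)
  p1 <- repro[sample.int(length(repro), census, replace = TRUE)]
  self <- stats::runif(census) < selfing
  p2 <- ifelse(self, p1,
               repro[sample.int(length(repro), census, replace = TRUE)])
  L <- ncol(A1)
  pick <- function(parent) {
    u <- matrix(stats::runif(census * L) < 0.5, census, L)
    out <- A1[parent, , drop = FALSE]
    alt <- A2[parent, , drop = FALSE]
    out[!u] <- alt[!u]
    out
  }
  list(A1 = pick(p1), A2 = pick(p2))
}

# fecundity weights exp(sum s * dosage) or NULL when neutral
fecundity <- function(A1, A2, sel_codes) {
  if (!nrow(sel_codes)) return(NULL)
  w <- rep(0, nrow(A1))
  for (i in seq_len(nrow(sel_codes))) {
    j <- sel_codes$col[i]
    dos <- (A1[, j] == sel_codes$code[i]) + (A2[, j] == sel_codes$code[i])
    w <- w + sel_codes$s[i] * dos
  }
  exp(w)
}

# per-locus frequency of every allele label (long data frame)
truth_freqs <- function(A1, A2, labels, loci, location, generation) {
  rows <- lapply(seq_along(loci), function(j) {
    a <- c(A1[, j], A2[, j])
    tab <- tabulate(a, nbins = length(labels[[j]]))
    data.frame(location = location, generation = generation,
               locus_id = loci[j], allele = labels[[j]],
               freq = tab / length(a), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Forward-time simulation of composite cross populations
#'
#' Builds the F1 genotypes of every cross, expands them into a pooled F2
#' generation sized by the per-cross seed counts (generation 1), keeps a
#' single shared population up to `separation_generation`, then evolves
#' each location independently to `n_generations`. Each generation,
#' `2 * target_Ne` effective gene transmissions are imposed by drawing
#' `target_Ne * (1 + F)` reproducing individuals (F the population's
#' current inbreeding coefficient; fecundity-weighted under selection,
#' uniformly otherwise) and producing `census_size` offspring by selfing
#' with probability `selfing_rate`, otherwise random outcrossing. The
#' inbreeding adjustment keeps the drift intensity at the nominal
#' `target_Ne` whatever the selfing rate, so parameter-recovery tests
#' have a known truth. No mutation and no migration: every allele
#' present in any generation descends from the parents.
#'
#' @param parents parental [genotype_table()] from [make_parents()].
#' @param scheme a [crossing_scheme()] (e.g. [make_crossing_scheme()]).
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @return a `sim_output` list: `genotypes` (sampled individuals,
#'   populations labelled by location), `truth` (true per-allele frequency
#'   trajectories per location), `parents`, `scheme`, `params`.
#' @export
simulate_generations <- function(parents, scheme, params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  pc <- parents_to_codes(parents)
  if (anyNA(pc$mat)) stop_ccp("simulate_generations: parent genotype missing")
  locations <- default_locations(params$n_locations)
  with_seed(seed, {
    L <- length(pc$loci)
    census <- params$census_size
    # selection bookkeeping: column index + favoured allele code per locus
    sel <- params$selection_coefficients
    sel_codes <- if (length(sel)) {
      miss <- setdiff(names(sel), pc$loci)
      if (length(miss))
        stop_ccp("simulate_generations: selected locus not in panel: ",
                 paste(miss, collapse = ", "))
      cols <- match(names(sel), pc$loci)
      fav <- vapply(seq_along(sel), function(i) {
        lab <- pc$labels[[cols[i]]]
        f <- params$favored_alleles[names(sel)[i]]
        if (!is.na(f) && length(f) && f %in% lab) match(f, lab)
        else if ("wt" %in% lab) match("wt", lab) else 1L
      }, 1L)
      data.frame(col = cols, code = fav, s = as.numeric(sel))
    } else data.frame(col = integer(), code = integer(), s = numeric())
    # generation 1: pooled F2, crosses drawn proportional to seed counts
    ci <- match(scheme$parent_i, rownames(pc$mat))
    cj <- match(scheme$parent_j, rownames(pc$mat))
    cross <- sample.int(nrow(scheme), census, replace = TRUE,
                        prob = scheme$seed_count)
    gi <- pc$mat[ci[cross], , drop = FALSE]   # census x L codes, parent i
    gj <- pc$mat[cj[cross], , drop = FALSE]
    f2_draw <- function() {
      u <- matrix(stats::runif(census * L) < 0.5, census, L)
      out <- gi; out[!u] <- gj[!u]; out
    }
    pop <- list(A1 = f2_draw(), A2 = f2_draw())
    truth <- list()
    rec_truth <- function(pop, loc, gen)
      truth_freqs(pop$A1, pop$A2, pc$labels, pc$loci, loc, gen)
    truth[[length(truth) + 1]] <- rec_truth(pop, "shared", 1L)
    # reproducing individuals needed for 2 * target_Ne effective gene
    # transmissions given the population's current inbreeding level
    n_repro <- function(pop) {
      f <- inbreeding_coef(pop$A1, pop$A2, pc$labels)
      min(census, max(2L, as.integer(round(params$target_Ne * (1 + f)))))
    }
    # shared generations up to the separation point
    g <- 1L
    while (g < params$separation_generation) {
      g <- g + 1L
      fec <- fecundity(pop$A1, pop$A2, sel_codes)
      pop <- step_generation(pop$A1, pop$A2, n_repro(pop), census,
                             params$selfing_rate, fec)
      truth[[length(truth) + 1]] <- rec_truth(pop, "shared", g)
    }
    # independent evolution per location
    samples <- list()
    smp_gens <- as.integer(names(params$sample_sizes))
    for (loc in locations) {
      lpop <- pop
      for (gg in seq(params$separation_generation + 1L,
                     params$n_generations)) {
        fec <- fecundity(lpop$A1, lpop$A2, sel_codes)
        lpop <- step_generation(lpop$A1, lpop$A2, n_repro(lpop), census,
                                params$selfing_rate, fec)
        truth[[length(truth) + 1]] <- rec_truth(lpop, loc, gg)
        if (gg %in% smp_gens) {
          ns <- params$sample_sizes[[as.character(gg)]]
          idx <- sample.int(census, min(ns, census))
          ids <- sprintf("%s_g%02d_%04d", loc, gg, seq_along(idx))
          samples[[length(samples) + 1]] <- data.frame(
            individual_id = rep(ids, times = L),
            population = loc, generation = gg,
            location = loc, locus_id = rep(pc$loci, each = length(idx)),
            allele_a = unlist(lapply(seq_len(L), function(j)
              pc$labels[[j]][lpop$A1[idx, j]])),
            allele_b = unlist(lapply(seq_len(L), function(j)
              pc$labels[[j]][lpop$A2[idx, j]])),
            stringsAsFactors = FALSE)
        }
      }
    }
    genotypes <- genotype_table(do.call(rbind, samples), pc$panel)
    structure(list(genotypes = genotypes,
                   truth = do.call(rbind, truth),
                   parents = parents, scheme = scheme, params = params,
                   target_Ne = params$target_Ne),
              class = "sim_output")
  })
}

#' Simulate single-plant and pure-stand phenotypes
#'
#' Mixed-stand values are generated for the sampled individuals of the
#' phenotyped locations and generations as
#' `y = mu + sum(effect * dosage) + trial + noise` with a random trial
#' effect per location x generation trial. Pure-stand values are plot
#' observations of every parent variety in a replicated multi-trial
#' design, with trial, block-in-trial, variety x trial and residual
#' noise around the same additive genetic values.
#'
#' @param sim a `sim_output` from [simulate_generations()].
#' @param params a [sim_params()] (defaults to the one stored in `sim`).
#' @param seed RNG seed.
#' @return a `trait_table` with both stand types.
#' @export
simulate_phenotypes <- function(sim, params = sim$params, seed = NULL) {
  stopifnot(inherits(sim, "sim_output"))
  tm <- params$trait_model
  if (!length(tm)) stop_ccp("simulate_phenotypes: empty trait_model")
  panel <- sim$genotypes$panel
  for (tr in names(tm)) {
    miss <- setdiff(names(tm[[tr]]$effects), panel$locus_id)
    if (length(miss))
      stop_ccp("simulate_phenotypes: effect on missing locus: ",
               paste(miss, collapse = ", "))
  }
  locations <- params$phenotyped_locations %||%
    utils::tail(default_locations(params$n_locations), 2)
  with_seed(seed, {
    rows <- list()
    r <- sim$genotypes$records
    mixed <- r[r$location %in% locations &
                 r$generation %in% params$phenotyped_generations, ]
    if (nrow(mixed)) {
      inds <- unique(mixed[, c("individual_id", "population", "generation",
                               "location")])
      trial <- paste0(inds$location, "_g", inds$generation)
      trials <- unique(trial)
      for (tr in names(tm)) {
        mdl <- tm[[tr]]
        gval <- genetic_values(mixed, panel, mdl$effects)
        t_eff <- stats::setNames(stats::rnorm(length(trials), 0,
                                              mdl$trial_sd), trials)
        rows[[length(rows) + 1]] <- data.frame(
          unit_id = inds$individual_id, stand = "mixed_single_plant",
          trial = trial, replicate_block = NA_character_,
          variety = NA_character_, trait = tr,
          value = mdl$mu + gval[inds$individual_id] + t_eff[trial] +
            stats::rnorm(nrow(inds), 0, mdl$residual_sd),
          stringsAsFactors = FALSE)
      }
    }
    # pure stands: parent varieties x trials x replicate blocks
    pr <- sim$parents$records
    varieties <- unique(pr$individual_id)
    trials_p <- sprintf("trial%02d", seq_len(params$n_trials_pure))
    reps <- sprintf("rep%d", seq_len(params$n_reps_pure))
    grid <- expand.grid(variety = varieties, trial = trials_p,
                        replicate_block = reps, stringsAsFactors = FALSE)
    for (tr in names(tm)) {
      mdl <- tm[[tr]]
      gval <- genetic_values(pr, panel, mdl$effects)
      t_eff <- stats::setNames(stats::rnorm(length(trials_p), 0,
                                            mdl$trial_sd), trials_p)
      blocks <- unique(grid[, c("trial", "replicate_block")])
      b_key <- paste(blocks$trial, blocks$replicate_block)
      b_eff <- stats::setNames(stats::rnorm(nrow(blocks), 0,
                                            mdl$trial_sd / 2), b_key)
      vt <- expand.grid(variety = varieties, trial = trials_p,
                        stringsAsFactors = FALSE)
      vt_key <- paste(vt$variety, vt$trial)
      vt_eff <- stats::setNames(stats::rnorm(nrow(vt), 0,
                                             mdl$interaction_sd %||% 0),
                                vt_key)
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = paste(grid$variety, grid$trial, grid$replicate_block,
                        sep = "_"),
        stand = "pure_plot", trial = grid$trial,
        replicate_block = grid$replicate_block, variety = grid$variety,
        trait = tr,
        value = mdl$mu + gval[grid$variety] + t_eff[grid$trial] +
          b_eff[paste(grid$trial, grid$replicate_block)] +
          vt_eff[paste(grid$variety, grid$trial)] +
          stats::rnorm(nrow(grid), 0, mdl$residual_sd),
        stringsAsFactors = FALSE)
    }
    trait_table(do.call(rbind, rows))
  })
}

# additive genetic value per individual: sum over effect loci of
# effect * dosage of the favoured (wild-type-labelled) allele
genetic_values <- function(records, panel, effects) {
  ids <- unique(records$individual_id)
  g <- stats::setNames(rep(0, length(ids)), ids)
  for (l in names(effects)) {
    lab <- panel$allele_labels[[match(l, panel$locus_id)]]
    fav <- if ("wt" %in% lab) "wt" else lab[1]
    sel <- records$locus_id == l
    dos <- (records$allele_a[sel] == fav) + (records$allele_b[sel] == fav)
    g[records$individual_id[sel]] <- g[records$individual_id[sel]] +
      effects[[l]] * dos
  }
  g
}
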