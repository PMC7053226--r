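# Homozygote allele class ("frequent" vs "other") at a locus for a set of
# genotype records; heterozygotes and missing calls are excluded at the
# tested locus only.
homozygote_classes <- function(genotypes, locus) {
  panel <- genotypes$panel
  j <- match(locus, panel$locus_id)
  if (is.na(j)) stop_ccp("unknown locus: ", locus)
  ref <- panel$frequent_allele[j]
  if (is.na(ref))
    stop_ccp("locus ", locus, " has no designated frequent allele; run ",
             "collapse_to_biallelic first")
  r <- genotypes$records
  r <- r[r$locus_id == locus & !is.na(r$allele_a) & !is.na(r$allele_b) &
           r$allele_a == r$allele_b, , drop = FALSE]
  cls <- ifelse(r$allele_a == ref, "frequent", "other")
  stats::setNames(factor(cls, levels = c("other", "frequent")),
                  r$individual_id)
}

effect_estimate <- function(locus, trait, stand, additive_effect = NA_real_,
                            se = NA_real_, f_stat = NA_real_,
                            df_num = NA_real_, df_den = NA_real_,
                            p_value = NA_real_, n_used = NA_integer_,
                            note = NA_character_) {
  structure(list(locus_id = locus, trait = trait, stand = stand,
                 additive_effect = additive_effect, se = se, f_stat = f_stat,
                 df_num = df_num, df_den = df_den, p_value = p_value,
                 n_used = n_used, note = note),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s on %s (%s): a = %.3f (se %.3f), F = %.2f, p = %.3g, n = %d%s\n",
              x$locus_id, x$trait, x$stand, x$additive_effect, x$se,
              x$f_stat, x$p_value, x$n_used,
              if (is.na(x$note)) "" else paste0(" [", x$note, "]")))
  invisible(x)
}

#' Additive allele effect from single plants in the mixed stand
#'
#' Fits, for one marker locus and one trait, the single-locus mixed model
#' `y = mu + allele_class + (1 | trial) + (1 | allele_class:trial) + e`
#' on the homozygous single plants measured inside the mixed population
#' (the allele class is fixed; trial, allele x trial and residual are
#' random). The allele-class contrast is tested by an F-test with
#' Satterthwaite denominator degrees of freedom, and the additive allele
#' effect of the frequent allele is half the fitted
#' frequent-minus-other-homozygote difference. When a random term has
#' zero estimated variance (singular fit) it is dropped and the model
#' refitted, down to an ordinary one-way fit; the `note` field records
#' the reduction.
#'
#' @param traits a `trait_table`.
#' @param genotypes a recoded [genotype_table()] of the same individuals.
#' @param locus,trait the marker locus and trait to test.
#' @param min_class minimum homozygous plants per allele class
#'   (default 2).
#' @return an `effect_estimate` (fields `NA` with a `note` when the
#'   estimate is undefined, e.g. one homozygote class absent).
#' @export
mixed_stand_effect <- function(traits, genotypes, locus, trait,
                               min_class = 2) {
  tt <- traits[traits$stand == "mixed_single_plant" &
                 traits$trait == trait, , drop = FALSE]
  if (!nrow(tt)) return(effect_estimate(locus, trait, "mixed",
                                        note = "no mixed-stand records"))
  cls <- homozygote_classes(genotypes, locus)
  d <- data.frame(value = tt$value, trial = tt$trial,
                  allele_class = cls[tt$unit_id], stringsAsFactors = FALSE)
  d <- d[!is.na(d$allele_class) & !is.na(d$value), , drop = FALSE]
  counts <- table(d$allele_class)
  if (any(counts < min_class))
    return(effect_estimate(locus, trait, "mixed", n_used = nrow(d),
                           note = paste0("homozygote class under-represented (",
                                         paste(names(counts), counts,
                                               sep = "=", collapse = ", "),
                                         ")")))
  if (length(unique(d$trial)) < 2)
    return(effect_estimate(locus, trait, "mixed", n_used = nrow(d),
                           note = "fewer than 2 trials"))
  d$trial <- factor(d$trial)
  quiet_lmer <- function(formula) tryCatch(
    suppressMessages(suppressWarnings(lmerTest::lmer(formula, data = d,
                                                     REML = TRUE))),
    error = function(e) NULL)
  fit <- quiet_lmer(value ~ allele_class + (1 | trial) +
                      (1 | allele_class:trial))
  note <- NA_character_
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    fit <- quiet_lmer(value ~ allele_class + (1 | trial))
    note <- "allele x trial variance ~ 0; term dropped"
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      lmfit <- stats::lm(value ~ allele_class, data = d)
      an <- stats::anova(lmfit)
      co <- summary(lmfit)$coefficients
      return(effect_estimate(locus, trait, "mixed",
        additive_effect = co["allele_classfrequent", "Estimate"] / 2,
        se = co["allele_classfrequent", "Std. Error"] / 2,
        f_stat = an["allele_class", "F value"],
        df_num = an["allele_class", "Df"],
        df_den = an["Residuals", "Df"],
        p_value = an["allele_class", "Pr(>F)"], n_used = nrow(d),
        note = "all random variances ~ 0; ordinary one-way fit"))
    }
  }
  an <- stats::anova(fit, ddf = "Satterthwaite")
  co <- summary(fit)$coefficients
  effect_estimate(locus, trait, "mixed",
    additive_effect = co["allele_classfrequent", "Estimate"] / 2,
    se = co["allele_classfrequent", "Std. Error"] / 2,
    f_stat = an["allele_class", "F value"],
    df_num = an["allele_class", "NumDF"],
    df_den = an["allele_class", "DenDF"],
    p_value = an["allele_class", "Pr(>F)"], n_used = nrow(d), note = note)
}

#' Additive allele effect from pure-stand variety trials
#'
#' Two-stage analysis of the parent varieties grown as pure plots.
#' Stage 1 estimates variety LS-means (equal trial weights) from
#' `y = mu + variety + (1 | trial) + (1 | trial:replicate_block) +
#' (1 | variety:trial) + e`. Stage 2 regresses the LS-means on the
#' homozygous allele class at the locus with a fixed one-way model; the
#' additive effect is again half the frequent-allele coefficient.
#' Varieties with a heterozygous or missing call at the locus are
#' excluded (logged in `note`).
#'
#' @param traits a `trait_table` (the `pure_plot` records are used).
#' @param parent_genotypes parental [genotype_table()] with the recoding
#'   applied.
#' @inheritParams mixed_stand_effect
#' @param min_class minimum varieties per allele class (default 2).
#' @return an `effect_estimate` with `stand = "pure"`.
#' @export
pure_stand_effect <- function(traits, parent_genotypes, locus, trait,
                              min_class = 2) {
  tt <- traits[traits$stand == "pure_plot" & traits$trait == trait, ,
               drop = FALSE]
  if (!nrow(tt)) return(effect_estimate(locus, trait, "pure",
                                        note = "no pure-stand records"))
  d <- data.frame(value = tt$value, variety = factor(tt$variety),
                  trial = factor(tt$trial),
                  block = factor(paste(tt$trial, tt$replicate_block)),
                  stringsAsFactors = FALSE)
  quiet_lmer <- function(formula) tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(formula, data = d,
                                                 REML = TRUE))),
    error = function(e) NULL)
  fit <- quiet_lmer(value ~ variety + (1 | trial) + (1 | block) +
                      (1 | variety:trial))
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5))
    fit <- quiet_lmer(value ~ variety + (1 | trial) + (1 | block))
  if (is.null(fit))
    fit <- if (nlevels(d$trial) > 1)
      stats::lm(value ~ variety + trial, data = d)
    else stats::lm(value ~ variety, data = d)
  em <- suppressMessages(emmeans::emmeans(fit, "variety",
                                          lmer.df = "asymptotic"))
  ls <- as.data.frame(em)
  lsmeans <- stats::setNames(ls$emmean, as.character(ls$variety))
  cls <- homozygote_classes(parent_genotypes, locus)
  varieties <- names(lsmeans)
  cc <- cls[varieties]
  excluded <- varieties[is.na(cc)]
  d2 <- data.frame(lsmean = lsmeans[!is.na(cc)],
                   allele_class = cc[!is.na(cc)])
  counts <- table(d2$allele_class)
  if (any(counts == 0))
    return(effect_estimate(locus, trait, "pure", n_used = nrow(d2),
                           note = "single class"))
  if (any(counts < min_class))
    return(effect_estimate(locus, trait, "pure", n_used = nrow(d2),
                           note = "allele class under-represented"))
  lmfit <- stats::lm(lsmean ~ allele_class, data = d2)
  # a perfect fit (noiseless validation data) warns harmlessly here
  an <- suppressWarnings(stats::anova(lmfit))
  co <- suppressWarnings(summary(lmfit))$coefficients
  note <- if (length(excluded))
    paste0("excluded (het/missing at locus): ",
           paste(excluded, collapse = ", ")) else NA_character_
  effect_estimate(locus, trait, "pure",
    additive_effect = co["allele_classfrequent", "Estimate"] / 2,
    se = co["allele_classfrequent", "Std. Error"] / 2,
    f_stat = an["allele_class", "F value"],
    df_num = an["allele_class", "Df"],
    df_den = an["Residuals", "Df"],
    p_value = an["allele_class", "Pr(>F)"], n_used = nrow(d2), note = note)
}

#' Effect estimates for many loci and traits
#'
#' @param traits a `trait_table`.
#' @param genotypes genotypes joined to the mixed-stand plants
#'   (`stand = "mixed"`) or the parent varieties (`stand = "pure"`).
#' @param loci,trait_names loci and traits to cover (defaults: all loci of
#'   the panel, all traits present for the stand).
#' @param stand `"mixed"` or `"pure"`.
#' @return data frame with one row per locus x trait.
#' @export
effects_table <- function(traits, genotypes, loci = NULL, trait_names = NULL,
                          stand = c("mixed", "pure")) {
  stand <- match.arg(stand)
  loci <- loci %||% genotypes$panel$locus_id
  stand_label <- if (stand == "mixed") "mixed_single_plant" else "pure_plot"
  trait_names <- trait_names %||%
    sort(unique(traits$trait[traits$stand == stand_label]))
  rows <- list()
  for (tr in trait_names) for (l in loci) {
    e <- if (stand == "mixed") mixed_stand_effect(traits, genotypes, l, tr)
         else pure_stand_effect(traits, genotypes, l, tr)
    rows[[length(rows) + 1]] <-
      data.frame(locus_id = e$locus_id, trait = e$trait, stand = e$stand,
                 additive_effect = e$additive_effect, se = e$se,
                 f_stat = e$f_stat, df_num = e$df_num, df_den = e$df_den,
                 p_value = e$p_value, n_used = e$n_used, note = e$note,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

effect_correlation <- function(ct, trait, scope) {
  structure(list(trait = trait, scope = scope, r = ct$r, L = ct$L,
                 df = ct$df, p_value = ct$p_value,
                 stars = significance_stars(ct$p_value)),
            class = "effect_correlation")
}

#' @export
print.effect_correlation <- function(x, ...) {
  cat(sprintf("<effect_correlation> %s / %s: r = %.2f %s (df = %d)\n",
              x$trait, x$scope, x$r, x$stars, x$df))
  invisible(x)
}

#' Correlate allele-frequency change with additive allele effects
#'
#' Pearson correlation, over loci, between the frequency change of the
#' frequent allele (founder to final generation) and its additive effect
#' on a trait, with the t-test on `L - 2` degrees of freedom. A positive
#' correlation means alleles increasing the trait rose in frequency.
#'
#' @param dp named per-locus frequency changes (`delta p`).
#' @param effects named per-locus additive effects (same allele
#'   convention).
#' @param trait,scope labels stored on the result (e.g. trait name and
#'   `"overall"` or a location).
#' @return an `effect_correlation`.
#' @export
correlate_dp_vs_effect <- function(dp, effects, trait = "trait",
                                   scope = "overall") {
  effect_correlation(pearson_test(dp, effects), trait, scope)
}

#' Correlate two per-locus effect vectors
#'
#' Same test as [correlate_dp_vs_effect()] but between two additive-effect
#' vectors — e.g. the effects on plant height versus the effects on a
#' yield component, or mixed-stand versus pure-stand effects of one trait
#' (the pleiotropy / stand-contrast view).
#'
#' @param effects_a,effects_b named per-locus effect vectors.
#' @param trait,scope labels stored on the result.
#' @return an `effect_correlation`.
#' @export
correlate_effect_vs_effect <- function(effects_a, effects_b,
                                       trait = "trait", scope = "overall") {
  effect_correlation(pearson_test(effects_a, effects_b), trait, scope)
}

#' Trait x scope grid of effect/frequency-change correlations
#'
#' Shapes correlations between per-trait additive effects and
#' allele-frequency changes into the conventional grid: one row per
#' trait, columns `Overall` (across-location mean generation-10
#' frequency) and one per location, entries `r` plus significance stars.
#'
#' @param effects data frame from [effects_table()] (mixed stand).
#' @param freqs descendant allele-frequency table.
#' @param fnd FND allele-frequency table.
#' @param generation generation compared with FND (default max).
#' @return list with `grid` (character matrix) and `detail` (long data
#'   frame of r, df, p).
#' @export
dp_effect_grid <- function(effects, freqs, fnd, generation = NULL) {
  fnd <- fnd[fnd$population == "FND", ]
  p_fnd <- stats::setNames(fnd$p, fnd$locus_id)
  obs <- freqs[freqs$population != "FND", ]
  generation <- generation %||% max(obs$generation)
  obs <- obs[obs$generation == generation, ]
  pops <- sort(unique(obs$population))
  # overall = across-location mean of final-generation frequencies
  mean_p <- tapply(obs$p, obs$locus_id, mean)
  dps <- c(list(Overall = stats::setNames(as.numeric(mean_p),
                                          names(mean_p)) -
                  p_fnd[names(mean_p)]),
           stats::setNames(lapply(pops, function(pop) {
             d <- obs[obs$population == pop, ]
             stats::setNames(d$p - p_fnd[d$locus_id], d$locus_id)
           }), pops))
  traits <- unique(effects$trait)
  detail <- list()
  grid <- matrix("", length(traits), length(dps),
                 dimnames = list(traits, names(dps)))
  for (tr in traits) {
    eff <- effects[effects$trait == tr, ]
    ev <- stats::setNames(eff$additive_effect, eff$locus_id)
    ev <- ev[!is.na(ev)]
    for (sc in names(dps)) {
      ct <- correlate_dp_vs_effect(dps[[sc]], ev, tr, sc)
      grid[tr, sc] <- if (is.na(ct$r)) "NA"
        else sprintf("%.2f %s", ct$r, ct$stars)
      detail[[length(detail) + 1]] <-
        data.frame(trait = tr, scope = sc, r = ct$r, L = ct$L, df = ct$df,
                   p_value = ct$p_value, stars = ct$stars,
                   stringsAsFactors = FALSE)
    }
  }
  list(grid = grid, detail = do.call(rbind, detail))
}

#' Grid of correlations between one trait's effects and all others
#'
#' For a reference trait (plant height in the motivating design), the
#' per-locus additive effects are correlated with those of every other
#' trait, separately within the mixed-stand and pure-stand effect sets —
#' the pleiotropy table contrasting individual-plant competition with
#' pure-stand performance.
#'
#' @param effects_mixed,effects_pure data frames from [effects_table()].
#' @param reference_trait trait whose effects form the reference vector.
#' @return list with `grid` (trait x stand character matrix) and `detail`.
#' @export
effect_effect_grid <- function(effects_mixed, effects_pure,
                               reference_trait = "height") {
  sets <- list(mixed = effects_mixed, pure = effects_pure)
  traits <- unique(c(effects_mixed$trait, effects_pure$trait))
  others <- setdiff(traits, reference_trait)
  grid <- matrix("(NA)", length(others), length(sets),
                 dimnames = list(others, names(sets)))
  detail <- list()
  for (st in names(sets)) {
    eff <- sets[[st]]
    ref <- eff[eff$trait == reference_trait, ]
    rv <- stats::setNames(ref$additive_effect, ref$locus_id)
    rv <- rv[!is.na(rv)]
    if (length(rv) < 3) next
    for (tr in others) {
      ot <- eff[eff$trait == tr, ]
      if (!nrow(ot)) next
      ov <- stats::setNames(ot$additive_effect, ot$locus_id)
      ov <- ov[!is.na(ov)]
      if (length(intersect(names(rv), names(ov))) < 3) next
      ct <- correlate_effect_vs_effect(rv, ov, tr, st)
      grid[tr, st] <- if (is.na(ct$r)) "(NA)"
        else sprintf("%.2f %s", ct$r, ct$stars)
      detail[[length(detail) + 1]] <-
        data.frame(trait = tr, stand = st, r = ct$r, L = ct$L, df = ct$df,
                   p_value = ct$p_value, stars = ct$stars,
                   stringsAsFactors = FALSE)
    }
  }
  list(grid = grid,
       detail = if (length(detail)) do.call(rbind, detail) else NULL)
}
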