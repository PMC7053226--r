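# two homozygous parents per locus over a small panel
founder_fixture <- function() {
  panel <- locus_panel(c("L1", "L2"), c("SSR", "SSR"),
                       list(c("100", "102", "104"), c("200", "202")))
  rec <- data.frame(
    individual_id = rep(c("A", "B", "C"), each = 2),
    population = "PARENTS", generation = 0L, location = "",
    locus_id = rep(c("L1", "L2"), 3),
    allele_a = c("100", "200", "102", "202", "104", "200"),
    allele_b = c("100", "200", "102", "202", "104", "200"),
    stringsAsFactors = FALSE)
  genotype_table(rec, panel)
}

test_that("virtual founder counts are proportional to seed counts", {
  parents <- founder_fixture()
  sch <- crossing_scheme(data.frame(
    parent_i = c("A", "A"), parent_j = c("B", "C"),
    seed_count = c(100, 300), stringsAsFactors = FALSE))
  fnd <- build_virtual_fnd(sch, parents, 10000)
  n_ij <- attr(fnd, "n_ij")
  expect_equal(n_ij, c(2500L, 7500L))
  expect_equal(length(unique(fnd$records$individual_id)), 10000)
  expect_true(all(fnd$records$population == "FND"))
  expect_true(all(fnd$records$generation == 0L))
})

test_that("virtual founders are the F1 heterozygotes of each cross", {
  parents <- founder_fixture()
  sch <- crossing_scheme(data.frame(parent_i = "A", parent_j = "B",
                                    seed_count = 10,
                                    stringsAsFactors = FALSE))
  fnd <- build_virtual_fnd(sch, parents, 10000)
  r <- fnd$records
  expect_equal(length(unique(r$individual_id)), 10000)
  l1 <- r[r$locus_id == "L1", ]
  expect_true(all(l1$allele_a == "100" & l1$allele_b == "102"))
  # single cross of distinct homozygotes: p = 0.5 exactly
  cb <- collapse_to_biallelic(fnd, fnd)
  fr <- allele_frequencies(cb)
  expect_equal(fr$p, rep(0.5, 2))
})

test_that("heterozygous parental calls are rejected unless overridden", {
  parents <- founder_fixture()
  parents$records$allele_b[1] <- "102"
  sch <- crossing_scheme(data.frame(parent_i = "A", parent_j = "B",
                                    seed_count = 10,
                                    stringsAsFactors = FALSE))
  expect_error(build_virtual_fnd(sch, parents, 100), "heterozygous")
  fnd <- build_virtual_fnd(sch, parents, 100, het_parents = "first")
  expect_equal(length(unique(fnd$records$individual_id)), 100)
})

test_that("non-parental alleles are removed at the offending locus only", {
  parents <- founder_fixture()
  rec <- data.frame(
    individual_id = rep(c("x1", "x2"), each = 2),
    population = "P", generation = 3L, location = "P",
    locus_id = rep(c("L1", "L2"), 2),
    allele_a = c("100", "200", "999", "202"),
    allele_b = c("102", "200", "100", "202"),
    stringsAsFactors = FALSE)
  gt <- genotype_table(rec, founder_fixture()$panel, extend_labels = TRUE)
  out <- filter_nonparental_alleles(gt, parents)
  expect_equal(sum(out$report$n_removed), 1L)
  expect_equal(out$report$n_removed[out$report$locus_id == "L1"], 1L)
  r <- out$genotypes$records
  expect_false(any(r$individual_id == "x2" & r$locus_id == "L1"))
  expect_true(any(r$individual_id == "x2" & r$locus_id == "L2"))

  # clean dataset passes through unchanged
  clean <- filter_nonparental_alleles(
    genotype_table(rec[c(1, 2, 4), ], founder_fixture()$panel), parents)
  expect_equal(clean$report$n_removed, c(0L, 0L))
  expect_equal(nrow(clean$genotypes$records), 3L)
})

test_that("biallelic collapsing pools non-frequent alleles and logs ties", {
  # FND frequencies A=0.5, B=0.3, C=0.2 at an SSR locus
  panel <- locus_panel("S1", "SSR", list(c("A", "B", "C")))
  mk <- function(a1, a2, n, pop, off = 0)
    data.frame(individual_id = sprintf("%s%03d", pop, off + seq_len(n)),
               population = pop, generation = 0L, location = "",
               locus_id = "S1", allele_a = a1, allele_b = a2,
               stringsAsFactors = FALSE)
  fnd <- genotype_table(rbind(mk("A", "A", 5, "FND"),
                              mk("B", "B", 3, "FND", 5),
                              mk("C", "C", 2, "FND", 8)), panel)
  obs <- genotype_table(rbind(mk("B", "C", 1, "P"), mk("A", "B", 1, "P", 1)),
                        panel)
  out <- collapse_to_biallelic(obs, fnd)
  expect_equal(out$panel$frequent_allele, "A")
  r <- out$records
  expect_equal(unname(unlist(r[r$individual_id == "P001",
                               c("allele_a", "allele_b")])),
               c("OTHER", "OTHER"))
  expect_equal(unname(unlist(r[r$individual_id == "P002",
                               c("allele_a", "allele_b")])),
               c("A", "OTHER"))

  # tie resolved lexicographically and logged
  fnd_tie <- genotype_table(rbind(mk("B", "B", 5, "FND"),
                                  mk("A", "A", 5, "FND", 5)), panel)
  out_tie <- collapse_to_biallelic(obs, fnd_tie)
  map <- attr(out_tie, "recode_map")
  expect_equal(map$frequent_allele, "A")
  expect_true(map$tie)
})

test_that("collapsing commutes with frequency computation", {
  panel <- locus_panel("S1", "SSR", list(c("A", "B", "C")))
  set.seed(11)
  n <- 40
  rec <- data.frame(
    individual_id = sprintf("i%03d", 1:n), population = "FND",
    generation = 0L, location = "",
    locus_id = "S1",
    allele_a = sample(c("A", "B", "C"), n, TRUE, prob = c(.5, .3, .2)),
    allele_b = sample(c("A", "B", "C"), n, TRUE, prob = c(.5, .3, .2)),
    stringsAsFactors = FALSE)
  gt <- genotype_table(rec, panel)
  cb <- collapse_to_biallelic(gt, gt)
  map <- attr(cb, "recode_map")
  freq_before <- mean(c(rec$allele_a, rec$allele_b) == map$frequent_allele)
  fr <- allele_frequencies(cb)
  expect_equal(fr$p, freq_before)
  # the frequent allele's FND frequency is maximal by construction
  tab <- table(c(rec$allele_a, rec$allele_b))
  expect_equal(max(tab) / sum(tab), map$p_fnd)
})

test_that("gene counting: 4 het + 6 other-homozygous gives p = 0.2", {
  gt <- counts_table(list(P1 = c(0, 4, 6)))
  fr <- allele_frequencies(gt)
  expect_equal(fr$p, 0.2)
  expect_equal(fr$n_obs, 20L)

  all_freq <- counts_table(list(P1 = c(10, 0, 0)))
  expect_equal(allele_frequencies(all_freq)$p, 1.0)
})
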