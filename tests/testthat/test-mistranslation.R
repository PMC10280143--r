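test_that("rate table validation enforces the probability contract", {
  expect_error(mistranslation_table(
    data.frame(codon = "GCT", amino_acid = "A", rate = 1e-3)),
    "cognate")
  expect_error(mistranslation_table(
    data.frame(codon = "TAA", amino_acid = "A", rate = 1e-3)),
    "stop")
  expect_error(mistranslation_table(
    data.frame(codon = "GCT", amino_acid = "D", rate = 1.2)),
    "\\[0, 1\\)")
  tab <- mistranslation_table(
    data.frame(codon = "GCT", amino_acid = "D", rate = 1e-3))
  expect_equal(unname(tab$cognate_prob[["GCT"]]), 1 - 1e-3)
  expect_equal(unname(tab$cognate_prob[["GCC"]]), 1)
  expect_equal(unname(rowSums(tab$prob)), rep(1, 61))
})

test_that("rate table TSV round trip preserves rates", {
  tab <- generate_rate_table(seed = 3L)
  path <- tempfile(fileext = ".tsv")
  write_rate_table(tab, path)
  back <- read_rate_table(path)
  expect_identical(back$prob, tab$prob)
})

test_that("variant distribution matches the hand-computed two-codon example", {
  # codon 1 errs to exactly one amino acid at 1e-3, codon 2 at 1e-4
  tab <- mistranslation_table(data.frame(
    codon = c("GCT", "GAT"), amino_acid = c("D", "E"),
    rate = c(1e-3, 1e-4)))
  g <- "GCTGAT"  # encodes AD
  d <- variant_distribution(g, tab, prune_threshold = 1e-9)
  expect_setequal(d$peptide, c("AD", "DD", "AE", "DE"))
  q <- setNames(d$prob, d$peptide)
  unpruned <- c(AD = 0.999 * 0.9999, DD = 1e-3 * 0.9999,
                AE = 0.999 * 1e-4, DE = 1e-3 * 1e-4)
  expect_equal(q[names(unpruned)], unpruned / sum(unpruned))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  # raising the threshold prunes the double variant and renormalizes
  d2 <- variant_distribution(g, tab, prune_threshold = 1e-6)
  expect_setequal(d2$peptide, c("AD", "DD", "AE"))
  expect_equal(sum(d2$prob), 1, tolerance = 1e-12)
  o2 <- brute_variant_distribution(g, tab, prune_threshold = 1e-6)
  expect_equal(setNames(d2$prob, d2$peptide)[o2$peptide],
               setNames(o2$prob, o2$peptide))
})

test_that("branch-and-bound enumeration equals brute force, pruned and unpruned", {
  fx <- get_fixture("enumerable-L2")
  set.seed(5)
  genos <- sample_sense_genotypes(genotype_fitness_view(fx$landscape), 5,
                                  seed = 5)
  for (g in genos) {
    for (thr in c(1e-9, 1e-6)) {
      d <- variant_distribution(g, fx$table, prune_threshold = thr)
      o <- brute_variant_distribution(g, fx$table, prune_threshold = thr)
      expect_setequal(d$peptide, o$peptide)
      expect_equal(setNames(d$prob, d$peptide)[o$peptide],
                   setNames(o$prob, o$peptide), tolerance = 1e-12)
    }
  }
  # an L = 3 genotype under a heterogeneous generated table
  tab3 <- generate_rate_table(log10_rate_mean = -2.5, seed = 9L)
  g3 <- "GCTGATAAA"
  d3 <- variant_distribution(g3, tab3, prune_threshold = 1e-9)
  o3 <- brute_variant_distribution(g3, tab3, prune_threshold = 1e-9)
  expect_setequal(d3$peptide, o3$peptide)
  expect_equal(setNames(d3$prob, d3$peptide)[o3$peptide],
               setNames(o3$prob, o3$peptide), tolerance = 1e-12)
})

test_that("all error rates zero collapses the distribution to the encoded peptide", {
  d <- variant_distribution("GCTGAT", zero_rate_table())
  expect_equal(d$peptide, "AD")
  expect_equal(d$prob, 1)
  expect_error(variant_distribution("TAAGAT", zero_rate_table()), "stop")
})

test_that("fitness moments follow the multinomial mean-of-n model", {
  fx <- get_fixture("flat")
  view <- genotype_fitness_view(fx$landscape)
  # single variant: variance 0
  d1 <- variant_distribution("GCTGAT", zero_rate_table())
  m1 <- fitness_moments(d1, view, n = 1)
  expect_equal(m1$mean, 1)
  expect_equal(m1$variance, 0)
  # two-variant hand case q = (0.9, 0.1), f = (1, 0)
  d2 <- structure(list(peptide = c("AD", "AA"), prob = c(0.9, 0.1),
                       encoded = "AD", prune_threshold = 1e-9),
                  class = "variant_distribution")
  f2 <- peptide_landscape(setNames(
    ifelse(enumerate_peptides(2) == "AA", 0, 1), enumerate_peptides(2)))
  v2 <- genotype_fitness_view(f2)
  mA <- fitness_moments(d2, v2, n = 1)
  expect_equal(mA$mean, 0.9)
  expect_equal(mA$variance, 0.09)
  mB <- fitness_moments(d2, v2, n = 10)
  expect_equal(mB$mean, 0.9)
  expect_equal(mB$variance, 0.009)
  # Monte Carlo multinomial oracle agreement (3 standard errors)
  mc <- mc_fitness_moments(d2, v2, n = 10, draws = 2e5, seed = 2)
  expect_lt(abs(mc$mean - mB$mean), 3 * mc$se_mean)
  expect_lt(abs(mc$variance - mB$variance), 3 * mc$variance * sqrt(2 / 2e5) * 10)
})

test_that("E(f) is n-independent and Var(f) scales exactly as 1/n", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  genos <- sample_sense_genotypes(view, 5, seed = 8)
  for (g in genos) {
    d <- variant_distribution(g, fx$table)
    m1 <- fitness_moments(d, view, n = 1)
    m500 <- fitness_moments(d, view, n = 500)
    expect_identical(m1$mean, m500$mean)
    expect_equal(m1$variance, 500 * m500$variance)
  }
})

test_that("per-protein mistranslation rate equals 1 - encoded-variant probability", {
  tab <- mistranslation_table(data.frame(
    codon = c("GCT", "GAT"), amino_acid = c("D", "E"),
    rate = c(1e-3, 1e-4)))
  g <- "GCTGAT"
  expect_equal(genotype_mistranslation_rate(g, tab), 1 - 0.999 * 0.9999)
  o <- brute_variant_distribution(g, tab)
  expect_equal(genotype_mistranslation_rate(g, tab),
               1 - o$prob[o$peptide == "AD"])
  expect_equal(genotype_mistranslation_rate(g, zero_rate_table()), 0)
  # monotone in any single error rate
  tab_hi <- mistranslation_table(data.frame(
    codon = c("GCT", "GAT"), amino_acid = c("D", "E"),
    rate = c(2e-3, 1e-4)))
  expect_gt(genotype_mistranslation_rate(g, tab_hi),
            genotype_mistranslation_rate(g, tab))
})

test_that("moments cache is transparent", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  cache <- new.env(parent = emptyenv())
  g <- sample_sense_genotypes(view, 1, seed = 3)
  a <- cached_moments(g, view, fx$table, 1L, cache)
  b <- cached_moments(g, view, fx$table, 1L, cache)
  direct <- genotype_moments(g, view, fx$table, 1L)
  expect_identical(a, direct)
  expect_identical(a, b)
})
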