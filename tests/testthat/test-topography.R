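test_that("flattening regression recovers exact linear relations", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  genos <- sample_sense_genotypes(view, 100, seed = 14)
  genos <- genos[encoded_fitness(view, genos) > 0]
  # all-zero table: identity, every delta 0
  ff0 <- flattening_fit(genos, view, zero_rate_table())
  expect_equal(ff0$slope, 1)
  expect_equal(ff0$r, 1)
  expect_equal(ff0$delta, rep(0, length(genos)))
  expect_error(flattening_fit(genos[1:2], view, fx$table), "at least 3")
  expect_error(flattening_fit(rep(genos[1], 5), view, fx$table),
               "degenerate")
})

test_that("neighborhood fitness means are exact on hand-enumerable cases", {
  fx <- get_fixture("flat")
  view <- genotype_fitness_view(fx$landscape)
  nm <- neighbor_fitness_means("GCTGAT", view)
  expect_equal(nm[["phenotypic"]], 1)  # all peptide neighbors have fitness 1
  # genotypic mean lowered only by stop-creating neighbors
  nb <- single_nucleotide_neighbors("GCTGAT")
  frac_sense <- mean(translate(nb) != inviable_marker())
  expect_equal(nm[["genotypic"]], frac_sense)
  # L = 1 toy, fully hand-computable
  peptides <- enumerate_peptides(1, c("A", "D", "E"))
  ls <- peptide_landscape(setNames(c(0.2, 0.5, 0.9), peptides),
                          missing_policy = "zero")
  v1 <- genotype_fitness_view(ls)
  nm1 <- neighbor_fitness_means("GCT", v1)
  ph <- phenotypic_neighbors("A")
  expect_equal(nm1[["phenotypic"]],
               mean(peptide_fitness(ls, ph)))
  gt <- single_nucleotide_neighbors("GCT")
  expect_equal(nm1[["genotypic"]], mean(encoded_fitness(v1, gt)))
})

test_that("mutation-effect census is diagonal without errors and conserves rows", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  params <- population_params(1e6, 1L)
  pairs <- sample_mutation_pairs(view, 60, seed = 6)
  cz <- classify_mutation_sample(view, zero_rate_table(), pairs, params)
  expect_equal(sum(diag(cz$census)), nrow(pairs))
  expect_equal(sum(cz$census), nrow(pairs))
  cm <- classify_mutation_sample(view, fx$table, pairs, params)
  expect_equal(unname(rowSums(cm$census)),
               unname(as.vector(table(factor(cm$pairs$class_none,
                 c("beneficial", "nearly_neutral", "deleterious"))))))
  expect_equal(sum(cm$census), nrow(pairs))
})

test_that("a dominant deleterious variant can reverse a beneficial mutation", {
  # L = 1 over {A, D}: A -> D is beneficial on encoded fitness, but the
  # mutant codon GAT misreads to E (fitness 0) so often that its expected
  # fitness drops below the wild type's.
  peptides <- enumerate_peptides(1, c("A", "D", "E"))
  ls <- peptide_landscape(setNames(c(0.50, 0.55, 0), peptides),
                          missing_policy = "zero")
  view <- genotype_fitness_view(ls)
  tab <- mistranslation_table(data.frame(
    codon = "GAT", amino_acid = "E", rate = 0.2))
  params <- population_params(1e6, 1L)
  e0 <- mutation_effect(view, NULL, "GCT", "GAT", params)
  e1 <- mutation_effect(view, tab, "GCT", "GAT", params)
  expect_equal(e0$effect_class, "beneficial")
  expect_equal(e1$effect_class, "deleterious")
  cz <- classify_mutation_sample(view, tab,
                                 data.frame(wt = "GCT", mt = "GAT"), params)
  expect_equal(unname(cz$census["beneficial", "deleterious"]), 1L)
})

test_that("neutral networks connect synonymous classes and flag peaks correctly", {
  fx <- get_fixture("two-peak")
  view <- genotype_fitness_view(fx$landscape)
  params <- population_params(1e6, 1L)
  gts <- enumerate_sense_genotypes(2, codons = fx$codons)
  nets <- neutral_networks(gts, view, NULL, params)
  # without mistranslation every synonymous codon class is connected:
  # components correspond to peptides
  mem_pep <- lapply(nets, function(nw) unique(translate(nw$members)))
  expect_true(all(lengths(mem_pep) == 1))
  expect_equal(length(nets), 4)  # AA, AD, DA, DD
  peaks <- unlist(mem_pep)[vapply(nets, `[[`, logical(1), "is_peak")]
  expect_setequal(peaks, c("AA", "DD"))
})

test_that("peak counting matches the brute-force oracle with and without errors", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  params <- population_params(1e6, 1L)
  gts <- enumerate_sense_genotypes(2, codons = fx$codons)
  for (tab in list(NULL, fx$table)) {
    res <- count_peaks_topk(view, tab, K = length(gts), params,
                            genotypes = gts)
    expect_equal(res$n_peaks, brute_count_peaks(gts, view, tab, params))
  }
  # K = universe equals global peak count. A smooth additive landscape
  # over {A, D} has exactly one genotype-level peak: A and D are single
  # nucleotide changes apart (GCT <-> GAT), so every suboptimal
  # synonymous network has an improving one-step neighbor. (Larger
  # alphabets genuinely add codon-level local peaks: some amino-acid
  # replacements need two nucleotide changes.)
  site_value <- c(A = 0.2, D = 0.5)
  peps <- enumerate_peptides(2, c("A", "D"))
  fvals <- site_value[substr(peps, 1, 1)] + site_value[substr(peps, 2, 2)]
  smooth <- peptide_landscape(setNames(unname(fvals), peps),
                              missing_policy = "zero")
  vs <- genotype_fitness_view(smooth)
  cs <- sense_codons()[standard_genetic_code()[sense_codons()] %in%
                         c("A", "D")]
  g2 <- enumerate_sense_genotypes(2, codons = cs)
  res2 <- count_peaks_topk(vs, NULL, K = length(g2), params,
                           genotypes = g2)
  expect_equal(res2$n_peaks, 1)
})

test_that("epistasis classification follows the square definitions", {
  N <- 1e6
  # exactly additive corners
  expect_equal(classify_epistasis(0.2, 0.5, 0.4, 0.7, N, N, N), "additive")
  # both mutations beneficial alone, deleterious together
  expect_equal(classify_epistasis(0.2, 0.5, 0.5, 0.1, N, N, N),
               "reciprocal_sign")
  # magnitude: classes preserved, interaction nonzero
  expect_equal(classify_epistasis(0.2, 0.4, 0.4, 0.9, N, N, N), "magnitude")
  # simple sign: exactly one mutation flips
  expect_equal(classify_epistasis(0.2, 0.5, 0.3, 0.4, N, N, N),
               "simple_sign")
  # invariance under swapping the two mutations (g10 <-> g01)
  set.seed(31)
  for (i in 1:50) {
    f <- runif(4, 0.01, 1)
    expect_equal(classify_epistasis(f[1], f[2], f[3], f[4], N, N, N),
                 classify_epistasis(f[1], f[3], f[2], f[4], N, N, N))
  }
})

test_that("sampled epistasis fractions partition the sample", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  params <- population_params(1e6, 1L)
  ep <- sample_epistasis_squares(view, fx$table, 50, params, seed = 3)
  expect_equal(sum(ep$fractions), 1)
  expect_equal(nrow(ep$squares), 50)
  expect_true(all(ep$squares$class %in% names(ep$fractions)))
  # squares are closed: g11 differs from g00 at exactly two positions
  d <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    ep$squares$g00, ep$squares$g11)
  expect_true(all(d == 2))
})
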