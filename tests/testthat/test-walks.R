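test_that("start genotypes come from the bottom viable quantile", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  f <- as.numeric(fx$landscape)
  cutoff <- quantile(f[f > 0], 0.10, names = FALSE)
  starts <- sample_start_genotypes(view, quantile = 0.10, count = 200,
                                   seed = 9)
  sf <- encoded_fitness(view, starts)
  expect_true(all(sf > 0))
  expect_true(all(sf <= cutoff))
  # quantile 1: any viable genotype, never an inviable one
  starts_all <- sample_start_genotypes(view, quantile = 1, count = 500,
                                       seed = 10)
  expect_true(all(encoded_fitness(view, starts_all) > 0))
  # determinism
  expect_identical(starts,
                   sample_start_genotypes(view, quantile = 0.10,
                                          count = 200, seed = 9))
})

test_that("walks are reproducible and respect synonymous neutrality", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  cfg <- walk_config(population_params(1e4), table = NULL,
                     total_attempts = 500L, replicates = 4L, seed = 21L)
  r1 <- run_walks(view, cfg)
  r2 <- run_walks(view, cfg)
  expect_identical(lapply(r1, `[[`, "events"), lapply(r2, `[[`, "events"))
  # without mistranslation no synonymous fixation carries |s| > 0
  for (r in r1) {
    if (any(r$events$synonymous)) {
      expect_true(all(r$events$s[r$events$synonymous] == 0))
    }
    expect_equal(r$n_syn_fixed + r$n_nonsyn_fixed, nrow(r$events))
    if (nrow(r$events) > 1) {
      expect_true(all(diff(r$events$attempt) > 0))
      expect_identical(r$events$from[-1],
                       r$events$to[-nrow(r$events)])
    }
  }
})

test_that("an all-zero rate table reproduces table-free walks event for event", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  p <- population_params(1e4)
  cfg0 <- walk_config(p, table = NULL, total_attempts = 400L,
                      replicates = 3L, seed = 33L)
  cfg1 <- walk_config(p, table = zero_rate_table(), total_attempts = 400L,
                      replicates = 3L, seed = 33L)
  r0 <- run_walks(view, cfg0)
  r1 <- run_walks(view, cfg1)
  drop_rate <- function(r) lapply(r, function(x)
    x$events[setdiff(names(x$events), "mistrans_rate_after")])
  expect_identical(drop_rate(r0), drop_rate(r1))
  expect_identical(vapply(r0, `[[`, numeric(1), "final_fitness"),
                   vapply(r1, `[[`, numeric(1), "final_fitness"))
})

test_that("neutral fixation rate on the flat fixture matches the closed form", {
  fx <- get_fixture("flat")
  view <- genotype_fitness_view(fx$landscape)
  N <- 50
  cfg <- walk_config(population_params(N), table = NULL,
                     total_attempts = 400L, replicates = 150L,
                     start_quantile = 1, seed = 17L)
  recs <- run_walks(view, cfg)
  counts <- vapply(recs, function(r) nrow(r$events), numeric(1))
  # expected per-attempt fixation probability: only sense proposals are
  # neutral (u = 1/N); stop-creating proposals are lethal. The time
  # average of the sense-neighbor fraction over the neutral walk is the
  # plain mean over sense genotypes.
  set.seed(1)
  gsamp <- sample_sense_genotypes(view, 300, seed = 2)
  qbar <- mean(vapply(gsamp, function(g) {
    mean(translate(single_nucleotide_neighbors(g)) != inviable_marker())
  }, numeric(1)))
  p <- qbar / N
  mu <- cfg$total_attempts * p
  se <- sqrt(cfg$total_attempts * p * (1 - p) / cfg$replicates)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("post hoc rates recompute per-resident rates and normalize to 100%", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  cfg <- walk_config(population_params(1e4), table = NULL,
                     total_attempts = 300L, replicates = 1L, seed = 5L)
  rec <- run_walks(view, cfg)[[1]]
  ph <- posthoc_rates(rec, fx$table, view, reference_sample = 200L)
  residents <- c(rec$start, rec$events$to)
  ref <- mean_mistranslation_rate(view, fx$table, sample_size = 200L,
                                  seed = 1L)
  direct <- vapply(residents, genotype_mistranslation_rate, numeric(1),
                   table = fx$table, USE.NAMES = FALSE)
  expect_equal(ph$rate_pct, 100 * direct / ref)
  expect_equal(ph$attempt, c(0L, rec$events$attempt))
  # uniform table: every genotype sits exactly at 100%
  uni <- uniform_rate_table(1e-4)
  ph_u <- posthoc_rates(rec, uni, view, reference_sample = 50L)
  expect_equal(ph_u$rate_pct, rep(100, length(residents)))
})

test_that("beneficial supply matches exhaustive enumeration on an L = 1 toy", {
  peptides <- enumerate_peptides(1, c("A", "D", "E"))
  ls <- peptide_landscape(setNames(c(0.2, 0.5, 0.9), peptides),
                          missing_policy = "zero")
  view <- genotype_fitness_view(ls)
  params <- population_params(1e6)
  g <- "GCT"  # encodes A, fitness 0.2
  nb <- single_nucleotide_neighbors(g)
  expected <- 0L
  for (m in nb) {
    pep <- translate(m)
    if (pep == inviable_marker()) next
    if (pep == "A") next  # synonymous
    fmt <- peptide_fitness(ls, pep)
    s <- fmt / 0.2 - 1
    if (s > 0 && abs(s) >= 1 / (4 * params$N)) expected <- expected + 1L
  }
  expect_equal(beneficial_supply(view, NULL, g, params), expected)
  expect_lte(beneficial_supply(view, NULL, g, params), 9)
  # a global-peak genotype has no beneficial neighbors
  gpk <- "GAA"  # encodes E, fitness 0.9
  expect_equal(beneficial_supply(view, NULL, gpk, params), 0)
})

test_that("walk summaries attribute fitness change exactly and rank-correlate", {
  fx <- get_fixture("enumerable-L2")
  view <- genotype_fitness_view(fx$landscape)
  cfg <- walk_config(population_params(1e6), table = fx$table,
                     total_attempts = 800L, replicates = 4L, seed = 12L)
  recs <- run_walks(view, cfg)
  s <- summarize_walks(recs, view, table = fx$table)
  # telescoping: syn + nonsyn attribution equals final - initial fitness
  total_gain <- mean(vapply(recs, function(r)
    r$final_fitness - r$start_fitness, numeric(1)))
  expect_equal(s$syn_fitness_gain[["mean"]] + s$nonsyn_fitness_gain[["mean"]],
               total_gain, tolerance = 1e-12)
  expect_equal(s$fixations[["mean"]],
               s$syn_fixations[["mean"]] + s$nonsyn_fixations[["mean"]])
  # hand-built record with perfectly anticorrelated (s, rate change)
  fake_events <- data.frame(
    attempt = 1:4, from = rep("x", 4), to = rep("y", 4),
    s = c(0.1, 0.2, 0.3, 0.4), synonymous = FALSE,
    fitness_after = c(0.2, 0.3, 0.4, 0.5),
    mistrans_rate_after = c(0.4, 0.35, 0.25, 0.1))
  fake <- structure(list(start = "x", start_fitness = 0.1,
                         events = fake_events, final = "y",
                         final_fitness = 0.5,
                         final_fitness_fraction = 0.5,
                         n_syn_fixed = 0, n_nonsyn_fixed = 4),
                    class = "walk_record")
  s2 <- summarize_walks(list(fake), view)
  expect_equal(s2$effect_rate_change_tau, -1)
  expect_error(summarize_walks(list(), view), "no walk records")
})
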