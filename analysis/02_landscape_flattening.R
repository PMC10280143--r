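#!/usr/bin/env Rscript
# Stage 2: how mistranslation reshapes genotype-level fitness.
#
# On a random genotype sample: (i) regression of expected fitness with
# mistranslation on encoded fitness (flattening; slope < 1 means high
# fitness genotypes lose and low fitness genotypes gain), (ii) the
# correlation between a genotype's phenotypic (amino-acid) and genotypic
# (nucleotide) neighborhood mean fitness, (iii) the reduction in
# effective population size across protein expression levels 1..1000.

suppressPackageStartupMessages(library(mistrans))

seed <- 20260922L
data_dir <- file.path("results", "data")
out_dir <- file.path("results", "flattening")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ls2 <- read_landscape(file.path(data_dir, "landscape.tsv"),
                      missing_policy = "zero")
tab <- read_rate_table(file.path(data_dir, "rates.tsv"))
view <- genotype_fitness_view(ls2)
N <- 1e6
n_sample <- 1000L

genos <- sample_sense_genotypes(view, 3L * n_sample, seed = seed + 10L)
genos <- unique(genos[encoded_fitness(view, genos) > 0])[seq_len(n_sample)]
cache <- new.env(parent = emptyenv())

ff <- flattening_fit(genos, view, tab, population_params(N, 1L),
                     cache = cache)
cat(sprintf("flattening slope m = %.4f (Pearson r = %.4f)\n",
            ff$slope, ff$r))

nm <- t(vapply(genos, neighbor_fitness_means, numeric(2), view = view))
tau <- cor(nm[, "phenotypic"], nm[, "genotypic"], method = "kendall")
cat(sprintf("phenotypic vs genotypic neighborhood fitness: Kendall tau = %.3f\n",
            tau))

expression_levels <- c(1L, 10L, 100L, 1000L)
ne_tab <- do.call(rbind, lapply(expression_levels, function(n) {
  ne <- vapply(genos, function(g) {
    m <- genotype_moments(g, view, tab, n)
    effective_population_size(N, m$mean, m$variance)
  }, numeric(1))
  data.frame(expression_n = n, median_Ne = median(ne), mean_Ne = mean(ne),
             sd_Ne = sd(ne), mean_reduction_pct = 100 * (1 - mean(ne) / N))
}))
cat("Ne reduction by expression level (N = 1e6):\n")
print(ne_tab, row.names = FALSE)

per_geno <- data.frame(genotype = genos,
                       encoded_fitness = encoded_fitness(view, genos),
                       expected_fitness_mis = ff$delta +
                         encoded_fitness(view, genos),
                       delta = ff$delta)
utils::write.table(per_geno, file.path(out_dir, "per_genotype.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ne_tab, file.path(out_dir, "ne_by_expression.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_run_summary(list(
  config = list(seed = seed, N = N, n_sample = n_sample,
                expression_levels = expression_levels),
  flattening = list(slope = ff$slope, intercept = ff$intercept, r = ff$r),
  neighbor_fitness_kendall_tau = tau
), file.path(out_dir, "summary.json"))
cat("wrote", out_dir, "\n")
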