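#!/usr/bin/env Rscript
# Stage 4: landscape ruggedness with and without mistranslation.
#
# Two complementary measures over the same landscape: (i) the number of
# fitness peaks (nearly-neutral networks whose outside neighbors are all
# deleterious) among the top-500 genotypes by expected fitness, at a
# large population size and both expression levels; (ii) the fractions
# of sampled genotype squares showing magnitude, simple sign and
# reciprocal sign epistasis.

suppressPackageStartupMessages(library(mistrans))

seed <- 20260922L
data_dir <- file.path("results", "data")
out_dir <- file.path("results", "ruggedness")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ls2 <- read_landscape(file.path(data_dir, "landscape.tsv"),
                      missing_policy = "zero")
tab <- read_rate_table(file.path(data_dir, "rates.tsv"))
view <- genotype_fitness_view(ls2)
N <- 1e8
K <- 500L
gts <- enumerate_sense_genotypes(2)

conditions <- list(
  none = list(table = NULL, n = 1L),
  mis_high_expression = list(table = tab, n = 500L),
  mis_low_expression = list(table = tab, n = 1L)
)
peak_tab <- do.call(rbind, lapply(names(conditions), function(nm) {
  cd <- conditions[[nm]]
  res <- count_peaks_topk(view, cd$table, K, population_params(N, cd$n),
                          genotypes = gts)
  data.frame(condition = nm, expression_n = cd$n, K = K,
             n_peaks = res$n_peaks)
}))
cat("fitness peaks among the top-500 genotypes (N = 1e8):\n")
print(peak_tab, row.names = FALSE)

n_squares <- 500L
epi_tab <- do.call(rbind, lapply(names(conditions), function(nm) {
  cd <- conditions[[nm]]
  ep <- sample_epistasis_squares(view, cd$table, n_squares,
                                 population_params(N, cd$n),
                                 seed = seed + 40L)
  cbind(data.frame(condition = nm, expression_n = cd$n),
        as.data.frame(as.list(100 * ep$fractions)))
}))
cat("epistasis class percentages over", n_squares, "squares:\n")
print(epi_tab, row.names = FALSE)

utils::write.table(peak_tab, file.path(out_dir, "peaks.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(epi_tab, file.path(out_dir, "epistasis.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_run_summary(list(
  config = list(seed = seed, N = N, K = K, n_squares = n_squares),
  peaks = peak_tab, epistasis = epi_tab
), file.path(out_dir, "summary.json"))
cat("wrote", out_dir, "\n")
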