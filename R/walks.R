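#' Configuration for adaptive walks
#'
#' @param params a `population_params` (census size N and proteins per
#'   cell n).
#' @param table a `mistranslation_table` to run walks with
#'   mistranslation, or `NULL` for walks without.
#' @param total_attempts mutations proposed per walk (fixed and lost
#'   both count; the attempt index is the proxy for evolutionary time).
#' @param replicates number of independent walks.
#' @param start_quantile walks start from viable genotypes in this bottom
#'   quantile of the viable fitness distribution (default bottom 10%).
#' @param seed root RNG seed; replicate r uses `seed + r`, so any
#'   replicate is reproducible in isolation.
#' @return List of class `walk_config`.
#' @export
walk_config <- function(params, table = NULL, total_attempts = 1e5L,
                        replicates = 1e4L, start_quantile = 0.10,
                        seed = 1L) {
  stopifnot(inherits(params, "population_params"),
            total_attempts >= 1, replicates >= 1,
            start_quantile > 0, start_quantile <= 1)
  structure(list(params = params, table = table,
                 total_attempts = as.integer(total_attempts),
                 replicates = as.integer(replicates),
                 start_quantile = start_quantile,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Sample starting genotypes for adaptive walks
#'
#' Draws peptides uniformly (with replacement) from the viable peptides
#' whose fitness is positive and at or below the `quantile` cutoff of the
#' viable fitness distribution, then picks a synonymous nucleotide
#' encoding uniformly at random for each.
#'
#' @param view a `genotype_fitness_view`.
#' @param quantile bottom quantile of the viable fitness distribution.
#' @param count number of genotypes to sample.
#' @param seed RNG seed.
#' @return Character vector of `count` genotypes.
#' @export
sample_start_genotypes <- function(view, quantile = 0.10, count = 1L,
                                   seed = 1L) {
  f <- as.numeric(view$landscape)
  peptides <- names(view$landscape)
  viable <- f > 0
  if (!any(viable)) stop("landscape has no viable peptides")
  cutoff <- stats::quantile(f[viable], probs = quantile, names = FALSE)
  eligible <- peptides[viable & f <= cutoff]
  if (length(eligible) == 0L) stop("no viable peptides below the quantile cutoff")
  set.seed(seed)
  pep <- eligible[sample.int(length(eligible), count, replace = TRUE)]
  vapply(pep, reverse_translate, character(1), code = view$code,
         random = TRUE, USE.NAMES = FALSE)
}

# Per-resident proposal table: neighbors, their fixation probabilities and
# bookkeeping quantities. Computing this once per resident makes each
# attempt O(1): proposals are i.i.d. uniform over the same 9L neighbors
# until a fixation replaces the resident.
.resident_block <- function(resident, view, table, params, cache) {
  res_m <- cached_moments(resident, view, table, params$n, cache)
  if (res_m$mean <= 0) {
    stop("walk resident has zero expected fitness: ", resident)
  }
  Ne <- effective_population_size(params$N, res_m$mean, res_m$variance)
  nb <- single_nucleotide_neighbors(resident)
  k <- length(nb)
  u <- numeric(k); s <- numeric(k); mt_mean <- numeric(k)
  for (j in seq_len(k)) {
    m <- cached_moments(nb[j], view, table, params$n, cache)
    mt_mean[j] <- m$mean
    s[j] <- m$mean / res_m$mean - 1
    u[j] <- fixation_probability(Ne, s[j], params$N)
  }
  list(resident = resident, mean = res_m$mean, neighbors = nb,
       s = s, u = u, mt_mean = mt_mean)
}

#' Run one adaptive walk
#'
#' Origin-fixation dynamics in the weak mutation-strong selection regime:
#' at each attempt one of the resident's 9L single-nucleotide neighbors is
#' proposed uniformly at random (stop-creating mutations included; they
#' are lethal and essentially never fix) and fixes with its Kimura
#' fixation probability (one Bernoulli draw). On fixation the mutant
#' becomes the resident. The RNG stream is whatever is current; callers
#' wanting reproducibility seed before calling (as [run_walks()] does).
#'
#' @param start starting genotype (must be viable).
#' @param view a `genotype_fitness_view`.
#' @param config a `walk_config`.
#' @param cache moments cache environment shared across walks of the same
#'   condition; created fresh if `NULL`.
#' @return List of class `walk_record`: `start`, `events` (data frame
#'   with columns attempt, from, to, s, synonymous, fitness_after,
#'   mistrans_rate_after), `final`, `final_fitness`,
#'   `final_fitness_fraction`, `n_syn_fixed`, `n_nonsyn_fixed`.
#' @export
run_walk <- function(start, view, config, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  params <- config$params
  table <- config$table
  blk <- .resident_block(start, view, table, params, cache)
  start_fitness <- blk$mean
  k <- length(blk$neighbors)
  ev_attempt <- integer(0); ev_from <- character(0); ev_to <- character(0)
  ev_s <- numeric(0); ev_syn <- logical(0); ev_fit <- numeric(0)
  ev_rate <- numeric(0)
  for (attempt in seq_len(config$total_attempts)) {
    j <- sample.int(k, 1L)
    if (stats::runif(1) < blk$u[j]) {
      to <- blk$neighbors[j]
      ev_attempt <- c(ev_attempt, attempt)
      ev_from <- c(ev_from, blk$resident)
      ev_to <- c(ev_to, to)
      ev_s <- c(ev_s, blk$s[j])
      ev_syn <- c(ev_syn, is_synonymous(blk$resident, to, view$code))
      ev_fit <- c(ev_fit, blk$mt_mean[j])
      ev_rate <- c(ev_rate,
                   if (is.null(table)) NA_real_
                   else genotype_mistranslation_rate(to, table))
      if (blk$mt_mean[j] <= 0) {
        stop("fixed mutant has zero expected fitness; walk aborted")
      }
      blk <- .resident_block(to, view, table, params, cache)
    }
  }
  events <- data.frame(attempt = ev_attempt, from = ev_from, to = ev_to,
                       s = ev_s, synonymous = ev_syn,
                       fitness_after = ev_fit,
                       mistrans_rate_after = ev_rate,
                       stringsAsFactors = FALSE)
  final <- blk$resident
  structure(list(start = start, start_fitness = start_fitness,
                 events = events, final = final,
                 final_fitness = blk$mean,
                 final_fitness_fraction =
                   blk$mean / attr(view$landscape, "max_fitness"),
                 n_syn_fixed = sum(ev_syn),
                 n_nonsyn_fixed = sum(!ev_syn)),
            class = "walk_record")
}

#' Run replicate adaptive walks
#'
#' Starting genotypes are sampled from the bottom `start_quantile` of the
#' viable fitness distribution (seeded by `config$seed`); replicate r then
#' runs under seed `config$seed + r`. Pass the same `config` except for
#' `table` to compare conditions with paired seeds, in which case the
#' starting genotypes (and all proposal draws, until the first divergence
#' in fixation outcomes) are identical across conditions.
#'
#' @param view a `genotype_fitness_view`.
#' @param config a `walk_config`.
#' @param starts optional explicit starting genotypes (recycled to
#'   `config$replicates`); default samples them via
#'   [sample_start_genotypes()].
#' @return List of `walk_record`s, one per replicate.
#' @export
run_walks <- function(view, config, starts = NULL) {
  if (is.null(starts)) {
    starts <- sample_start_genotypes(view, config$start_quantile,
                                     config$replicates, seed = config$seed)
  }
  starts <- rep_len(starts, config$replicates)
  cache <- new.env(parent = emptyenv())
  lapply(seq_len(config$replicates), function(r) {
    set.seed(config$seed + r)
    run_walk(starts[r], view, config, cache = cache)
  })
}

#' Post hoc mistranslation rates along a walk
#'
#' For a walk simulated *without* mistranslation, the mistranslation rate
#' each resident genotype would have had under `table`. Rates are
#' reported as percent of a reference mean rate (100 = the landscape-mean
#' mistranslation rate), estimated from `reference_sample` random sense
#' genotypes unless `reference_rate` is given.
#'
#' @param record a `walk_record` produced without mistranslation.
#' @param table a `mistranslation_table`.
#' @param view a `genotype_fitness_view` (supplies L and the code for the
#'   reference sample).
#' @param reference_rate optional precomputed landscape-mean rate.
#' @param reference_sample number of random genotypes for the reference
#'   mean.
#' @param seed RNG seed for the reference sample.
#' @return Data frame with columns `attempt` (0 for the start) and
#'   `rate_pct`.
#' @export
posthoc_rates <- function(record, table, view, reference_rate = NULL,
                          reference_sample = 1000L, seed = 1L) {
  if (is.null(reference_rate)) {
    reference_rate <- mean_mistranslation_rate(view, table,
                                               sample_size = reference_sample,
                                               seed = seed)
  }
  residents <- c(record$start, record$events$to)
  attempts <- c(0L, record$events$attempt)
  rates <- vapply(residents, genotype_mistranslation_rate, numeric(1),
                  table = table, USE.NAMES = FALSE)
  data.frame(attempt = attempts, rate_pct = 100 * rates / reference_rate)
}

#' Landscape-mean mistranslation rate
#'
#' Mean per-protein mistranslation rate over a uniform sample of sense
#' genotypes (or all of them if the space is small enough).
#'
#' @param view a `genotype_fitness_view`.
#' @param table a `mistranslation_table`.
#' @param sample_size number of genotypes to sample.
#' @param seed RNG seed.
#' @return Mean rate (probability).
#' @export
mean_mistranslation_rate <- function(view, table, sample_size = 1000L,
                                     seed = 1L) {
  g <- sample_sense_genotypes(view, sample_size, seed)
  mean(vapply(g, genotype_mistranslation_rate, numeric(1), table = table,
              USE.NAMES = FALSE))
}

#' Uniform sample of sense genotypes
#'
#' Samples codons uniformly from the sense codons encoding amino acids in
#' the landscape alphabet, independently per position.
#'
#' @param view a `genotype_fitness_view`.
#' @param count number of genotypes.
#' @param seed RNG seed.
#' @return Character vector of genotypes.
#' @export
sample_sense_genotypes <- function(view, count, seed = 1L) {
  L <- attr(view$landscape, "L")
  code <- view$code
  cs <- sense_codons(code)
  cs <- cs[code[cs] %in% attr(view$landscape, "alphabet")]
  set.seed(seed)
  m <- matrix(cs[sample.int(length(cs), count * L, replace = TRUE)],
              nrow = count)
  apply(m, 1, paste, collapse = "")
}

#' Beneficial mutation supply of a genotype
#'
#' The number of nonsynonymous single-nucleotide neighbors classified
#' beneficial under the configured condition; synonymous neutrality makes
#' this the count of genetic neighbors offering a selectable fitness
#' increase.
#'
#' @param view a `genotype_fitness_view`.
#' @param table rate table or `NULL`.
#' @param genotype focal genotype.
#' @param params a `population_params`.
#' @param cache optional moments cache.
#' @return Integer count.
#' @export
beneficial_supply <- function(view, table, genotype, params, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  nb <- single_nucleotide_neighbors(genotype)
  count <- 0L
  for (m in nb) {
    if (translate(m, view$code) == inviable_marker()) next
    eff <- mutation_effect(view, table, genotype, m, params, cache = cache,
                           check = FALSE)
    if (!eff$synonymous && eff$effect_class == "beneficial") count <- count + 1L
  }
  count
}

#' Summarize a set of adaptive walks
#'
#' Means and standard deviations of walk outcomes, plus the attribution
#' of fitness change to synonymous versus nonsynonymous fixations (the
#' attributions telescope to final minus initial fitness) and, where
#' walks carry mistranslation rates, the Kendall rank correlation between
#' an event's selection coefficient and the change in mistranslation rate
#' it causes.
#'
#' @param records list of `walk_record`s.
#' @param view a `genotype_fitness_view`.
#' @param table optional `mistranslation_table` used to compute
#'   per-event mistranslation rate changes (defaults to the rates stored
#'   in the records when present).
#' @return List of class `walk_summary`.
#' @export
summarize_walks <- function(records, view, table = NULL) {
  if (length(records) == 0L) stop("no walk records to summarize")
  fff <- vapply(records, `[[`, numeric(1), "final_fitness_fraction")
  nfix <- vapply(records, function(r) nrow(r$events), numeric(1))
  nsyn <- vapply(records, `[[`, numeric(1), "n_syn_fixed")
  nnon <- vapply(records, `[[`, numeric(1), "n_nonsyn_fixed")
  syn_gain <- numeric(length(records))
  nonsyn_gain <- numeric(length(records))
  ev_s <- numeric(0); ev_syn <- logical(0); ev_drate <- numeric(0)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (nrow(r$events) == 0L) next
    before <- c(r$start_fitness, utils::head(r$events$fitness_after, -1))
    delta <- r$events$fitness_after - before
    syn_gain[i] <- sum(delta[r$events$synonymous])
    nonsyn_gain[i] <- sum(delta[!r$events$synonymous])
    ev_s <- c(ev_s, r$events$s)
    ev_syn <- c(ev_syn, r$events$synonymous)
    if (!is.null(table)) {
      rate_from <- vapply(r$events$from, genotype_mistranslation_rate,
                          numeric(1), table = table, USE.NAMES = FALSE)
      rate_to <- vapply(r$events$to, genotype_mistranslation_rate,
                        numeric(1), table = table, USE.NAMES = FALSE)
      ev_drate <- c(ev_drate, rate_to - rate_from)
    } else if (!all(is.na(r$events$mistrans_rate_after))) {
      rate_from <- c(NA_real_, utils::head(r$events$mistrans_rate_after, -1))
      ev_drate <- c(ev_drate, r$events$mistrans_rate_after - rate_from)
    } else {
      ev_drate <- c(ev_drate, rep(NA_real_, nrow(r$events)))
    }
  }
  tau <- if (sum(stats::complete.cases(ev_s, ev_drate)) >= 3 &&
             stats::sd(ev_drate, na.rm = TRUE) > 0) {
    stats::cor(ev_s, ev_drate, method = "kendall", use = "complete.obs")
  } else NA_real_
  structure(list(
    n_walks = length(records),
    final_fitness_fraction = c(mean = mean(fff), sd = stats::sd(fff)),
    fixations = c(mean = mean(nfix), sd = stats::sd(nfix)),
    syn_fixations = c(mean = mean(nsyn), sd = stats::sd(nsyn)),
    nonsyn_fixations = c(mean = mean(nnon), sd = stats::sd(nnon)),
    syn_fitness_gain = c(mean = mean(syn_gain), sd = stats::sd(syn_gain)),
    nonsyn_fitness_gain = c(mean = mean(nonsyn_gain),
                            sd = stats::sd(nonsyn_gain)),
    effect_rate_change_tau = tau
  ), class = "walk_summary")
}

#' Write walk events to TSV
#'
#' One row per fixation event across replicates, with columns
#' `replicate`, `attempt`, `from`, `to`, `s`, `synonymous`,
#' `fitness_after`, `mistrans_rate_after`.
#'
#' @param records list of `walk_record`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_walk_events <- function(records, path) {
  rows <- lapply(seq_along(records), function(i) {
    ev <- records[[i]]$events
    if (nrow(ev) == 0L) return(NULL)
    cbind(replicate = i, ev)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(replicate = integer(0), attempt = integer(0),
                      from = character(0), to = character(0), s = numeric(0),
                      synonymous = logical(0), fitness_after = numeric(0),
                      mistrans_rate_after = numeric(0))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
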