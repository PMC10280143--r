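#' Population parameters
#'
#' @param N census (haploid) population size, at least 2.
#' @param n proteins produced per cell, at least 1.
#' @return List of class `population_params`.
#' @export
population_params <- function(N, n = 1L) {
  stopifnot(N >= 2, n >= 1)
  structure(list(N = N, n = as.integer(n)), class = "population_params")
}

#' Selection coefficient of a mutant
#'
#' The relative difference in expected fitness between an invading mutant
#' and the resident wild type: `s = E(f_mt) / E(f_wt) - 1`. A mutant with
#' zero expected fitness is lethal (`s = -1`). If the resident itself has
#' zero expected fitness, `s = 0` when the mutant does too, and `Inf`
#' ("rescue") when the mutant is viable.
#'
#' @param mean_wt,mean_mt nonnegative expected fitness of resident and
#'   mutant.
#' @return The selection coefficient (possibly `Inf`).
#' @export
selection_coefficient <- function(mean_wt, mean_mt) {
  if (mean_wt < 0 || mean_mt < 0) stop("expected fitness must be nonnegative")
  if (mean_wt == 0) {
    return(if (mean_mt == 0) 0 else Inf)
  }
  mean_mt / mean_wt - 1
}

#' Mistranslation-adjusted effective population size
#'
#' Nongenetic (between-cell) fitness variance weakens selection; the
#' effect is equivalent to shrinking a haploid population from N to
#' `Ne = N / (1 + CV^2)` where `CV^2 = Var(f_wt) / E(f_wt)^2` is the
#' squared coefficient of variation of the resident's fitness. Only the
#' resident's moments enter; `Ne = N` exactly when the variance is 0.
#'
#' @param N census population size.
#' @param mean_wt resident expected fitness, must be positive.
#' @param var_wt resident between-cell fitness variance, nonnegative.
#' @return Effective population size in `(0, N]`.
#' @export
effective_population_size <- function(N, mean_wt, var_wt) {
  stopifnot(N >= 2, var_wt >= 0)
  if (mean_wt <= 0) stop("effective population size undefined for zero mean fitness")
  N / (1 + var_wt / mean_wt^2)
}

#' Kimura fixation probability of a new mutant
#'
#' Diffusion approximation for a haploid population:
#' `u_fix = (1 - exp(-2 Ne s p)) / (1 - exp(-2 Ne s))` with initial
#' frequency `p = 1/N` (the initial frequency is set by the census size,
#' not by Ne). Evaluated via `expm1` so the neutral limit `u_fix -> 1/N`
#' is reached smoothly; exactly `s = 0` (or `|2 Ne s| < 1e-12`) returns
#' `1/N`. For strongly deleterious mutants the expression underflows to
#' an exponentially small value, computed in log space to avoid overflow.
#' `s = Inf` (rescue) gives 1. The result is clamped to `[0, 1]`.
#'
#' @param Ne effective population size (> 0).
#' @param s selection coefficient.
#' @param N census population size (initial frequency `1/N`).
#' @return Fixation probability in `[0, 1]`.
#' @export
fixation_probability <- function(Ne, s, N) {
  stopifnot(Ne > 0, N >= 2)
  if (is.infinite(s) && s > 0) return(1)
  x <- 2 * Ne * s
  if (abs(x) < 1e-12) return(1 / N)
  if (-x > 700) {
    # deleterious overflow guard: u ~ exp(x (1 - 1/N))
    return(exp(x * (1 - 1 / N)))
  }
  u <- expm1(-x / N) / expm1(-x)
  min(max(u, 0), 1)
}

#' Classify a mutation's fitness effect
#'
#' Nearly neutral iff `|s| < 1 / (4 Ne)` (effectively invisible to
#' selection at the resident's effective population size); otherwise
#' beneficial or deleterious by the sign of s. The same `|s|` can
#' therefore be neutral in one condition and selected in another, because
#' mistranslation changes Ne.
#'
#' @param s selection coefficient (may be `Inf` for rescue).
#' @param Ne effective population size under the condition being analyzed.
#' @return One of `"beneficial"`, `"nearly_neutral"`, `"deleterious"`.
#' @export
classify_effect <- function(s, Ne) {
  stopifnot(Ne > 0)
  if (is.infinite(s)) return("beneficial")
  if (abs(s) < 1 / (4 * Ne)) return("nearly_neutral")
  if (s > 0) "beneficial" else "deleterious"
}

#' Full effect of a single-nucleotide mutation
#'
#' Composes the fitness moments of resident and mutant (with a rate table,
#' or encoded fitness with zero variance without one) into the selection
#' coefficient, the resident's effective population size, the fixation
#' probability, the effect class and the synonymous flag.
#'
#' @param view a `genotype_fitness_view`.
#' @param table a `mistranslation_table`, or `NULL` for the
#'   no-mistranslation condition.
#' @param wt,mt resident and mutant genotypes (single-nucleotide
#'   neighbors).
#' @param params a `population_params`.
#' @param cache optional environment memoizing moments (per condition and
#'   expression level).
#' @param check if `FALSE`, skip the Hamming-distance precondition check
#'   (used by the walk inner loop, which constructs neighbors itself).
#' @return List of class `mutation_effect` with elements `s`, `Ne`,
#'   `u_fix`, `effect_class`, `synonymous`, `mean_wt`, `mean_mt`.
#' @export
mutation_effect <- function(view, table, wt, mt, params, cache = NULL,
                            check = TRUE) {
  if (check) {
    if (sum(strsplit(wt, "")[[1]] != strsplit(mt, "")[[1]]) != 1L) {
      stop("wt and mt must be single-nucleotide neighbors")
    }
  }
  mom <- function(g) {
    if (is.null(cache)) genotype_moments(g, view, table, params$n)
    else cached_moments(g, view, table, params$n, cache)
  }
  wt_m <- mom(wt)
  mt_m <- mom(mt)
  s <- selection_coefficient(wt_m$mean, mt_m$mean)
  if (wt_m$mean > 0) {
    Ne <- effective_population_size(params$N, wt_m$mean, wt_m$variance)
    u <- fixation_probability(Ne, s, params$N)
  } else {
    # degenerate resident: rescue fixes, dead-on-dead is neutral drift
    Ne <- params$N
    u <- if (is.infinite(s)) 1 else 1 / params$N
  }
  structure(list(s = s, Ne = Ne, u_fix = u,
                 effect_class = classify_effect(s, Ne),
                 synonymous = is_synonymous(wt, mt, view$code),
                 mean_wt = wt_m$mean, mean_mt = mt_m$mean),
            class = "mutation_effect")
}

#' Monte Carlo Wright-Fisher fixation estimate
#'
#' Validation oracle for the diffusion formula: haploid Wright-Fisher
#' binomial resampling with constant fitness values and one initial
#' mutant copy; returns the fraction of replicates in which the mutant
#' fixes. Replicates are simulated in parallel as a vector of mutant
#' counts.
#'
#' @param N population size.
#' @param fitness_wt,fitness_mt constant fitness of the two alleles.
#' @param replicates number of independent populations.
#' @param seed RNG seed.
#' @param max_generations safety cap (unfinished replicates count as
#'   lost; with the default cap this is vanishingly rare).
#' @return Estimated fixation probability.
#' @export
wright_fisher_fixation_estimate <- function(N, fitness_wt, fitness_mt,
                                            replicates = 1e5, seed = 1,
                                            max_generations = 200L * N) {
  stopifnot(N >= 2, fitness_wt > 0, fitness_mt >= 0)
  set.seed(seed)
  w <- fitness_mt / fitness_wt
  counts <- rep(1L, replicates)
  fixed <- 0L
  for (gen in seq_len(max_generations)) {
    active <- counts > 0L & counts < N
    if (!any(active)) break
    p <- counts[active] / N
    p_sel <- (p * w) / (p * w + (1 - p))
    counts[active] <- stats::rbinom(sum(active), N, p_sel)
    nf <- counts == N
    fixed <- fixed + sum(nf)
    counts[nf] <- 0L  # retire fixed replicates
  }
  fixed / replicates
}
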