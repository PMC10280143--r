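#' Generate a synthetic peptide fitness landscape
#'
#' Rough-Mount-Fuji-style generator: each peptide's raw score is an
#' additive sum of per-site amino-acid effects plus independent epistatic
#' noise; the ratio of `epistatic_sd` to `additive_weight` is the single
#' ruggedness knob (0 gives a smooth, purely additive landscape). A
#' lethal fraction is imposed by thresholding the raw scores at the
#' corresponding quantile (which preserves the neighbor-fitness
#' correlation near the viability boundary), the result is scaled to a
#' maximum of 1, and a power transform sets the mean of the viable
#' fitness values to `target_mean` while keeping the range [0, 1]. The
#' default `target_mean` of 0.08 emulates the highly skewed fitness
#' distribution of large deep-mutational-scanning binding landscapes,
#' whose typical variant binds far below the best one.
#'
#' @param L peptide length.
#' @param alphabet_size number of amino acids used (2-20, alphabetically
#'   first `alphabet_size` of the 20).
#' @param additive_weight weight of the additive component.
#' @param epistatic_sd standard deviation of the epistatic noise.
#' @param lethal_fraction fraction of peptides forced to exactly zero
#'   fitness (inviable).
#' @param target_mean target mean of the viable (> 0) fitness values.
#' @param seed RNG seed; generation is fully deterministic per seed
#'   (R's default Mersenne-Twister generator).
#' @param max_peptides enumeration budget guard.
#' @return A `peptide_landscape` (missing policy `"zero"` so mutation may
#'   step outside a reduced alphabet).
#' @export
generate_landscape <- function(L, alphabet_size = 20, additive_weight = 1,
                               epistatic_sd = 0.5, lethal_fraction = 0.2,
                               target_mean = 0.08, seed = 1L,
                               max_peptides = 2e5) {
  stopifnot(L >= 1, alphabet_size >= 2, alphabet_size <= 20,
            additive_weight >= 0, epistatic_sd >= 0,
            lethal_fraction >= 0, lethal_fraction < 1, target_mean > 0)
  if (alphabet_size^L > max_peptides) {
    stop("alphabet_size^L exceeds the enumeration budget")
  }
  alphabet <- amino_acids()[seq_len(alphabet_size)]
  peptides <- enumerate_peptides(L, alphabet)
  set.seed(seed)
  site_effects <- matrix(stats::rnorm(L * alphabet_size), nrow = L,
                         dimnames = list(NULL, alphabet))
  chars <- do.call(rbind, strsplit(peptides, ""))
  additive <- numeric(length(peptides))
  for (j in seq_len(L)) {
    additive <- additive + site_effects[j, match(chars[, j], alphabet)]
  }
  raw <- additive_weight * additive +
    stats::rnorm(length(peptides), sd = epistatic_sd)
  thr <- stats::quantile(raw, probs = lethal_fraction, names = FALSE)
  f <- pmax(0, raw - thr)
  if (max(f) == 0) stop("degenerate landscape: all fitness zero")
  f <- f / max(f)
  viable <- f > 0
  if (sum(viable) > 1 && stats::sd(f[viable]) > 0) {
    # power transform keeps [0, 1] and max = 1 while setting the viable mean
    obj <- function(lg) mean(f[viable]^exp(lg)) - target_mean
    lo <- -7; hi <- 7
    if (obj(lo) * obj(hi) < 0) {
      g <- exp(stats::uniroot(obj, c(lo, hi), tol = 1e-12)$root)
      f[viable] <- f[viable]^g
    }
  }
  peptide_landscape(stats::setNames(f, peptides), missing_policy = "zero")
}

#' Generate a synthetic mistranslation rate table
#'
#' Per sense codon, error rates to each of the 19 noncognate amino acids
#' are drawn log-normally: `log10(rate) ~ Normal(log10_rate_mean +
#' codon_effect, log10_rate_sd)` with a per-codon random effect
#' `codon_effect ~ Normal(0, per_codon_heterogeneity)` shared by the
#' codon's 19 targets. Rates are clamped to `rate_bounds` (default
#' [1e-5, 1e-2], the span measured for E. coli by mass spectrometry) and
#' row sums are validated to stay below 1.
#'
#' @param log10_rate_mean mean log10 error rate per (codon, target) pair
#'   (default -3.5).
#' @param log10_rate_sd spread of log10 rates within a codon.
#' @param per_codon_heterogeneity sd of the codon-level random effect;
#'   this is what makes some codons orders of magnitude more error-prone
#'   than others.
#' @param rate_bounds length-2 numeric, clamping interval for rates.
#' @param seed RNG seed.
#' @param code genetic code.
#' @return A `mistranslation_table`.
#' @export
generate_rate_table <- function(log10_rate_mean = -3.5, log10_rate_sd = 0.5,
                                per_codon_heterogeneity = 0.5,
                                rate_bounds = c(1e-5, 1e-2), seed = 1L,
                                code = standard_genetic_code()) {
  stopifnot(log10_rate_sd >= 0, per_codon_heterogeneity >= 0,
            length(rate_bounds) == 2, rate_bounds[1] > 0,
            rate_bounds[2] < 1, rate_bounds[1] <= rate_bounds[2])
  codons <- sense_codons(code)
  aas <- amino_acids()
  set.seed(seed)
  codon_effect <- stats::rnorm(length(codons), 0, per_codon_heterogeneity)
  rows <- vector("list", length(codons))
  for (i in seq_along(codons)) {
    cd <- codons[i]
    targets <- setdiff(aas, code[[cd]])
    lg <- stats::rnorm(length(targets), log10_rate_mean + codon_effect[i],
                       log10_rate_sd)
    rate <- pmin(pmax(10^lg, rate_bounds[1]), rate_bounds[2])
    rows[[i]] <- data.frame(codon = cd, amino_acid = targets, rate = rate,
                            stringsAsFactors = FALSE)
  }
  mistranslation_table(do.call(rbind, rows), code = code)
}

#' Built-in small fixtures
#'
#' Hand-written, fully enumerable instances used throughout the test
#' suite and examples:
#' \describe{
#'   \item{`flat`}{L = 2 over the full alphabet, every peptide fitness 1,
#'     uniform small error rates. Walks on it fix at the neutral rate.}
#'   \item{`toy-AD`}{L = 2 cartoon around the peptide "AD": the rate
#'     table makes the variant "AE" (one error at the second codon) more
#'     likely than "ED" (one error at the first), and the double
#'     substitution "DA" least likely, from the genotype GCTGAT.}
#'   \item{`enumerable-L2`}{L = 2 over the 4 amino acids {A, C, D, E}, a
#'     mildly rugged seeded synthetic landscape; the sense genotype space
#'     is small enough for every brute-force oracle.}
#'   \item{`two-peak`}{L = 2 over {A, D}, two separated fitness peaks
#'     (AA and DD high, AD and DA low).}
#' }
#'
#' @param name fixture name.
#' @return List with `landscape`, `table`, `code`, and for reduced
#'   fixtures `codons` (the codon universe used by exhaustive analyses).
#' @export
make_fixture <- function(name = c("flat", "toy-AD", "enumerable-L2",
                                  "two-peak")) {
  name <- match.arg(name)
  code <- standard_genetic_code()
  if (name == "flat") {
    peptides <- enumerate_peptides(2L)
    landscape <- peptide_landscape(
      stats::setNames(rep(1, length(peptides)), peptides))
    tab <- uniform_rate_table(1e-4, code)
    return(list(landscape = landscape, table = tab, code = code))
  }
  if (name == "toy-AD") {
    peptides <- enumerate_peptides(2L)
    # smooth toy scores: distance-from-"AD" decay plus a mild E bonus
    d <- (substr(peptides, 1, 1) != "A") + (substr(peptides, 2, 2) != "D")
    f <- 0.9^d
    f[peptides == "AE"] <- 0.95
    landscape <- peptide_landscape(stats::setNames(f, peptides))
    rates <- data.frame(
      codon = c("GAT", "GCT", "GCT", "GAT"),
      amino_acid = c("E", "E", "D", "A"),
      rate = c(1e-3, 1e-4, 1e-3, 1e-3),
      stringsAsFactors = FALSE)
    return(list(landscape = landscape,
                table = mistranslation_table(rates, code), code = code,
                genotype_AD = "GCTGAT"))
  }
  if (name == "enumerable-L2") {
    landscape <- generate_landscape(L = 2, alphabet_size = 4,
                                    epistatic_sd = 0.8,
                                    lethal_fraction = 0.15,
                                    target_mean = 0.3, seed = 42L)
    tab <- generate_rate_table(log10_rate_mean = -3,
                               per_codon_heterogeneity = 0.6, seed = 42L)
    codons <- sense_codons(code)
    codons <- codons[code[codons] %in% attr(landscape, "alphabet")]
    return(list(landscape = landscape, table = tab, code = code,
                codons = codons))
  }
  # two-peak
  f <- c(AA = 1, AD = 0.05, DA = 0.05, DD = 0.9)
  landscape <- peptide_landscape(f, missing_policy = "zero")
  tab <- uniform_rate_table(1e-4, code)
  codons <- sense_codons(code)
  codons <- codons[code[codons] %in% c("A", "D")]
  list(landscape = landscape, table = tab, code = code, codons = codons)
}

#' Uniform mistranslation rate table
#'
#' Every (sense codon, noncognate amino acid) pair gets the same error
#' rate; every genotype of a given length then has the same per-protein
#' mistranslation rate.
#'
#' @param rate the common error rate (must satisfy `19 * rate < 1`).
#' @param code genetic code.
#' @return A `mistranslation_table`.
#' @export
uniform_rate_table <- function(rate, code = standard_genetic_code()) {
  stopifnot(rate >= 0, 19 * rate < 1)
  if (rate == 0) return(zero_rate_table(code))
  codons <- sense_codons(code)
  rows <- do.call(rbind, lapply(codons, function(cd) {
    data.frame(codon = cd, amino_acid = setdiff(amino_acids(), code[[cd]]),
               rate = rate, stringsAsFactors = FALSE)
  }))
  mistranslation_table(rows, code = code)
}
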