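#' Construct a mistranslation rate table
#'
#' Per sense codon, the probability per translation event of incorporating
#' each of the 19 noncognate amino acids (misreading to stop codons is not
#' modeled). Codons or (codon, target) pairs without a measured rate get
#' rate 0, reflecting that mass-spectrometry surveys detect only a subset
#' of substitutions. The cognate probability of a codon is 1 minus the sum
#' of its error rates.
#'
#' @param rates data frame with columns `codon`, `amino_acid`, `rate`:
#'   one row per (sense codon, noncognate amino acid) pair with a nonzero
#'   error rate. May be empty (error-free translation).
#' @param code genetic code.
#' @return An object of class `mistranslation_table`: a list with
#'   `prob` (61 x 20 matrix of full per-codon amino-acid probabilities,
#'   rows summing to 1), `cognate_prob` (named vector) and `targets`
#'   (per-codon list of nonzero error targets, used by the
#'   branch-and-bound variant enumeration).
#' @export
mistranslation_table <- function(rates = data.frame(codon = character(),
                                                    amino_acid = character(),
                                                    rate = numeric()),
                                 code = standard_genetic_code()) {
  stopifnot(all(c("codon", "amino_acid", "rate") %in% names(rates)))
  codons <- sense_codons(code)
  aas <- amino_acids()
  if (nrow(rates) > 0) {
    rates$codon <- toupper(chartr("U", "T", rates$codon))
    bad <- !(rates$codon %in% codons)
    if (any(bad)) stop("unknown or stop codon in rate table: ",
                       paste(unique(rates$codon[bad]), collapse = ", "))
    if (!all(rates$amino_acid %in% aas)) stop("invalid amino-acid symbol in rate table")
    cognate <- code[rates$codon] == rates$amino_acid
    if (any(cognate)) stop("rate table lists cognate (codon, amino acid) pairs")
    if (any(rates$rate < 0 | rates$rate >= 1)) stop("rates must lie in [0, 1)")
    if (anyDuplicated(rates[c("codon", "amino_acid")])) {
      stop("duplicate (codon, amino_acid) rows in rate table")
    }
  }
  prob <- matrix(0, nrow = length(codons), ncol = length(aas),
                 dimnames = list(codons, aas))
  if (nrow(rates) > 0) {
    prob[cbind(rates$codon, rates$amino_acid)] <- rates$rate
  }
  err_sum <- rowSums(prob)
  if (any(err_sum >= 1)) {
    stop("per-codon error probabilities must sum to < 1; offending codon(s): ",
         paste(codons[err_sum >= 1], collapse = ", "))
  }
  cognate_prob <- 1 - err_sum
  prob[cbind(codons, unname(code[codons]))] <- cognate_prob
  targets <- lapply(codons, function(cd) {
    r <- prob[cd, ]
    r <- r[r > 0]
    # cognate first so the encoded branch is explored first
    ord <- order(names(r) != code[[cd]], -r)
    list(aa = names(r)[ord], p = unname(r[ord]))
  })
  names(targets) <- codons
  structure(list(prob = prob,
                 cognate_prob = stats::setNames(cognate_prob, codons),
                 targets = targets,
                 code = code),
            class = "mistranslation_table")
}

#' @export
print.mistranslation_table <- function(x, ...) {
  err <- 1 - x$cognate_prob
  cat("mistranslation_table:", sum(x$prob > 0) - nrow(x$prob),
      "nonzero error entries | per-codon error totals:",
      signif(min(err), 3), "-", signif(max(err), 3), "\n")
  invisible(x)
}

#' Read a mistranslation rate table from TSV
#'
#' Expects header columns `codon`, `amino_acid`, `rate`; one row per
#' measured (codon, noncognate amino acid) pair. Unlisted pairs get rate 0.
#'
#' @param path file path.
#' @param code genetic code.
#' @return A `mistranslation_table`.
#' @export
read_rate_table <- function(path, code = standard_genetic_code()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = character(0))
  if (!all(c("codon", "amino_acid", "rate") %in% names(tab))) {
    stop("rate table file must have columns codon, amino_acid, rate")
  }
  tab$rate <- as.numeric(tab$rate)
  mistranslation_table(tab, code = code)
}

#' Write a mistranslation rate table to TSV
#'
#' Emits only nonzero error rates, sorted by codon then amino acid, with
#' 17 significant digits.
#'
#' @param table a `mistranslation_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path) {
  code <- table$code
  idx <- which(table$prob > 0, arr.ind = TRUE)
  codon <- rownames(table$prob)[idx[, 1]]
  aa <- colnames(table$prob)[idx[, 2]]
  keep <- code[codon] != aa
  tab <- data.frame(codon = codon[keep], amino_acid = aa[keep],
                    rate = formatC(table$prob[idx][keep], digits = 17,
                                   format = "g"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$codon, tab$amino_acid), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' An error-free (all-zero) rate table
#'
#' Useful as the degenerate control: with it, the whole pipeline reduces
#' exactly to the no-mistranslation condition.
#'
#' @param code genetic code.
#' @return A `mistranslation_table` with every error rate 0.
#' @export
zero_rate_table <- function(code = standard_genetic_code()) {
  mistranslation_table(code = code)
}

#' Distribution of protein variants produced by error-prone translation
#'
#' For a sense genotype, every translation event yields the encoded
#' peptide or one of its mistranslated variants. Codon errors are
#' independent, so the probability of a variant peptide is the product of
#' the per-codon amino-acid probabilities. Variants whose unpruned
#' probability falls below `prune_threshold` are dropped (the encoded
#' peptide is always retained) and the remaining mass is renormalized
#' to 1. Enumeration is branch-and-bound over per-codon substitutions with
#' an exact remaining-product upper bound, so the 20^L candidate set is
#' never materialized.
#'
#' @param genotype a single sense nucleotide sequence.
#' @param table a `mistranslation_table`.
#' @param prune_threshold probability below which variants are ignored
#'   (default 1e-9).
#' @return An object of class `variant_distribution`: list with
#'   `peptide`, `prob` (renormalized, summing to 1), `encoded`,
#'   `prune_threshold`.
#' @export
variant_distribution <- function(genotype, table, prune_threshold = 1e-9) {
  stopifnot(inherits(table, "mistranslation_table"))
  if (!(prune_threshold > 0 && prune_threshold < 1)) {
    stop("prune_threshold must lie in (0, 1)")
  }
  genotype <- as_genotype(genotype)
  codons <- genotype_codons(genotype)
  if (any(table$code[codons] == "*")) {
    stop("cannot build a variant distribution for a stop-containing genotype")
  }
  tg <- table$targets[codons]
  L <- length(codons)
  # suffix_max[i]: largest achievable product over codons i..L
  maxp <- vapply(tg, function(t) max(t$p), numeric(1))
  suffix_max <- rev(cumprod(rev(maxp)))
  suffix_max <- c(suffix_max[-1], 1)
  # iterative cross product with pruning against the exact upper bound
  pep <- ""
  pr <- 1
  for (i in seq_len(L)) {
    aa <- tg[[i]]$aa
    p <- tg[[i]]$p
    pep <- as.vector(outer(pep, aa, paste0))
    pr <- as.vector(outer(pr, p))
    keep <- pr * suffix_max[i] >= prune_threshold
    pep <- pep[keep]
    pr <- pr[keep]
  }
  keep <- pr >= prune_threshold
  pep <- pep[keep]
  pr <- pr[keep]
  encoded <- paste(table$code[codons], collapse = "")
  if (!(encoded %in% pep)) {
    pep <- c(encoded, pep)
    pr <- c(prod(table$cognate_prob[codons]), pr)
  }
  ord <- order(-pr, pep)
  structure(list(peptide = pep[ord], prob = pr[ord] / sum(pr),
                 encoded = encoded, prune_threshold = prune_threshold),
            class = "variant_distribution")
}

#' @export
print.variant_distribution <- function(x, ...) {
  cat("variant_distribution:", length(x$prob), "variants | encoded",
      x$encoded, "retains", signif(x$prob[x$peptide == x$encoded], 4), "\n")
  invisible(x)
}

#' Expected fitness and between-cell fitness variance of a genotype
#'
#' Each cell produces `n` protein copies, drawn independently from the
#' variant distribution, and every copy contributes equally and
#' independently to fitness; cell fitness is the average contribution.
#' Hence `E(f) = sum(q_v * f_v)` (independent of `n`) and
#' `Var(f) = (sum(q_v * f_v^2) - E(f)^2) / n`, the variance of the mean of
#' `n` independent draws under multinomial sampling.
#'
#' @param dist a `variant_distribution`.
#' @param view a `genotype_fitness_view` supplying variant fitness values.
#' @param n proteins produced per cell (positive integer).
#' @return List with `mean`, `variance`, `n`.
#' @export
fitness_moments <- function(dist, view, n = 1L) {
  stopifnot(inherits(dist, "variant_distribution"), n >= 1)
  f <- peptide_fitness(view$landscape, dist$peptide)
  m <- sum(dist$prob * f)
  v <- max(0, sum(dist$prob * f^2) - m^2) / n
  list(mean = m, variance = v, n = as.integer(n))
}

#' Per-protein mistranslation rate of a genotype
#'
#' The probability that a single produced protein differs from the encoded
#' peptide at one or more positions: 1 minus the product of per-codon
#' cognate probabilities. Equals 1 minus the unpruned probability of the
#' encoded variant.
#'
#' @param genotype a single sense nucleotide sequence.
#' @param table a `mistranslation_table`.
#' @return Probability in `[0, 1)`.
#' @export
genotype_mistranslation_rate <- function(genotype, table) {
  genotype <- as_genotype(genotype)
  codons <- genotype_codons(genotype)
  if (any(table$code[codons] == "*")) {
    stop("mistranslation rate undefined for stop-containing genotype")
  }
  1 - prod(table$cognate_prob[codons])
}

#' Fitness moments of a genotype under a condition
#'
#' Convenience composition: with a rate table, the moments come from the
#' pruned variant distribution; without one (`table = NULL`, the
#' no-mistranslation condition) the mean is the encoded fitness and the
#' variance is 0. Stop-containing genotypes have mean 0 and variance 0
#' under either condition.
#'
#' @param genotype a single nucleotide sequence.
#' @param view a `genotype_fitness_view`.
#' @param table a `mistranslation_table` or `NULL`.
#' @param n proteins per cell.
#' @param prune_threshold passed to [variant_distribution()].
#' @return List with `mean`, `variance`, `n`.
#' @export
genotype_moments <- function(genotype, view, table = NULL, n = 1L,
                             prune_threshold = 1e-9) {
  if (translate(genotype, view$code) == inviable_marker()) {
    return(list(mean = 0, variance = 0, n = as.integer(n)))
  }
  if (is.null(table)) {
    return(list(mean = encoded_fitness(view, genotype), variance = 0,
                n = as.integer(n)))
  }
  fitness_moments(variant_distribution(genotype, table, prune_threshold),
                  view, n = n)
}

#' Memoizing wrapper around [genotype_moments()]
#'
#' The adaptive-walk simulator evaluates the same genotypes many times
#' (every proposal needs the mutant's mean and the resident's mean and
#' variance); moments are cached in an environment keyed by genotype.
#' Keys are condition-specific because `Var(f)` scales as 1/n: use one
#' cache per (condition, n).
#'
#' @param cache an environment (e.g. `new.env(parent = emptyenv())`).
#' @inheritParams genotype_moments
#' @return List with `mean`, `variance`, `n`.
#' @export
cached_moments <- function(genotype, view, table, n, cache,
                           prune_threshold = 1e-9) {
  hit <- get0(genotype, envir = cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  m <- genotype_moments(genotype, view, table, n, prune_threshold)
  cache[[genotype]] <- m
  m
}
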