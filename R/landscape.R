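#' Construct a peptide fitness landscape
#'
#' A peptide landscape maps every length-L amino-acid sequence over a
#' (possibly reduced) alphabet to a nonnegative fitness value. Landscapes
#' are combinatorially complete over their alphabet; peptides outside the
#' alphabet are handled by the missing-value policy: `"error"` refuses
#' lookups of unknown peptides, `"zero"` treats them as inviable
#' (fitness 0). The reduced-alphabet fixtures rely on the `"zero"` policy
#' so that mutation can still step outside the measured alphabet.
#'
#' @param fitness named numeric vector: names are peptides, values are
#'   nonnegative fitness (a binding-affinity proxy or a growth rate,
#'   depending on the assay the landscape emulates).
#' @param missing_policy `"error"` or `"zero"`.
#' @return An object of class `peptide_landscape`: the named fitness
#'   vector with attributes `L`, `alphabet`, `max_fitness`, `mean_fitness`
#'   and `missing_policy`.
#' @export
peptide_landscape <- function(fitness, missing_policy = c("error", "zero")) {
  missing_policy <- match.arg(missing_policy)
  peptides <- names(fitness)
  if (is.null(peptides) || anyNA(peptides)) stop("fitness must be named by peptide")
  if (anyDuplicated(peptides)) stop("duplicate peptide rows")
  if (any(!is.finite(fitness)) || any(fitness < 0)) {
    stop("fitness values must be finite and nonnegative")
  }
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("all peptides must have the same length")
  alphabet <- sort(unique(unlist(strsplit(peptides, ""))))
  if (!all(alphabet %in% amino_acids())) {
    stop("peptides contain non-amino-acid symbols")
  }
  if (length(fitness) != length(alphabet)^L) {
    stop("landscape is not combinatorially complete over its alphabet: ",
         length(fitness), " entries for alphabet size ", length(alphabet),
         " and L = ", L)
  }
  fitness <- fitness[order(peptides)]
  structure(fitness,
            L = L,
            alphabet = alphabet,
            max_fitness = max(fitness),
            mean_fitness = mean(fitness),
            missing_policy = missing_policy,
            class = "peptide_landscape")
}

#' @export
print.peptide_landscape <- function(x, ...) {
  cat("peptide_landscape: L =", attr(x, "L"),
      "| alphabet", length(attr(x, "alphabet")),
      "| entries", length(x),
      "| mean", signif(attr(x, "mean_fitness"), 4),
      "| max", signif(attr(x, "max_fitness"), 4), "\n")
  invisible(x)
}

#' Look up peptide fitness
#'
#' @param landscape a `peptide_landscape`.
#' @param peptide character vector of peptides.
#' @return Numeric vector of fitness values; unknown peptides follow the
#'   landscape's missing-value policy.
#' @export
peptide_fitness <- function(landscape, peptide) {
  f <- unclass(landscape)[peptide]
  if (anyNA(f)) {
    if (attr(landscape, "missing_policy") == "zero") {
      f[is.na(f)] <- 0
    } else {
      stop("peptide(s) absent from landscape: ",
           paste(utils::head(peptide[is.na(f)], 3), collapse = ", "))
    }
  }
  unname(f)
}

#' Read a peptide landscape from a TSV file
#'
#' Expects a header with columns `peptide` and `fitness`.
#'
#' @param path file path.
#' @param missing_policy `"error"` or `"zero"`; with `"error"`, a file
#'   that is not combinatorially complete over its alphabet is refused.
#' @return A `peptide_landscape`.
#' @export
read_landscape <- function(path, missing_policy = c("error", "zero")) {
  missing_policy <- match.arg(missing_policy)
  # read everything as character: peptides like "NA" (Asn-Ala) or "T"
  # must not be parsed as missing values or logicals
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = character(0))
  if (!all(c("peptide", "fitness") %in% names(tab))) {
    stop("landscape file must have columns 'peptide' and 'fitness'")
  }
  fitness <- stats::setNames(as.numeric(tab$fitness), tab$peptide)
  if (anyDuplicated(tab$peptide)) stop("duplicate peptide rows in ", path)
  if (any(fitness < 0)) stop("negative fitness in ", path)
  L <- unique(nchar(tab$peptide))
  if (length(L) != 1L) stop("peptides of differing length in ", path)
  alphabet <- sort(unique(unlist(strsplit(tab$peptide, ""))))
  n_expected <- length(alphabet)^L
  if (length(fitness) < n_expected) {
    if (missing_policy == "error") {
      stop("landscape incomplete: ", length(fitness), " of ", n_expected,
           " peptides present")
    }
    all_pep <- enumerate_peptides(L, alphabet)
    filled <- stats::setNames(numeric(length(all_pep)), all_pep)
    filled[names(fitness)] <- fitness
    fitness <- filled
  }
  peptide_landscape(fitness, missing_policy = missing_policy)
}

#' Write a peptide landscape to TSV
#'
#' Rows are emitted in lexicographic peptide order; fitness is serialized
#' with 17 significant digits so that a write/read round trip is
#' bit-exact.
#'
#' @param landscape a `peptide_landscape`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  tab <- data.frame(peptide = names(landscape),
                    fitness = formatC(as.numeric(landscape), digits = 17,
                                      format = "g"),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate all peptides of length L over an alphabet
#' @param L peptide length.
#' @param alphabet character vector of amino-acid symbols.
#' @return Character vector of `length(alphabet)^L` peptides, sorted.
#' @export
enumerate_peptides <- function(L, alphabet = amino_acids()) {
  alphabet <- sort(alphabet)
  grids <- rep(list(alphabet), L)
  m <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(m)))
}

#' Bind a landscape to a genetic code
#'
#' The genotype fitness view lifts a peptide landscape to nucleotide
#' genotype space: the encoded fitness of a genotype is the landscape
#' fitness of its translated peptide, and 0 for stop-containing
#' genotypes.
#'
#' @param landscape a `peptide_landscape`.
#' @param code genetic code.
#' @return An object of class `genotype_fitness_view`.
#' @export
genotype_fitness_view <- function(landscape, code = standard_genetic_code()) {
  stopifnot(inherits(landscape, "peptide_landscape"))
  structure(list(landscape = landscape, code = code),
            class = "genotype_fitness_view")
}

#' Encoded fitness of nucleotide genotypes
#'
#' @param view a `genotype_fitness_view`.
#' @param genotype character vector of nucleotide sequences.
#' @return Numeric vector: landscape fitness of the translated peptide,
#'   0 for stop-containing genotypes.
#' @export
encoded_fitness <- function(view, genotype) {
  pep <- translate(genotype, view$code)
  out <- numeric(length(pep))
  sense <- pep != inviable_marker()
  if (any(sense)) out[sense] <- peptide_fitness(view$landscape, pep[sense])
  out
}

#' Single-amino-acid neighbors of a peptide
#'
#' All peptides at amino-acid Hamming distance 1, over a configurable
#' alphabet, in deterministic order (position-major, substitutions in
#' alphabetical order).
#'
#' @param peptide a single amino-acid sequence.
#' @param alphabet amino-acid alphabet to substitute from (default all 20).
#' @return Character vector of `(length(alphabet) - 1) * nchar(peptide)`
#'   peptides.
#' @export
phenotypic_neighbors <- function(peptide, alphabet = amino_acids()) {
  chars <- strsplit(peptide, "")[[1]]
  alphabet <- sort(alphabet)
  out <- character((length(alphabet) - 1L) * length(chars))
  k <- 0L
  for (i in seq_along(chars)) {
    for (a in alphabet) {
      if (a == chars[i]) next
      k <- k + 1L
      tmp <- chars
      tmp[i] <- a
      out[k] <- paste(tmp, collapse = "")
    }
  }
  out[seq_len(k)]
}

#' Enumerate all sense genotypes encoding peptides of length L
#'
#' All combinations of sense codons; used by the exhaustive analyses on
#' small landscapes.
#'
#' @param L peptide length.
#' @param code genetic code.
#' @param codons optional restricted codon set (must be sense codons).
#' @return Character vector of genotypes, sorted.
#' @export
enumerate_sense_genotypes <- function(L, code = standard_genetic_code(),
                                      codons = NULL) {
  cs <- if (is.null(codons)) sense_codons(code) else codons
  if (any(code[cs] == "*")) stop("restricted codon set contains stop codons")
  grids <- rep(list(sort(cs)), L)
  m <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(m)))
}
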