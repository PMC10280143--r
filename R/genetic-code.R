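#' The standard genetic code
#'
#' A named character vector mapping each of the 64 DNA codons (uppercase,
#' T not U) to a one-letter amino-acid symbol, with `"*"` marking the three
#' stop codons (TAA, TAG, TGA).
#'
#' @return Named character vector of length 64.
#' @examples
#' standard_genetic_code()[["GCT"]]  # "A"
#' @export
standard_genetic_code <- function() {
  .STANDARD_CODE
}

# Hard-coded standard code; the codon order is the usual TCAG enumeration.
.CODE_BASES <- c("T", "C", "A", "G")
.STANDARD_CODE <- local({
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(.CODE_BASES, .CODE_BASES, paste0))),
    .CODE_BASES, paste0
  )))
  stats::setNames(aas, codons)
})

#' Amino-acid alphabet
#'
#' The 20 standard amino acids, one-letter symbols in alphabetical order.
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  sort(unique(.STANDARD_CODE[.STANDARD_CODE != "*"]))
}

#' Sense codons of a genetic code
#'
#' @param code named character vector as returned by
#'   [standard_genetic_code()].
#' @return Character vector of the codons not translated to stop.
#' @export
sense_codons <- function(code = standard_genetic_code()) {
  names(code)[code != "*"]
}

#' Stop marker used for inviable (stop-containing) genotypes
#' @return The string `"*"`.
#' @export
inviable_marker <- function() "*"

#' Normalize and validate a nucleotide genotype
#'
#' Uppercases, converts U to T and checks that the sequence contains only
#' A, C, G, T and has length divisible by 3.
#'
#' @param x character vector of nucleotide sequences.
#' @return The canonicalized sequences.
#' @export
as_genotype <- function(x) {
  x <- chartr("acgtu", "ACGTT", x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid nucleotide characters in genotype(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  if (any(nchar(x) %% 3L != 0L)) {
    stop("genotype length must be divisible by 3")
  }
  x
}

#' Split a genotype into its codons
#' @param genotype a single nucleotide sequence (length divisible by 3).
#' @return Character vector of 3-letter codons.
#' @export
genotype_codons <- function(genotype) {
  n <- nchar(genotype)
  substring(genotype, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate nucleotide genotypes to peptides
#'
#' Codon-wise translation under `code`. Genotypes containing one or more
#' stop codons translate to the inviable marker `"*"`: they are legitimate
#' members of genotype space (reachable by mutation) but encode no
#' full-length peptide and are assigned fitness zero downstream.
#'
#' @param genotype character vector of nucleotide sequences.
#' @param code genetic code, default the standard code.
#' @return Character vector: the encoded peptide, or `"*"` for
#'   stop-containing genotypes.
#' @examples
#' translate("GCTGAT")  # "AD"
#' translate("TAAGCT")  # "*"
#' @export
translate <- function(genotype, code = standard_genetic_code()) {
  genotype <- as_genotype(genotype)
  vapply(genotype, function(g) {
    aa <- code[genotype_codons(g)]
    if (anyNA(aa) || any(aa == "*")) inviable_marker() else
      paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse-translate a peptide into one encoding genotype
#'
#' Picks, for every amino acid, either the alphabetically first codon or a
#' uniformly random synonymous codon.
#'
#' @param peptide a single amino-acid sequence.
#' @param code genetic code.
#' @param random if `TRUE`, sample a synonymous codon uniformly at random
#'   for each position (uses the current RNG stream).
#' @return A nucleotide sequence of length `3 * nchar(peptide)`.
#' @export
reverse_translate <- function(peptide, code = standard_genetic_code(),
                              random = FALSE) {
  aas <- strsplit(peptide, "")[[1]]
  codons <- vapply(aas, function(a) {
    opts <- sort(names(code)[code == a])
    if (length(opts) == 0L) stop("no codon encodes amino acid ", a)
    if (random && length(opts) > 1L) opts[sample.int(length(opts), 1L)]
    else opts[1L]
  }, character(1))
  paste(codons, collapse = "")
}

#' All single-nucleotide neighbors of a genotype
#'
#' Returns the 9L sequences that differ from `genotype` at exactly one
#' position, in deterministic order: position-major, alternative bases in
#' alphabetical order.
#'
#' @param genotype a single nucleotide sequence.
#' @return Character vector of length `3 * nchar(genotype)` (9L for a
#'   genotype encoding L amino acids).
#' @export
single_nucleotide_neighbors <- function(genotype) {
  genotype <- as_genotype(genotype)
  n <- nchar(genotype)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(genotype, "")[[1]]
  out <- character(3L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (b in bases) {
      if (b == chars[i]) next
      k <- k + 1L
      tmp <- chars
      tmp[i] <- b
      out[k] <- paste(tmp, collapse = "")
    }
  }
  out
}

#' Is a single-nucleotide mutation synonymous?
#'
#' Two genotypes at nucleotide Hamming distance 1 are synonymous iff they
#' encode the same peptide. A stop-containing genotype is never synonymous
#' to a sense genotype (and two stop-containing genotypes are not treated
#' as synonymous either: neither encodes a peptide).
#'
#' @param g1,g2 nucleotide sequences differing at exactly one position.
#' @param code genetic code.
#' @return Logical scalar.
#' @export
is_synonymous <- function(g1, g2, code = standard_genetic_code()) {
  g1 <- as_genotype(g1); g2 <- as_genotype(g2)
  if (nchar(g1) != nchar(g2) ||
      sum(strsplit(g1, "")[[1]] != strsplit(g2, "")[[1]]) != 1L) {
    stop("genotypes must differ at exactly one nucleotide")
  }
  p1 <- translate(g1, code)
  p2 <- translate(g2, code)
  if (p1 == inviable_marker() || p2 == inviable_marker()) return(FALSE)
  p1 == p2
}
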