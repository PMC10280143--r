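Package: mistrans
Title: Mistranslation and the Topography of Protein Adaptive Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models how translation errors (phenotypic mutations) reshape
    protein adaptive landscapes and evolutionary dynamics. From per-codon
    mistranslation rates and a peptide-level fitness landscape the package
    computes the distribution of protein variants produced by error-prone
    translation, the expected fitness and between-cell fitness variance of a
    genotype, mistranslation-adjusted effective population sizes and Kimura
    fixation probabilities, origin-fixation adaptive walks in the weak
    mutation-strong selection regime, and landscape topography statistics
    (flattening, mutation-effect censuses, nearly-neutral-network fitness
    peaks, epistasis classification). Includes generators for synthetic
    combinatorially complete landscapes and codon-level error-rate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
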