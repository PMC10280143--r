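#' Landscape flattening regression
#'
#' Least-squares regression of expected fitness with mistranslation on
#' encoded (no-mistranslation) fitness over a sample of genotypes. A
#' slope below one is the signature of landscape flattening: genotypes of
#' low fitness tend to gain from mistranslation, genotypes of high
#' fitness tend to lose.
#'
#' @param genotypes character vector of sense genotypes (>= 3).
#' @param view a `genotype_fitness_view`.
#' @param table a `mistranslation_table`.
#' @param params a `population_params` (expression level `n` sets the
#'   variance but not the mean, so the slope is n-independent).
#' @param cache optional moments cache.
#' @return List with `slope`, `intercept`, `r` (Pearson correlation),
#'   and `delta` (per-genotype fitness change, mistranslation minus
#'   encoded).
#' @export
flattening_fit <- function(genotypes, view, table, params = population_params(1e6),
                           cache = NULL) {
  if (length(genotypes) < 3L) stop("need at least 3 genotypes")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  f0 <- encoded_fitness(view, genotypes)
  f1 <- vapply(genotypes, function(g)
    cached_moments(g, view, table, params$n, cache)$mean,
    numeric(1), USE.NAMES = FALSE)
  if (stats::sd(f0) == 0) stop("degenerate sample: encoded fitness is constant")
  fit <- stats::lm(f1 ~ f0)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(f0, f1),
       delta = f1 - f0)
}

#' Mean fitness of a genotype's phenotypic and genotypic neighborhoods
#'
#' The phenotypic mean averages landscape fitness over the 19L
#' single-amino-acid neighbors of the encoded peptide; the genotypic mean
#' averages encoded fitness over the 9L single-nucleotide neighbors
#' (stop-creating neighbors contribute 0). Their correlation across
#' genotypes links the nongenetic variation mistranslation creates to the
#' genetic variation available to mutation.
#'
#' @param genotype a single sense genotype.
#' @param view a `genotype_fitness_view`.
#' @return Named numeric vector `c(phenotypic, genotypic)`.
#' @export
neighbor_fitness_means <- function(genotype, view) {
  pep <- translate(genotype, view$code)
  if (pep == inviable_marker()) stop("genotype contains a stop codon")
  ph <- phenotypic_neighbors(pep)
  gt <- single_nucleotide_neighbors(genotype)
  c(phenotypic = mean(peptide_fitness(view$landscape, ph)),
    genotypic = mean(encoded_fitness(view, gt)))
}

#' Census of mutation-effect classes with and without mistranslation
#'
#' Classifies each (wild type, mutant) pair under both conditions and
#' tabulates the 3x3 transition census between the no-mistranslation and
#' mistranslation classifications, together with the per-pair change in
#' fixation probability.
#'
#' @param view a `genotype_fitness_view`.
#' @param table a `mistranslation_table` (the with-mistranslation
#'   condition).
#' @param pairs data frame with columns `wt` and `mt`, single-nucleotide
#'   neighbor genotypes.
#' @param params a `population_params`.
#' @return List with `census` (3x3 table, rows = class without
#'   mistranslation, cols = class with), `pairs` (the input plus columns
#'   `class_none`, `class_mis`, `s_none`, `s_mis`, `u_none`, `u_mis`,
#'   `synonymous`).
#' @export
classify_mutation_sample <- function(view, table, pairs, params) {
  stopifnot(all(c("wt", "mt") %in% names(pairs)))
  cache0 <- new.env(parent = emptyenv())
  cache1 <- new.env(parent = emptyenv())
  classes <- c("beneficial", "nearly_neutral", "deleterious")
  n <- nrow(pairs)
  class_none <- character(n); class_mis <- character(n)
  s_none <- numeric(n); s_mis <- numeric(n)
  u_none <- numeric(n); u_mis <- numeric(n)
  syn <- logical(n)
  for (i in seq_len(n)) {
    e0 <- mutation_effect(view, NULL, pairs$wt[i], pairs$mt[i], params,
                          cache = cache0)
    e1 <- mutation_effect(view, table, pairs$wt[i], pairs$mt[i], params,
                          cache = cache1)
    class_none[i] <- e0$effect_class; class_mis[i] <- e1$effect_class
    s_none[i] <- e0$s; s_mis[i] <- e1$s
    u_none[i] <- e0$u_fix; u_mis[i] <- e1$u_fix
    syn[i] <- e0$synonymous
  }
  census <- base::table(factor(class_none, classes),
                        factor(class_mis, classes))
  names(dimnames(census)) <- c("without", "with")
  out_pairs <- cbind(pairs,
                     data.frame(class_none = class_none, class_mis = class_mis,
                                s_none = s_none, s_mis = s_mis,
                                u_none = u_none, u_mis = u_mis,
                                synonymous = syn,
                                stringsAsFactors = FALSE))
  list(census = census, pairs = out_pairs)
}

#' Sample single-nucleotide mutation pairs
#'
#' Uniform random genotypes with one uniformly chosen single-nucleotide
#' neighbor each; wild types are restricted to viable (sense, nonzero
#' encoded fitness) genotypes so that selection coefficients are defined.
#'
#' @param view a `genotype_fitness_view`.
#' @param count number of pairs.
#' @param seed RNG seed.
#' @return Data frame with columns `wt`, `mt`.
#' @export
sample_mutation_pairs <- function(view, count, seed = 1L) {
  g <- sample_sense_genotypes(view, 3L * count, seed)
  f <- encoded_fitness(view, g)
  g <- g[f > 0]
  if (length(g) < count) stop("too few viable genotypes sampled; enlarge the pool")
  g <- g[seq_len(count)]
  mt <- vapply(g, function(x) {
    nb <- single_nucleotide_neighbors(x)
    nb[sample.int(length(nb), 1L)]
  }, character(1), USE.NAMES = FALSE)
  data.frame(wt = g, mt = mt, stringsAsFactors = FALSE)
}

#' Nearly-neutral networks and fitness peaks
#'
#' Builds the undirected graph on `genotype_set` with an edge between
#' single-nucleotide neighbors a, b iff the mutation is nearly neutral in
#' both directions (|s(a->b)| < 1/(4 Ne(a)) and |s(b->a)| < 1/(4 Ne(b))).
#' Each connected component is a nearly-neutral network; it is a fitness
#' peak iff every single-nucleotide neighbor of a member that lies outside
#' the network has lower expected fitness beyond the neutral threshold
#' (i.e. the outgoing mutation is classified deleterious). Outside
#' neighbors are evaluated on demand against their adjacent member;
#' stop-containing neighbors are lethal and never block a peak.
#'
#' @param genotype_set character vector of sense genotypes.
#' @param view a `genotype_fitness_view`.
#' @param table rate table or `NULL`.
#' @param params a `population_params`.
#' @param cache optional moments cache.
#' @return List of networks, each a list with `members` and `is_peak`.
#' @export
neutral_networks <- function(genotype_set, view, table, params,
                             cache = NULL) {
  stopifnot(length(genotype_set) > 0)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  genotype_set <- unique(genotype_set)
  in_set <- new.env(parent = emptyenv())
  for (g in genotype_set) assign(g, TRUE, envir = in_set)
  mom <- function(g) cached_moments(g, view, table, params$n, cache)
  ne_of <- function(m) effective_population_size(params$N, m$mean, m$variance)
  edges_from <- character(0); edges_to <- character(0)
  for (a in genotype_set) {
    ma <- mom(a)
    if (ma$mean <= 0) next
    Nea <- ne_of(ma)
    for (b in single_nucleotide_neighbors(a)) {
      if (b <= a) next  # each unordered pair once
      if (!isTRUE(get0(b, envir = in_set, inherits = FALSE))) next
      mb <- mom(b)
      if (mb$mean <= 0) next
      s_ab <- mb$mean / ma$mean - 1
      if (abs(s_ab) >= 1 / (4 * Nea)) next
      s_ba <- ma$mean / mb$mean - 1
      if (abs(s_ba) >= 1 / (4 * ne_of(mb))) next
      edges_from <- c(edges_from, a); edges_to <- c(edges_to, b)
    }
  }
  gr <- igraph::make_empty_graph(n = 0, directed = FALSE)
  gr <- igraph::add_vertices(gr, length(genotype_set),
                             name = genotype_set)
  if (length(edges_from) > 0) {
    gr <- igraph::add_edges(gr, rbind(edges_from, edges_to))
  }
  comp <- igraph::components(gr)
  membership <- comp$membership
  lapply(seq_len(comp$no), function(ci) {
    members <- genotype_set[membership == ci]
    is_peak <- TRUE
    for (a in members) {
      ma <- mom(a)
      if (ma$mean <= 0) { is_peak <- FALSE; break }
      Nea <- ne_of(ma)
      for (b in single_nucleotide_neighbors(a)) {
        if (b %in% members) next
        mb <- mom(b)
        s_ab <- selection_coefficient(ma$mean, mb$mean)
        if (classify_effect(s_ab, Nea) != "deleterious") {
          is_peak <- FALSE
          break
        }
      }
      if (!is_peak) break
    }
    list(members = members, is_peak = is_peak)
  })
}

#' Count fitness peaks among the top-K genotypes
#'
#' Ranks sense genotypes by expected fitness under the condition (ties
#' broken by lexicographic genotype order), takes the top K, partitions
#' them into nearly-neutral networks and counts the networks flagged as
#' fitness peaks.
#'
#' @param view a `genotype_fitness_view`.
#' @param table rate table or `NULL`.
#' @param K number of top genotypes to consider.
#' @param params a `population_params`.
#' @param genotypes optional genotype universe; defaults to all sense
#'   genotypes over the landscape alphabet (only feasible for small
#'   landscapes).
#' @param cache optional moments cache.
#' @return List with `n_peaks`, `networks`, `topk`.
#' @export
count_peaks_topk <- function(view, table, K, params, genotypes = NULL,
                             cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(genotypes)) {
    code <- view$code
    cs <- sense_codons(code)
    cs <- cs[code[cs] %in% attr(view$landscape, "alphabet")]
    genotypes <- enumerate_sense_genotypes(attr(view$landscape, "L"),
                                           code, codons = cs)
  }
  if (K > length(genotypes)) stop("K exceeds the genotype universe")
  ef <- vapply(genotypes, function(g)
    cached_moments(g, view, table, params$n, cache)$mean,
    numeric(1), USE.NAMES = FALSE)
  ord <- order(-ef, genotypes)
  topk <- genotypes[ord[seq_len(K)]]
  nets <- neutral_networks(topk, view, table, params, cache = cache)
  list(n_peaks = sum(vapply(nets, `[[`, logical(1), "is_peak")),
       networks = nets, topk = topk)
}

#' Classify an epistasis square
#'
#' Given condition-specific expected fitness at the four corners of a
#' genotype square (wild type, two single mutants, double mutant), the
#' interaction is additive when the deviation
#' `eps = f11 - f10 - f01 + f00` is within the drift-scale tolerance
#' `f00 / (4 Ne00)`; otherwise it is magnitude, simple sign or reciprocal
#' sign epistasis according to whether zero, one or both mutations change
#' effect class across backgrounds (classes from [classify_effect()] with
#' the resident corner's Ne).
#'
#' @param f00,f10,f01,f11 expected fitness at the corners.
#' @param Ne00,Ne10,Ne01 effective population size at the resident corner
#'   of each classified mutation (g00 for both single mutations, g10 and
#'   g01 for the background-swapped ones).
#' @return One of `"additive"`, `"magnitude"`, `"simple_sign"`,
#'   `"reciprocal_sign"`.
#' @export
classify_epistasis <- function(f00, f10, f01, f11, Ne00, Ne10, Ne01) {
  eps <- f11 - f10 - f01 + f00
  tol <- f00 / (4 * Ne00)
  if (abs(eps) < tol) return("additive")
  cls <- function(wt, mt, Ne) classify_effect(selection_coefficient(wt, mt), Ne)
  a_in_00 <- cls(f00, f10, Ne00)
  a_in_01 <- cls(f01, f11, Ne01)
  b_in_00 <- cls(f00, f01, Ne00)
  b_in_10 <- cls(f10, f11, Ne10)
  changed <- (a_in_00 != a_in_01) + (b_in_00 != b_in_10)
  switch(as.character(changed),
         "0" = "magnitude",
         "1" = "simple_sign",
         "2" = "reciprocal_sign")
}

#' Sample and classify epistasis squares
#'
#' Uniformly samples viable wild-type genotypes and two single-nucleotide
#' substitutions at distinct nucleotide positions (within or across
#' codons), evaluates the four corners' expected fitness under the
#' condition, and classifies each square.
#'
#' @param view a `genotype_fitness_view`.
#' @param table rate table or `NULL`.
#' @param count number of squares.
#' @param params a `population_params`.
#' @param seed RNG seed.
#' @return List with `squares` (data frame: corner genotypes, corner
#'   fitness, class) and `fractions` (named class fractions, summing
#'   to 1).
#' @export
sample_epistasis_squares <- function(view, table, count, params, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  g00s <- sample_sense_genotypes(view, 4L * count, seed)
  f <- encoded_fitness(view, g00s)
  g00s <- g00s[f > 0]
  if (length(g00s) < count) stop("too few viable genotypes sampled")
  g00s <- g00s[seq_len(count)]
  bases <- c("A", "C", "G", "T")
  len <- nchar(g00s[1])
  mut_at <- function(g, pos, base) {
    substr(g, pos, pos) <- base
    g
  }
  classes <- character(count)
  rows <- vector("list", count)
  for (i in seq_len(count)) {
    g00 <- g00s[i]
    pos <- sample.int(len, 2L)
    ch1 <- substr(g00, pos[1], pos[1]); ch2 <- substr(g00, pos[2], pos[2])
    b1 <- sample(setdiff(bases, ch1), 1L)
    b2 <- sample(setdiff(bases, ch2), 1L)
    g10 <- mut_at(g00, pos[1], b1)
    g01 <- mut_at(g00, pos[2], b2)
    g11 <- mut_at(g10, pos[2], b2)
    mm <- lapply(c(g00, g10, g01, g11), function(g)
      cached_moments(g, view, table, params$n, cache))
    fvals <- vapply(mm, `[[`, numeric(1), "mean")
    ne <- function(m) if (m$mean > 0)
      effective_population_size(params$N, m$mean, m$variance) else params$N
    classes[i] <- classify_epistasis(fvals[1], fvals[2], fvals[3], fvals[4],
                                     Ne00 = ne(mm[[1]]), Ne10 = ne(mm[[2]]),
                                     Ne01 = ne(mm[[3]]))
    rows[[i]] <- data.frame(g00 = g00, g10 = g10, g01 = g01, g11 = g11,
                            f00 = fvals[1], f10 = fvals[2], f01 = fvals[3],
                            f11 = fvals[4], class = classes[i],
                            stringsAsFactors = FALSE)
  }
  lv <- c("additive", "magnitude", "simple_sign", "reciprocal_sign")
  fractions <- prop.table(base::table(factor(classes, levels = lv)))
  list(squares = do.call(rbind, rows),
       fractions = stats::setNames(as.numeric(fractions), lv))
}
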