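# Independent brute-force oracles used across the suite. These
# deliberately avoid the package's branch-and-bound / graph machinery.

# Full enumeration of the variant distribution: every combination of the
# 20 amino acids at every codon, probabilities as plain products of the
# full per-codon probability rows. Feasible for L <= 3.
brute_variant_distribution <- function(genotype, table, prune_threshold = NULL) {
  codons <- mistrans::genotype_codons(genotype)
  rows <- lapply(codons, function(cd) table$prob[cd, ])
  aas <- colnames(table$prob)
  grid <- do.call(expand.grid,
                  c(rep(list(aas), length(codons)),
                    stringsAsFactors = FALSE))
  pep <- do.call(paste0, grid)
  pr <- rep(1, nrow(grid))
  for (i in seq_along(codons)) pr <- pr * rows[[i]][grid[[i]]]
  keep <- pr > 0
  pep <- pep[keep]; pr <- unname(pr[keep])
  encoded <- paste(table$code[codons], collapse = "")
  if (!is.null(prune_threshold)) {
    keep <- pr >= prune_threshold | pep == encoded
    pep <- pep[keep]; pr <- pr[keep]
    pr <- pr / sum(pr)
  }
  ord <- order(pep)
  list(peptide = pep[ord], prob = pr[ord], encoded = encoded)
}

# Monte Carlo oracle for the fitness moments: draw the multinomial count
# vector explicitly and average per-protein fitness contributions.
# Drawn in chunks so the count matrix (categories x draws) stays small.
mc_fitness_moments <- function(dist, view, n, draws = 1e5, seed = 1,
                               chunk = 2e4) {
  set.seed(seed)
  f <- mistrans::peptide_fitness(view$landscape, dist$peptide)
  total <- 0; total_sq <- 0; done <- 0
  while (done < draws) {
    m <- min(chunk, draws - done)
    counts <- stats::rmultinom(m, size = n, prob = dist$prob)
    cell_fitness <- colSums(counts * f) / n
    total <- total + sum(cell_fitness)
    total_sq <- total_sq + sum(cell_fitness^2)
    done <- done + m
  }
  mean_f <- total / draws
  var_f <- (total_sq - draws * mean_f^2) / (draws - 1)
  list(mean = mean_f, variance = var_f,
       se_mean = sqrt(var_f / draws))
}

# Brute-force fitness-peak counter: flood-fill nearly-neutral components
# with direct pairwise tests, then check every member's outside
# neighbors. No igraph, no ranking machinery.
brute_count_peaks <- function(genotypes, view, table, params) {
  moments <- lapply(genotypes, mistrans::genotype_moments, view = view,
                    table = table, n = params$n)
  names(moments) <- genotypes
  ne <- function(m) params$N / (1 + m$variance / m$mean^2)
  neutral_pair <- function(a, b) {
    ma <- moments[[a]]; mb <- moments[[b]]
    if (ma$mean <= 0 || mb$mean <= 0) return(FALSE)
    abs(mb$mean / ma$mean - 1) < 1 / (4 * ne(ma)) &&
      abs(ma$mean / mb$mean - 1) < 1 / (4 * ne(mb))
  }
  unvisited <- stats::setNames(rep(TRUE, length(genotypes)), genotypes)
  n_peaks <- 0L
  for (g in genotypes) {
    if (!unvisited[[g]]) next
    comp <- character(0)
    queue <- g
    unvisited[[g]] <- FALSE
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      for (nb in mistrans::single_nucleotide_neighbors(cur)) {
        if (nb %in% names(unvisited) && isTRUE(unvisited[[nb]]) &&
            neutral_pair(cur, nb)) {
          unvisited[[nb]] <- FALSE
          queue <- c(queue, nb)
        }
      }
    }
    is_peak <- TRUE
    for (a in comp) {
      ma <- moments[[a]]
      if (ma$mean <= 0) { is_peak <- FALSE; break }
      thr <- 1 / (4 * ne(ma))
      for (nb in mistrans::single_nucleotide_neighbors(a)) {
        if (nb %in% comp) next
        mnb <- if (!is.null(moments[[nb]])) moments[[nb]] else
          mistrans::genotype_moments(nb, view, table, params$n)
        s <- if (ma$mean == 0) 0 else mnb$mean / ma$mean - 1
        if (!(s < 0 && abs(s) >= thr)) { is_peak <- FALSE; break }
      }
      if (!is_peak) break
    }
    if (is_peak) n_peaks <- n_peaks + 1L
  }
  n_peaks
}

# Rate table with every error rate scaled by a constant factor.
scale_rate_table <- function(table, factor) {
  code <- table$code
  idx <- which(table$prob > 0, arr.ind = TRUE)
  codon <- rownames(table$prob)[idx[, 1]]
  aa <- colnames(table$prob)[idx[, 2]]
  keep <- code[codon] != aa
  mistrans::mistranslation_table(
    data.frame(codon = codon[keep], amino_acid = aa[keep],
               rate = table$prob[idx][keep] * factor,
               stringsAsFactors = FALSE),
    code = code)
}

# Small shared fixtures, built once per test run.
fixture_env <- new.env(parent = emptyenv())
get_fixture <- function(name) {
  key <- gsub("-", "_", name)
  hit <- get0(key, envir = fixture_env, inherits = FALSE)
  if (is.null(hit)) {
    hit <- mistrans::make_fixture(name)
    assign(key, hit, envir = fixture_env)
  }
  hit
}
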