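---
title: "Modeling mistranslation on protein adaptive landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mistranslation on protein adaptive landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mistrans)
```

## The model

Ribosomes misincorporate amino acids at rates of roughly $10^{-5}$ to
$10^{-2}$ per codon, so a cell expressing a single protein-coding
sequence actually produces a cloud of protein variants. These
*phenotypic mutations* are not heritable, but they change both the mean
and the between-cell variance of fitness, and through them the course of
adaptive evolution. This package implements that model end to end and
studies its consequences on combinatorially complete peptide fitness
landscapes.

**Genotypes and landscapes.** A genotype is a nucleotide sequence of
length $3L$; its encoded peptide is obtained codon-wise under the
standard genetic code. Fitness is defined at the peptide level: a
`peptide_landscape` maps every length-$L$ peptide over its alphabet to a
nonnegative fitness (a binding-affinity proxy or a growth rate,
depending on the assay being emulated). A genotype containing a stop
codon encodes no full-length protein and has fitness 0. Such genotypes
remain members of genotype space — mutation can propose them — and are
eliminated by selection, not by fiat. "Viable" means encoded fitness
strictly positive.

**The variant distribution.** Each codon $i$ is translated into amino
acid $a$ with probability $P(a \mid c_i)$, where the 19 noncognate
probabilities come from a per-codon error-rate table and the cognate
probability is one minus their sum. Errors at different codons are
independent, so a variant peptide $v$ is produced with probability
$q_v = \prod_i P(v_i \mid c_i)$. Variants with $q_v < 10^{-9}$ are
pruned (the encoded peptide is always kept) and the retained mass is
renormalized to 1. Renormalization — rather than assigning the lost mass
to the encoded variant — keeps the distribution proper; at realistic
rates the pruned mass is below $10^{-5}$ and the choice is verified
against a full-enumeration oracle in the tests. The enumeration itself
is branch-and-bound over per-codon substitutions with an exact
remaining-product bound, so the $20^L$ candidate set is never
materialized.

**Fitness moments.** A cell produces $n$ protein copies, drawn
independently from the variant distribution (a multinomial with $n$
trials); each copy contributes equally and independently to fitness and
the cell's fitness is the average contribution $f_v$ looked up in the
landscape. Hence

$$E(f) = \sum_v q_v f_v, \qquad
  \mathrm{Var}(f) = \frac{\sum_v q_v f_v^2 - E(f)^2}{n}.$$

The mean is independent of $n$; the variance scales exactly as $1/n$,
which is why low expression (few copies per cell) amplifies the
consequences of mistranslation. Only these two moments are needed
downstream; the multinomial count vector is never materialized.

**Selection, drift, fixation.** For a resident (wild-type) genotype and
a single-nucleotide mutant,

$$s = \frac{E(f_{mt})}{E(f_{wt})} - 1, \qquad
  N_e = \frac{N}{1 + \mathrm{Var}(f_{wt})/E(f_{wt})^2}, \qquad
  u_{fix} = \frac{1 - e^{-2 N_e s p}}{1 - e^{-2 N_e s}},\; p = \tfrac1N.$$

$N_e$ uses the *resident's* moments only: nongenetic fitness variance
weakens selection in the resident population, which is what the
$1/(1+\mathrm{CV}^2)$ correction captures. The initial frequency is
$1/N$ (set by the census size, not by $N_e$). A mutation is *nearly
neutral* when $|s| < 1/(4 N_e)$ — with the $N_e$ of the condition under
analysis, so the same $|s|$ can be invisible to selection without
mistranslation and selected with it. Without a rate table the pipeline
uses encoded fitness with zero variance; synonymous mutations are then
exactly neutral.

**Adaptive walks.** Evolution is simulated in the weak mutation–strong
selection (origin-fixation) regime: one of the $9L$ single-nucleotide
neighbors is proposed uniformly at random, fixed with probability
$u_{fix}$ in a single Bernoulli trial, and on fixation becomes the new
resident. The attempt index (fixed and lost mutations both count) is the
proxy for evolutionary time. Stop-creating proposals are lethal
($s = -1$, $u_{fix} \approx 0$); a resident with zero expected fitness
aborts the walk with an error rather than dividing by zero silently.

## Numerical choices

* $u_{fix}$ is evaluated as `expm1(-2*Ne*s/N) / expm1(-2*Ne*s)`, which
  is accurate through the neutral limit; $|2 N_e s| < 10^{-12}$ returns
  $1/N$ exactly, and strongly deleterious values are computed in log
  space to avoid overflow. The result is clamped to $[0, 1]$.
* Moments are memoized per genotype in an environment keyed by the
  (condition, expression level); the walk additionally precomputes the
  fixation probabilities of all $9L$ neighbors once per resident, which
  makes an attempt O(1). Both are correctness-neutral performance
  contracts, exercised by the reproducibility tests.
* Nearly-neutral network edges require neutrality in *both* directions
  ($s$ is not symmetric under Eq. 1's ratio form), which makes the
  networks well-defined undirected components. Peak status requires
  every outside neighbor of every member to be classified deleterious
  against its adjacent member; a merely nearly-neutral outside neighbor
  vetoes the peak.
* Top-$K$ ranking for peak counting breaks ties lexicographically, so
  results are deterministic.
* Epistasis squares are classified on raw (not log) fitness, because the
  landscapes contain exact zeros; the additivity tolerance is tied to
  the drift scale, $|\epsilon| < E(f_{00})/(4 N_e^{00})$, so
  "additive" means "indistinguishable from additive at the population
  size under study". Squares are sampled at two distinct nucleotide
  positions, within or across codons.
* Seeds: every stochastic entry point takes an explicit seed; replicate
  $r$ of a walk runs under `seed + r`, so any replicate can be
  reproduced in isolation and paired-seed comparisons across conditions
  share their proposal streams until the first divergent fixation.

## The synthetic study system

The empirical landscapes this model was designed around (a
combinatorially complete antibody-binding landscape of ~160,000 protein
variants and two toxin–antitoxin growth-rate landscapes of ~8,000
variants, combined with mass-spectrometry mistranslation rates) are
external datasets; the package ships generators that reproduce their
statistical structure instead.

`generate_landscape()` is a Rough-Mount-Fuji-style generator: additive
per-site effects plus independent epistatic noise, with the
noise-to-additive ratio as the single ruggedness knob. Rough Mount Fuji
was chosen over NK because one knob interpolates smoothly from easily
navigable to rugged, matching the contrast between toxin–antitoxin and
antibody-binding landscapes. Inviability is imposed by thresholding the
raw scores at the `lethal_fraction` quantile (default 0.2), which
preserves the neighbor-fitness correlation near the viability boundary;
scores are then scaled to a maximum of 1 and a power transform sets the
viable mean to `target_mean` (default 0.08, the skew typical of large
binding landscapes).

`generate_rate_table()` draws per-(codon, target) error rates
log-normally around a codon-level random effect (defaults:
$10^{-3.5}$ center, 0.5 decades within-codon spread, 0.5 decades
codon-to-codon heterogeneity), clamped to $[10^{-5}, 10^{-2}]$ — the
experimentally observed span. The codon random effect is what gives
synonymous codons different error rates, the raw material for selection
on synonymous sites.

What the generator does **not** emulate: the amino-acid-specific error
spectrum of real ribosomes (near-cognate codons err more, and toward
specific residues), correlations between a codon's error rate and its
usage, misreading to stop codons, and any structure-mediated buffering
(chaperones, degradation, aggregation). Passing tests on synthetic data
therefore demonstrate that the *machinery* is correct and that the
qualitative phenomena are generic consequences of the model's
assumptions — not that effect sizes match any particular organism.

## Problem sizes

The analyses and tests run on an $L = 2$, full-alphabet system: 400
peptides, 3721 sense genotypes — large enough for heterogeneous
neighborhoods and codon-level structure, small enough that expected
fitness can be computed for every genotype. The test fixtures go smaller
(reduced alphabets, $L \le 3$) so that brute-force enumeration oracles
cover every code path. Walks in the shipped analyses use 40–100
replicates of 2,000–3,000 attempts at $N = 10^8$ and high expression
(500 proteins per cell, a typical bacterial median); these are the
package's desk-scale defaults, chosen so a full pipeline run completes
in seconds while leaving every per-walk statistic well resolved. The
full-scale protocol of the original studies ($10^4$ replicates of
$10^5$ attempts on the empirical landscapes) is reachable through the
same `walk_config()` interface.

## Worked example

```{r example}
ls2 <- generate_landscape(L = 2, alphabet_size = 20, epistatic_sd = 0.8,
                          lethal_fraction = 0.2, target_mean = 0.08,
                          seed = 1L)
tab <- generate_rate_table(seed = 1L)
view <- genotype_fitness_view(ls2)

# one genotype's variant cloud and moments at low expression
g <- sample_sense_genotypes(view, 1, seed = 1)
variant_distribution(g, tab)
genotype_moments(g, view, tab, n = 1L)

# the flattening slope over a genotype sample
genos <- sample_sense_genotypes(view, 500, seed = 2)
genos <- genos[encoded_fitness(view, genos) > 0]
flattening_fit(genos, view, tab)$slope
```

## Known limitations

* Fitness is taken from the landscape file as-is; comparing walk
  outcomes across landscapes is only meaningful as a percentage of each
  landscape's maximum.
* The per-protein independence assumption ignores autocatalytic or
  dominant-negative variant effects; $\mathrm{Var}(f)$ would otherwise
  not scale as $1/n$.
* Only single-nucleotide substitutions are modeled — no indels,
  multi-nucleotide mutations, or misreading-to-stop.
* The origin-fixation regime excludes clonal interference; at very high
  $N\mu$ the walk picture breaks down.
* Post hoc rate trajectories are reported against a sampled
  landscape-mean rate; with small reference samples that normalization
  carries Monte Carlo error of its own.
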