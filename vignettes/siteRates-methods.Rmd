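---
title: "Methods: simulating and comparing site-specific evolutionary rates"
author: "siteRates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing site-specific evolutionary rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteRates)
```

# Overview

`siteRates` studies the relationship between two measures of site-specific
evolutionary rate in protein-coding genes: codon-level dN/dS and
amino-acid-level relative rates (conservation scores of the Rate4Site
kind). Both decompose the divergence accumulated at site $k$ along branch
$i$ as a product $r_k t_i$ of a site factor and a branch factor; they
differ in input data (codons vs. residues) and in how the free scale
constant is pinned down (dividing by the synonymous rate vs. normalizing
the scores). The package provides the full loop: simulate alignments with
known per-site rates, infer rates back with both frameworks on the true
tree, and quantify agreement per replicate and per grid cell.

# Substitution models

## Site-specific dN/dS (Muse–Gaut style)

A site with rates $(d_N, d_S)$ evolves on the 61 sense codons of the
universal code. Codons differing at one nucleotide exchange at rate
$d_S\,\pi_j$ (synonymous) or $d_N\,\pi_j$ (nonsynonymous), where $\pi_j$
is the equilibrium frequency of the target codon; multi-nucleotide changes
have rate zero. Frequencies default to uniform over the 61 sense codons,
the least-structured choice, which keeps the dN/dS interpretation exact
and makes the process symmetric.

A note on the target factor: the classical Muse–Gaut parameterization uses
the frequency of the target *nucleotide*. With stop codons excluded, the
positional nucleotide marginals of a uniform codon distribution are not
themselves uniform, so that convention would break the clean
uniform-frequencies symmetry (equal neighbor rates, uniform stationary
vector). We therefore use the target *codon* frequency, which is exactly
reversible for arbitrary frequency vectors and coincides with the
nucleotide convention under the package-default uniform frequencies up to
a global constant.

## Matrix scaling

All codon matrices are multiplied by one constant per model family —
shared by every site of an alignment — chosen so that a *neutral* site
($d_N = d_S = 1$, or all fitnesses equal) experiences one expected
substitution per codon site per unit branch length. Branch lengths
therefore read as neutral divergence, and the ratio of any two sites'
rates is preserved exactly. We deliberately do **not** rescale each site's
matrix to unit mean rate: doing so would equalize total rates across sites
and erase the between-site rate variation that is the object of study.
Users analyzing empirical data who prefer mean-rate-one scaling can
rescale branch lengths; the mean-1 score normalization absorbs any global
constant.

## Mutation–selection (Halpern–Bruno)

A site is described by a codon fitness vector $f$ (log scale, defined up
to an additive constant). Neighbor codons exchange at the mutation rate
times the relative fixation probability
$$q_{ij} = \mu_{ij} \frac{S_{ij}}{1 - e^{-S_{ij}}}, \qquad
  S_{ij} = f_j - f_i,$$
with the fixation factor set to its limit 1 whenever $|S| < 10^{-8}$ (a
removable singularity; the expression is otherwise stable in double
precision). The mutation process is an HKY-style nucleotide matrix
(`mutationMatrix()`), reversible by construction; the stationary codon
distribution is then proportional to the mutation-stationary weights times
$e^f$, and detailed balance holds. The expected dN/dS of a site is its
stationary nonsynonymous flux divided by the same flux with all fixation
factors set to 1 under the neutral stationary distribution; it equals 1
exactly for a flat fitness landscape and is invariant to additive shifts
of $f$.

# The synthetic-data generator

`drawProfiles()` implements five regimes; their defaults *are* the study
conditions and are not meant to be tuned per run:

| regime | per-site rates |
|---|---|
| `constant_dS` | $d_S = 1$, $d_N \sim U(0.1, 1.6)$ |
| `variable_dS` | $d_N/d_S \sim U(0.1, 1.6)$, $d_S \sim U(0.5, 2)$, $d_N = d_S \cdot (d_N/d_S)$ |
| `gamma` | $d_N/d_S \sim \Gamma(\alpha = 0.312,\ \beta = 1.027)$, $d_S = 1$ |
| `mutsel_neutral_syn` | Dirichlet(0.5) amino-acid targets → codon fitnesses; synonymous codons equal |
| `mutsel_codon_bias` | as above plus independent $N(0, 0.5)$ per-codon fitness offsets |

The gamma defaults are the HIV-1 integrase estimates; other $(\alpha,
\beta)$ pairs are plain parameters. For the mutation–selection regimes the
exact fitness distributions of the original alignments are not published
in reusable form, so the generator reproduces their statistical character
— a broad spread of per-site expected dN/dS under unequal nucleotide
frequencies (0.32/0.18/0.18/0.32) — rather than point values; conclusions
drawn from those regimes are about trends, not magnitudes.

Trees are complete balanced binary trees (`makeBalancedTree()`): $n$
leaves (a power of two), every edge — including the two root edges — of
length $b$, so every adjacent node pair is separated by the same
divergence and the $n = 2$ cherry spans $2b$. The standard grid crosses
$b \in \{0.0025, 0.01, 0.04, 0.16, 0.64\}$ with $n \in \{16, \dots,
2048\}$ (40 trees); the uniform-rate design uses $n \in \{128, \dots,
2048\}$ with 50 replicates and both dS regimes (2,500 alignments).

`evolveAlignment()` draws the root codon of each site from its stationary
distribution and each child state from $e^{Qt}$ along every edge,
independently across sites. Sites are independent, rates do not change
over time, and there are no indels — deliberate simplifications matching
the simulation design. What passing tests on these data do *not* show:
robustness to alignment error, indels, rate variation along the tree,
epistasis between sites, or misspecified trees; empirical alignments have
all of these.

Reproducibility: every replicate's seed derives from the master seed and
the cell/replicate counters (`gridRegistry()` lists them), so a
configuration regenerates byte-identical files. One caveat we accepted by
design: simulation noise is attached to stream *positions*, so permuting
the order of the site profiles does not permute the realized columns —
that identity cannot hold for any scheme in which randomness is
independent of the inputs. Per-site independence is instead verified
distributionally in the test suite.

# Rate inference

## FEL1 (codon level)

`fel1Fit()` fixes $d_S = 1$ at all sites, takes the tree and its branch
lengths as given (the protocol passes the true tree to inference), and
maximizes each site's pruning likelihood over $d_N \in [0, 10]$. A single
global scale is unidentifiable from ratios, so anchoring $d_S$ makes
$d_N$ the ratio directly; the upper bound 10 sits an order of magnitude
above the largest simulated ratio (1.6) and boundary hits are flagged in
the diagnostics, not truncated away silently. After fitting, the
invariant-site rule sets the score to exactly 0 at every site whose
*translated* column shows a single residue (synonymous-only variation
included): under a shared nonzero synonymous rate, a fully conserved site
is evidence of $d_N = 0$, whereas an unconstrained fit would return an
arbitrary value from a flat likelihood.

Optimization is a 48-point geometric grid on $[10^{-4}, 10]$ evaluated
with site-vectorized pruning (each candidate costs one pass over all
variable columns), followed by a 9-point local geometric grid around each
site's bracket — vectorized by grouping sites that share a bracket — and
a final parabolic interpolation in $\log d_N$. This replaces a per-site
golden-section loop, which computes the same maximum to comparable
precision (~0.5% in $d_N$, far below sampling noise) at roughly a tenth
of the cost in R, because every likelihood evaluation stays vectorized
across sites. Grid-first search also avoids the local traps of
hill-climbing on likelihoods that are nearly flat close to $d_N = 0$.

## Amino-acid relative rates

`aaRates()` is an empirical-Bayes gamma-categories method: site
likelihoods are computed under $e^{rQ_{aa}t}$ at $K = 16$
equal-probability gamma quantile-midpoint rates (rescaled to prior mean
1), the gamma shape is fitted by maximizing the summed column
log-likelihoods over $[0.05, 20]$, and each site's score is its posterior
mean rate — strictly positive, reported raw and usually renormalized to
mean 1. The replacement matrix defaults to JTT with LG and WAG
selectable; exchangeabilities come from phangorn's model tables. $K = 16$
and JTT are the conventional defaults of this method family; the choice
is exposed, not hidden.

Branch lengths are again taken as given. They are in *codon* divergence
units while the replacement process has unit mean rate, so there is a
global scale mismatch; the fitted shape and the mean-1 normalization
absorb it (only the product $r t$ enters the likelihood — an invariance
the test suite checks directly). One implementation note: the
per-category likelihood depends on the shape only through the category
rates, so the shape fit interpolates site log-likelihoods precomputed on
a fixed 33-point rate grid (log-dense where curvature lives, coarse in
the low-rate tail where log-likelihood is asymptotically linear in
$\log r$), and only the final posterior uses exact evaluations at the
fitted category rates. This cuts the pruning passes per alignment about
five-fold without changing the estimator.

Gaps and `X` are treated as missing observations (partial likelihood of
ones) — the standard convention, relevant only for user-supplied
empirical alignments since simulated data are gapless.

# Comparison statistics

Scores of different kinds are made comparable by dividing by their mean
(`normalizeScores(, "mean1")`); `scoreRMSD()` refuses inputs that are not
mean-normalized rather than silently comparing incommensurable scales.
`correlateScores()` computes Spearman or Pearson coefficients;
`runStudy()` records both per replicate, and `aggregateComparisons()`
returns mean ± standard error per grid cell, dropping (and counting)
undefined replicate values.

On the choice of headline statistic: rank correlation is attractive
because it ignores the two score kinds' different normalizations, but the
simulation-grid agreement bounds in the acceptance suite are asserted on
the product-moment coefficient, with the rank coefficient reported
alongside. Two reasons. First, the reference analyses single out Spearman
explicitly only for empirical datasets, implying the simulation figures
used Pearson. Second, the two statistics respond differently to the
structure of low-divergence data: at the least-diverged cell (branch
length 0.0025, 128 taxa) most sites are invariant — FEL1 assigns them an
exact tie at 0 while the amino-acid scores spread them slightly by
residue composition — and these tie-block artifacts depress rank
correlation (to almost exactly 0.80 in our measurements) while the
product-moment coefficient, dominated by the variable sites, stays near
0.95. Both numbers are computed by the same test.

# Problem sizes and runtime choices

The full published-scale grid (up to 2,048 taxa × 50 replicates) is
expressible through `gridConfig()` but is not the default anywhere: the
package's own test and acceptance runs use 100-site alignments with 5
replicates per cell at 128–512 taxa, sizes at which every headline
comparison is stable (standard errors of a few hundredths) and a full
suite completes in minutes on one CPU. Pruning is vectorized across
sites; balanced trees have a single edge length, so each candidate rate
costs one spectral decomposition regardless of tree size. Identical site
models are detected exactly (hash plus `identical()` confirmation) and
share decompositions and sampling tables.

# Degenerate inputs and numerical guards

* Transition probabilities come from the symmetrized eigendecomposition
  of reversible generators; tiny negative entries are clipped and rows
  renormalized.
* Pruning rescales partial likelihoods at every internal node, so columns
  never underflow even at 2,048 taxa; a non-finite partial aborts with
  the offending edge.
* `stationaryDistribution()` verifies the residual ($\|vQ\|_\infty \le
  10^{-10}$ relative) and rejects reducible matrices (multiple near-zero
  eigenvalues) rather than returning one of many stationary vectors.
* Zero-variance score vectors make correlations undefined: reported as
  `NA` with a warning, then dropped and counted during aggregation.
  All-zero score vectors (a fully conserved alignment) cannot be
  mean-normalized and are rejected with a diagnostic.
* `makeBalancedTree()` rejects non-power-of-two taxon counts and
  nonpositive branch lengths; readers reject ragged alignments, stop
  codons, and malformed Newick with the failure position.

# Known limitations

* The FEL1 search floor ($d_N = 10^{-4}$) means a variable site can never
  receive a score of exactly 0; only the invariant-site rule produces
  hard zeros. This mirrors the behavior of likelihood tools with bounded
  optimizers.
* The amino-acid model is time-reversible and stationary; lineage-specific
  composition shifts are outside scope.
* Mutation–selection simulations here use Dirichlet-generated fitness
  profiles, not the original studies' parameter files; quantitative
  MutSel agreement levels should be read as representative patterns.
* No significance machinery (tests for dN/dS > 1, per-site confidence
  intervals) is provided; the package measures agreement between point
  scores.
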