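---
title: "Detecting community nestedness along an environmental gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting community nestedness along an environmental gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nestgrad` asks a simple ecological question of community survey data:
are the communities of harsh habitats subsets of the communities of
milder habitats? The motivating system is arbuscular mycorrhizal (AM)
fungi along a soil-pH gradient, where the hypothesis takes a concrete
form: fungi that tolerate strongly acidic soil are not acid specialists
but **pH generalists**, so low-pH communities should be nested inside
high-pH communities, and a phylotype's pH range should widen as its lower
tolerance limit drops. This vignette explains the statistical machinery,
the choices behind it, and what the package's synthetic data can and
cannot tell you about real surveys.

## From samples to matrices

The raw input is one row per sample-by-phylotype occurrence (sample id,
site/treatment, sample soil pH, phylotype, optional clone count). pH is
stored and compared as a plain real number throughout; although pH is a
logarithmic quantity, the analyses treat it as an ordinary covariate.

Pooling counts, for each phylotype and site, the number of distinct
samples containing the phylotype. These pooled *frequencies* are the
quantitative ("abundance") data. Because sites contribute unequal sample
numbers, frequencies are normalized to percentage relative abundance
(100 × count / site sample number) before any cross-site quantitative
comparison; binarizing instead yields the presence/absence matrix.
All-zero rows or columns produced by pooling subsets of samples are
dropped with a message rather than raising an error.

Ordering is hypothesis-driven, not data-driven: columns are sorted by the
site's gradient value (mean pH over its samples; descending, so the
richest/neutral site is leftmost) and rows by phylotype occurrence (total
samples occupied). The mean is used as the per-site pH summary; a mode or
any other per-column value can be supplied as the gradient instead, since
the sort consumes whatever `col_gradient` carries. Both sorts need
deterministic tie-breaks to make indices reproducible: ties fall back to
the marginal total (descending), then the label. Composite layouts that a
single sort cannot express — e.g. a combined glasshouse matrix with the
neutral-soil block left and the acidic-soil block right, each sorted by
pH — are built with `arrange_columns()`.

## NODF and weighted NODF under an imposed order

For one ordered pair of columns, with the earlier (left) column as the
nesting reference, the paired NODF term is zero unless the right column's
fill is *strictly* smaller than the left's, and otherwise equals the
percentage of the right column's presences shared with the left. The
index is the mean over all ordered pairs along the chosen axis (columns,
rows, or both pooled). Because the order is imposed by the gradient
hypothesis rather than by marginal totals, the index specifically
measures nestedness *along the gradient*; the classic marginal-total
ordering remains available (`ordering = "by_marginal_total"`), and with
it the index is invariant to any input permutation (ties contribute zero
either way).

The weighted variant replaces the fill condition with a strict decrease
of the marginal total and counts the fraction of the lighter vector's
nonzero cells that are strictly smaller than their counterparts — tied
positive cells are not nested. Row-wise weighted NODF therefore asks
whether commoner phylotypes dominate rarer ones *consistently across
sites*; a strong deficit relative to its null signals dominance turnover
("anti-nestedness") even when incidence is nested.

## Null models and significance

Significance is judged against 1000 randomized matrices that preserve
both row and column totals — margins carry most of the gradient signal,
so the test isolates structure beyond richness and occurrence.

* **Presence/absence:** the curveball algorithm (random trades of the
  non-shared elements of two rows) run as a Markov chain from the
  observed matrix, with a burn-in of 5 × max(rows, columns) accepted
  trades and 10 accepted trades between samples; the classic checkerboard
  swap is available for cross-checking. A matrix admitting no
  perturbation (e.g. a full or perfectly chained matrix) has a singleton
  ensemble; the sampler then returns copies with a warning and the test
  reports an undefined Z with p-values of 1.
* **Quantitative matrices:** the both-margins-fixed constraint extends
  naturally to counts as uniform random contingency tables with the
  observed margins (Patefield's algorithm). When the analyzed matrix is a
  column-rescaled transform of counts (percentage relative abundance),
  draws are taken on the counts and rescaled identically. Two
  alternatives are provided: `skeleton_shuffle` (fixed-fixed
  randomization of the binary skeleton, observed positive values
  scattered uniformly over occupied cells) and
  `cell_permute_within_rows`. The margins-fixed scheme is the default
  because it is the direct quantitative analogue of the binary
  constraint; the skeleton scheme preserves the value multiset instead of
  the margins and yields a much less structured null, which compresses
  |Z| by an order of magnitude on dominance-turnover data.

Null indices are computed under the same imposed row/column order as the
observed matrix (margins are preserved, so the order remains meaningful).
Monte-Carlo p-values use the add-one correction
`(count + 1) / (n_null + 1)`, so p is never zero and never smaller than
`1/(n_null + 1)`; `Z = (obs − mean)/SD` is reported alongside. A
significant positive Z is nestedness; a significant negative Z is
anti-nestedness.

## S-D-R simplex

Each unordered site pair decomposes into similarity, richness/abundance
difference, and replacement: binary `S = a/n`, `D = |b−c|/n`,
`R = 2·min(b,c)/n` with `n = a+b+c`; abundance mode substitutes
`A = Σ min`, `B`, `C` (the directed abundance surpluses), making `S` the
Ruzicka index and reducing exactly to the binary form on 0/1 data. The
matrix-level summary reports the unweighted mean over pairs of the
percentage contributions of turnover (1−S), agreement (1−D) and
nestedness (1−R); since the three complements sum to 2 per pair, the
three percentages sum to 200. A totals-weighted alternative (components
pooled over pairs before relativizing) sits behind
`aggregate = "pooled"`; the unweighted mean is the default because each
site pair is one observation of the gradient contrast, regardless of how
many taxa it involves. Degenerate pairs (empty union) are excluded with a
message rather than imputed.

## Rarefaction and the sufficiency criterion

Expected richness and its variance in a subsample of `n` clones follow
the hypergeometric formulation; binomial coefficients are evaluated in
log space so clone totals in the thousands do not overflow. The
sequencing-sufficiency rule — increase sequencing until the 95% CI of
rarefied richness is within ±0.4 phylotype — needs an evaluation point:
at `n = N` the variance is identically zero, so the package evaluates the
half-width at the penultimate point `n = N − 1` by default, with a
fixed-fraction alternative (`at = "fraction"`). The criterion is
therefore conservative near saturation and should be read as "the curve
has flattened", not as an estimate of undetected richness.

## PERMANOVA, Mantel, generality

One-way PERMANOVA partitions the squared Jaccard dissimilarities among
and within groups and permutes group labels; two-way PERMANOVA handles
the balanced crossed glasshouse design (pH × inoculum) through the
Gower-centered inner-product matrix and hat-matrix traces, with
unrestricted permutation of units for all terms — the conventional
default when no exchangeability structure is imposed. Unbalanced crossed
designs are rejected rather than approximated. Both tests, and the Mantel
test of community dissimilarity against gradient distance, support exact
enumeration of all permutations for small unit counts (≤ 8), in which
case the p-value is the exact proportion including the identity;
otherwise sampled permutations use the add-one correction.

Generality profiles summarize, per phylotype, the pH of its occupied
samples: the minimum (observed acid tolerance) and the SD (realized pH
range width). Only phylotypes occupying ≥ 3 samples enter the Pearson
correlation of SD against minimum pH, whose p-value comes from the t
distribution with n − 2 degrees of freedom. A significantly negative
correlation is the generalist signature.

## The synthetic generator

The generator emulates the study conditions end to end: six sites with
mean pH evenly spaced over 3.2–7.2, twelve samples per site with
within-site pH spread of SD 0.4 pH units (field sites show ranges of one
to two units), and fifty phylotypes whose lower tolerance limit `L` is
uniform on 3.0–7.0. Occupancy is hierarchical:

1. **Establishment** — phylotype × site Bernoulli with probability
   `max(1 − 0.2·(L − 3), 0.2)`: the most acid-tolerant phylotypes
   establish wherever they tolerate the pH (the ruderal, generalist end
   of the continuum), acid-sensitive phylotypes are patchy. This is what
   gives the pooled incidence matrix nestedness *beyond its margins*; a
   purely sample-level thinning saturates site presence and leaves the
   fixed-fixed ensemble nearly degenerate.
2. **Sample occupancy** — within established sites, each sample at or
   above `L` is occupied with probability `p_occ = 0.6` (regimes:
   `nested` — open upper range, acid-tolerant ⇒ generalist; `turnover` —
   a 1.5-unit window above `L`; `random` — pH ignored).
3. **Clone sampling** — 25 clones per sample allocated multinomially
   among the phylotypes present; with `dominance_shift` the weights are
   Gaussian around a per-phylotype abundance optimum placed 0.5 units
   above its tolerance limit (width 1.0), so acid-tolerant generalists
   dominate near their limit and are outcompeted at high pH. This
   produces the study signature: nested incidence with anti-nested
   abundance. A sample left empty receives its most acid-tolerant
   eligible phylotype, so every sequenced sample is non-empty.

Truth (limits, optima, establishment probabilities, sample pH) is always
returned beside the data, and everything is deterministic given the
seed. A companion generator emulates the glasshouse design — two inocula
(the acidic-soil pool restricted to `L ≤ 4`) × three medium pH levels
(3.4, 4.0, 5.5) × five pots — with the same tolerance-dependent
establishment at the treatment level.

What the generator does **not** emulate: sequencing error and chimeras,
phylotype-calling uncertainty, spatial autocorrelation within sites,
year-to-year variation, host-plant effects, and soil covariates
correlated with pH. Passing recovery tests therefore show that the
pipeline detects the hypothesized structure at realistic effect sizes —
not that real surveys are free of these confounders.

Two calibration facts are worth stating plainly. First, at these
study-scale conditions the site-pooled incidence matrix is strongly
constrained by its margins, so column-wise NODF Z values concentrate
around 1.5–2.5 and a single survey-sized dataset yields a significant
incidence test in only roughly half to three-quarters of replicates —
the incidence signal is intrinsically marginal at this design size.
Second, the abundance signal is not: with dominance turnover on, the
row-wise weighted NODF Z against the margins-fixed null is on the order
of −10 to −16 and essentially always significant.

## Numerical and testing choices

Indices are exact rational arithmetic in double precision; the test suite
pins them to brute-force pairwise enumeration on a thousand random
matrices up to 6 × 6, rarefaction to complete subsample enumeration for
all compositions with N ≤ 8, and exact permutation p-values to full
enumeration on six units. Type-I error of the three permutation tests is
checked on 200 null simulations at 99 permutations each; the curveball
sampler's uniformity is checked against the fully enumerated 4 × 4
ensemble with margins (2,2,1,1)/(2,2,1,1) at 10⁴ thinned draws. Recovery
runs use 20 replicates at 199 null draws. These sizes were chosen to make
the suite a routine desk-scale run while keeping every Monte-Carlo
tolerance interpretable.

## Limitations

* The hypothesis-imposed ordering makes the indices directional: a wrong
  gradient hypothesis gives an uninterpretable index, not an error.
* The quantitative null question has no canonical answer; Z magnitudes
  (not signs) for weighted indices depend on the chosen scheme, which is
  why the scheme is recorded in every result object.
* Exact permutation enumeration is limited to 8 units; beyond that,
  p-values are Monte-carlo estimates with resolution `1/(n_perm + 1)`.
* The penultimate-point sufficiency criterion is a convention; published
  half-widths evaluated at unstated points are not comparable to it to
  the second decimal.
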