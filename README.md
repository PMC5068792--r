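# nestgrad

Nestedness of microbial communities along environmental gradients.

Communities in harsh habitats are often *subsets* of the communities found
in milder habitats — the harsh-habitat species are not specialists of the
stressful end of the gradient but generalists that occur across it.
`nestgrad` implements the statistical pipeline for testing this hypothesis
on community survey data, built around the motivating case of arbuscular
mycorrhizal (AM) fungal phylotypes in *Miscanthus sinensis* rhizosphere
soil along a soil-pH gradient (strongly acidic quarry soils to neutral
dune sand). It is intended for community ecologists working with
sample-by-taxon occurrence records pooled into site-by-taxon frequency
matrices.

## What it computes

**Nestedness indices under a hypothesis-imposed ordering.** For a matrix
whose columns are ordered by the gradient (highest pH leftmost) and whose
rows are ordered by taxon occurrence, the NODF index ("nested overlap and
decreasing fill") is the mean over ordered pairs of columns (or rows) of
the paired term

    N_pair(left, right) = 100 · |left ∩ right| / fill(right),   if fill(right) < fill(left)
                        = 0                                      otherwise,

so NODF ranges from 0 (no nestedness) to 100 (every poorer community a
perfect subset of every richer one). The weighted variant (WNODF) for
quantitative matrices zeroes a pair unless its marginal total decreases
strictly and counts the fraction of the lighter vector's nonzero cells
that are strictly smaller than the matching cells: row-wise WNODF measures
whether taxon *dominance* is consistent across sites. Significance comes
from Monte-Carlo null models that fix both row and column totals: the
curveball algorithm for presence/absence matrices, and Patefield draws of
random count tables (with the same column rescaling as the data) for
quantitative matrices. Each test reports

    Z = (observed − mean_null) / sd_null,
    p_upper = (#{null ≥ obs} + 1) / (n_null + 1)   (and p_lower analogously),

with significant positive Z indicating nestedness and significant negative
Z "anti-nestedness" (inconsistent dominance).

**S-D-R simplex.** Every site pair is decomposed into similarity
`S = a/n` (Jaccard; Ruzicka in abundance mode), richness/abundance
difference `D = |b − c|/n`, and replacement `R = 2·min(b, c)/n`, with
`S + D + R = 1`. Mean percentage contributions of turnover (1−S),
agreement (1−D) and nestedness (1−R) summarize the matrix.

**Supporting analyses.** One-way and two-way (crossed, balanced) PERMANOVA
on Jaccard distances; Mantel tests of community dissimilarity
(Morisita-Horn or Ruzicka) against gradient distance; analytic
(hypergeometric) rarefaction with exact variance and a CI-half-width
sequencing-sufficiency criterion; and per-taxon pH-generality profiles
(lowest occupied pH vs. SD of occupied pH) with their Pearson correlation.

**Synthetic data.** A generator with known truth — per-phylotype lower pH
tolerance limits, tolerance-dependent site establishment, optional
pH-dependent dominance optima — emulates a six-site survey (pH 3.2–7.2,
12 samples/site, 50 phylotypes) and a two-inoculum × three-pH glasshouse
experiment, so the whole pipeline is testable end to end.

## Worked example

```r
library(nestgrad)
cfg <- simulation_config(regime = "nested", dominance_shift = TRUE, seed = 1)
sim <- simulate_communities(cfg)
report <- run_pipeline(list(n_null = 1000, n_perm = 999, seed = 11),
                       samples = sim$samples)
print(report)
#> Gradient-nestedness analysis report
#>   matrix: 41 phylotypes x 6 groups
#> NODF (columns): observed = 51.00, null = 48.11 +/- 1.41
#> Z = 2.05, p(nested) = 0.01898, p(anti-nested) = 0.984  [n_null = 1000, fixed-fixed (curveball)]
#> WNODF (rows): observed = 31.59, null = 53.84 +/- 1.98
#> Z = -11.25, p(nested) = 1, p(anti-nested) = 0.000999  [n_null = 1000, weighted null (margins_fixed)]
#> S-D-R simplex (binary mode, 15 pairs):
#>   turnover (1-S): 65.6%  agreement (1-D): 72.5%  nestedness (1-R): 61.9%
#> S-D-R simplex (abundance mode, 15 pairs):
#>   turnover (1-S): 81.2%  agreement (1-D): 65.1%  nestedness (1-R): 53.7%
#> PERMANOVA (999 permutations)
#>    term df ss pseudo_f     p
#>  groups  5 NA     7.92 0.001
#> Mantel test: r = 0.922, p = 0.004 (999 permutations)
#> Generality: r = -0.549, p = 0.0003 (n = 39 profiles)
```

Reading the report: incidence is significantly *nested* along the pH
order (NODF Z = 2.05, p = 0.019 — poorer acidic communities are subsets
of richer neutral ones), while abundance is strongly *anti-nested*
(WNODF Z = −11.25, p = 0.001 — the dominant phylotypes differ between
sites). Consistently, the S-D-R nestedness contribution drops (61.9% →
53.7%) and turnover rises (65.6% → 81.2%) when abundance is taken into
account. Sites differ overall (PERMANOVA p = 0.001), community
dissimilarity tracks pH difference (Mantel r = 0.922), and phylotypes with
lower minimum occupied pH span wider pH ranges (r = −0.549, p < 0.001):
the acid-tolerant phylotypes are pH generalists.

The same steps are laid out as a narrated workflow in `analysis/01…05`,
each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic survey + glasshouse data
Rscript analysis/02_nestedness.R    # NODF / WNODF with null models
Rscript analysis/03_sdr.R           # S-D-R simplex decomposition
Rscript analysis/04_multivariate.R  # PERMANOVA (1- and 2-way), Mantel
Rscript analysis/05_generality_rarefaction.R
```

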