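# antbiogeo

Biogeographic realms are regions whose species assemblages are more similar
to each other than to anywhere else — think of Wallace's classical realms.
Human-mediated dispersal of non-native species blurs these boundaries:
when the same set of species establishes in many places, assemblages
homogenize. `antbiogeo` implements a complete before/after analysis of
this process for presence/absence data on spatial reporting units
("polygons"), as used in global ant biogeography, and ships a synthetic
world generator so the entire pipeline is testable without any external
download.

It is aimed at macroecologists and invasion biologists with a long-format
species × polygon occurrence table in which every occurrence is flagged
`native` or `nonnative`. The *before* configuration uses native
occurrences only (ranges before human-mediated dispersal); the *after*
configuration uses all occurrences.

## Methods at a glance

* **Turnover.** Pairwise Simpson turnover
  `β_sim = 1 − a / (min(b, c) + a)`, with `a` shared species and `b`, `c`
  species unique to each polygon; 0 for identical or nested assemblages,
  1 for disjoint ones.
* **Bioregionalization.** UPGMA clustering of the `β_sim` matrix with a
  permutation test per dendrogram node (species prevalence preserved,
  spatial structure destroyed; 999 iterations by default). Realms are the
  maximal subtrees significantly more cohesive than random. Elbow,
  silhouette and Kelley–Gardner–Sutcliffe diagnostics and a species-pool
  sensitivity analysis are included.
* **Homogenization.** `h_ij = β_after(i,j) − β_before(i,j)` (negative =
  homogenized), per-polygon means `h̄_i = Σ_j h_ij / N`, and island ×
  tropical stratum summaries.
* **Inference.** Scheirer–Ray–Hare rank-based two-way ANOVA, pairwise
  Wilcoxon tests with Bonferroni correction, Poisson / negative-binomial
  GLMMs with a regional random intercept (AIC model selection), Mantel
  tests, and negative-exponential distance-decay fits
  `s(d) = a · exp(−b·d)`.

## Worked example

```r
library(antbiogeo)

cfg   <- world_config(n_realms = 5, polygons_per_realm = 30,
                      species_per_realm = 120, range_max = 24, seed = 1)
world <- generate_introductions(generate_world(cfg), cfg)

bundle <- run_full(world$table, world$meta, n_perm = 99, seed = 1,
                   fit_glmms = FALSE)

bundle$realms_before
#> realm_assignment: 5 realm(s) over 150 polygons; cut height 0.6546
#>
#>  1  2  3  4  5
#> 30 30 30 30 30
compare_assignments(bundle$realms_before, world$realms)
#> [1] 1
bundle$homogenization
#> homogenization_result over 150 polygons: 12.3% homogenized, 10.5% differentiated, 77.2% unchanged
c(bundle$mantel_before$r, bundle$mantel_after$r)
#> [1] 0.6829601 0.6778290
```

The five planted realms are recovered exactly (adjusted Rand index 1).
After the biased introduction process, 12.3% of polygon pairs are more
similar than before (they homogenized), and the Mantel correlation
between turnover and geographic distance weakens slightly — at
realistically small introduction pressure most pairs are untouched;
raising `nonnative_fraction` or `lambda` strengthens both signals.

Real data enter through `read_incidence()` (long or wide CSV) and
`read_polygon_metadata()`; see the vignette for the file formats and the
full analysis walk-through, including the `focus = "island"` /
`"mainland"` splits and `dataset = "nonnative_only"` runs.

A command-line interface wraps the same stages:

```sh
Rscript inst/cli.R simulate --seed 1 --out world/
Rscript inst/cli.R run-all --incidence world/incidence.csv \
    --meta world/metadata.csv --n-perm 99 --seed 1 --out results/
```

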