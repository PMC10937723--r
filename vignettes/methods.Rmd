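---
title: "Bioregionalization and biotic homogenization: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioregionalization and biotic homogenization: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antbiogeo)
```

This vignette documents the statistical model behind `antbiogeo`, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not
establish.

## The data model

The unit of analysis is the *polygon*: a sub-country spatial reporting
unit. Input is a binary species × polygon incidence relation in which
every occurrence carries a status, `native` or `nonnative`. Two
configurations are derived: **before** human-mediated dispersal (native
occurrences only) and **after** (all occurrences). Absences are inferred
from missing presences; there are no explicit absence records. A pair
recorded as both native and nonnative is resolved to native — a species
cannot be introduced where it is native — with a warning, because the
upstream databases do not document how such conflicts should be read.
Polygons with no species in a configuration are excluded from that
configuration's turnover matrix (the index below is undefined on empty
assemblages), with a warning.

## Turnover and homogenization

Compositional dissimilarity between polygons *i* and *j* is the Simpson
turnover

$$\beta_{\mathrm{sim}} = 1 - \frac{a}{\min(b, c) + a}$$

with $a$ the shared species count and $b, c$ the counts unique to each
side. Unlike Sørensen or Jaccard it ignores nestedness: a strict subset
assemblage scores 0. All set arithmetic is exact integer work (a single
matrix cross-product) followed by one division, so the matrix path and
the pairwise path agree bit-for-bit.

The homogenization index is the change
$h_{ij} = \beta^{\mathrm{after}}_{ij} - \beta^{\mathrm{before}}_{ij}$:
negative values mean the pair became more similar (homogenization),
positive values differentiation, and exact zeros are counted as
*unchanged* — they are deliberately left out of both proportions. The
per-polygon summary is $\bar h_{i} = \sum_j h_{ij} / N$ where $N$ is the
polygon count of the geographic focus; the zero self-pair is included in
the sum and the divisor is $N$, not $N - 1$, following the index's
published definition ($N-1$ normalization is available via
`drop_self = TRUE`). Mainland-only or island-only analyses recompute
$\beta$ *within* the focus subset rather than subsetting the global
matrix, because $\beta_{\mathrm{sim}}$ itself does not decompose over
subsets of pairs.

## Realm delineation

Realms come from UPGMA (average-linkage) clustering of the
$\beta_{\mathrm{sim}}$ matrix. Ties in the minimal inter-cluster
distance are broken by the lexicographically smallest label pair, which
makes the tree — and everything downstream — invariant to polygon input
order. The implementation is a small C++ routine; its heights are tested
against an independent reference agglomeration.

**Node significance.** The null model reassigns each species'
occurrences to a uniformly random polygon subset of the same size:
species prevalence is preserved, spatial structure destroyed. For each
of `n_perm` permutations the turnover matrix and tree are recomputed.
Nodes are ranked by height (deepest first) and the observed rank-*r*
statistic is compared with the permuted rank-*r* statistics using the
$(1 + k)/(1 + n_{\mathrm{perm}})$ estimator, so p-values are never zero
and the test is exact (the observed tree is exchangeable with the
permuted ones under the null, whatever the statistic).

**Choice of node statistic.** This was the one genuinely open design
point. The first candidate — the height gap between a node and its
taller child — fails on a basic thought experiment: with three or more
mutually disjoint realms, all upper merges happen at exactly
$\beta_{\mathrm{sim}} = 1$, so every upper node except the first has a
gap of zero and can never be flagged, and no cut can recover the realms.
A gap to the *shallower* child fixes that case but has the converse
problem: the nodes *joining* unrelated realms get the largest gaps, so a
height cut above "all significant nodes" descends into every cohesive
realm and over-splits. The default statistic is therefore the node
**height itself, tested one-sided low**: a cluster is significant when
it merges at a lower dissimilarity than rank-matched null nodes, i.e.
when it is more cohesive than chance. A merge of unrelated realms sits
at a height indistinguishable from random merges and is not flagged;
each realm's root is. Realms are then the **maximal significant
subtrees**, found by descending from the root through non-significant
merges; leaves stranded between realms become singletons, and if nothing
is significant a single realm is reported. This matches the stated goal
of finding the dissimilarity level below which all clusters are
non-random. Both gap statistics remain available
(`statistic = "min_child"` / `"max_child"`, with a contiguous
cut-from-the-root rule) for comparison.

**Cluster-number diagnostics.** Elbow (total within-cluster mean
dissimilarity; maximum-curvature point), mean silhouette width computed
directly from the dissimilarity matrix, and a
Kelley–Gardner–Sutcliffe-style penalty — mean within-cluster spread
min-max rescaled to $[1, n-1]$ plus the cluster count, minimized. The
penalty's published form is tied to fitted cophenetic spreads; the
rescaled-spread version used here keeps its intent (penalize both loose
clusters and many clusters) without depending on a particular fit.

**Sensitivity analysis.** `subset_sensitivity()` resamples the species
pool at the study's ladder of sizes (300 … 10,000 by default), reruns
the full delineation, and scores agreement with the full-data realms by
the adjusted Rand index.

## Inferential statistics

* **Scheirer–Ray–Hare.** Mid-ranks of the pooled response enter a
  two-way ANOVA decomposition with Type-II sums of squares (the common
  implementation's behaviour in unbalanced designs);
  $H = SS_{\mathrm{term}} / MS_{\mathrm{total}}$ is referred to
  $\chi^2$ with the term's df. $MS_{\mathrm{total}}$ is the total rank
  variance, which equals $n(n+1)/12$ without ties and applies the tie
  correction automatically otherwise. With one factor constant the other
  factor's $H$ is exactly Kruskal–Wallis.
* **Group comparisons.** The donated/received species counts are
  compared between strata with *unpaired* two-sided Wilcoxon rank-sum
  tests, Bonferroni-corrected. The source analysis names the signed-rank
  test, but the island/mainland groups are independent samples of
  unequal size, for which the rank-sum test is the coherent choice; this
  discrepancy is deliberate and documented here.
* **Count GLMMs.** Donated and received counts are modelled with
  log-link mixed models, tropical and island status as fixed effects
  (optionally interacting) and a random intercept per subcontinental
  region. Both a Poisson and a negative-binomial family are fitted and
  compared by AIC (`select_count_glmm()`). Both use the Laplace
  approximation by default: `lme4` drops constant deviance terms when
  `nAGQ > 1`, which would silently corrupt the cross-family AIC
  comparison (adaptive quadrature remains available through `nagq` when
  only coefficients matter). Zero inflation is not modelled: the source
  framework supports it but no retained model is reported to use it.
  Non-convergence is flagged on the fit, never silently dropped.
* **Mantel test.** Pearson correlation of upper-triangle entries with
  simultaneous row/column permutation of the first matrix; the default
  alternative is one-sided (`greater`), the classical distance-decay
  direction. For $n \le 8$ an exhaustive enumeration over all $n!$
  permutations is available.
* **Distance decay.** Similarity $1 - \beta_{\mathrm{sim}}$ against
  great-circle distance between centroids (haversine, sphere radius
  6371 km). The fitted form is the negative exponential
  $s(d) = a\,e^{-bd}$ — the fitting call in the source is not spelled
  out, and the negative exponential is the standard distance-decay
  model; a power law is available as an alternative. Starting values:
  $a_0$ = mean similarity in the shortest-distance decile, $b_0$ from a
  log-linear regression on positive similarities; the `port` algorithm
  is used because it converges cleanly on noiseless (zero-residual)
  data. The "decay rate per 1000 km" is defined only in a figure in the
  source, so both readings are reported: the fractional similarity loss
  $1 - e^{-1000b}$ and the raw slope $1000b$.

Tropical status is $|\mathrm{lat}| \le 23°$ of the centroid — the stated
threshold is the round 23°, not the astronomical tropic, and the
boundary is counted as tropical (a convention; the source does not say).

## The synthetic world

`generate_world()` plants `n_realms` realms, each in its own longitude
sector with a latitude band drawn from a tropical / north-temperate /
tropical / south-temperate / tropical template, so default worlds mix
tropical and non-tropical polygons. Within a realm, every species'
native range is a uniform random polygon subset with log-uniform size
(default 2–50 of 100 polygons per realm — many narrow-ranged species,
few widespread ones, a standard macroecological shape). A bleed
probability ε relocates single occurrences into foreign realms
(default 0.02), blurring boundaries the way imperfect sampling and
natural dispersal do. One region label is minted per realm × island
block, approximating subcontinental regions at configurable
granularity.

`generate_introductions()` emulates human-mediated dispersal: 2% of
species (default) become non-native, drawn with weight 4 for species
that are both mostly-tropical and mostly-mainland (tropical mainlands
are the dominant donor pool); each receives a truncated-Poisson(λ = 8)
number of introductions outside its native range, targets drawn with
multiplicative weights 2 for tropical and 3 for island polygons — a
tropical island is 6 times as attractive as a non-tropical mainland.
These defaults were chosen once, to mirror the qualitative structure of
the empirical system (~500 polygons, ~30% islands, ~2% non-native
species, introductions concentrated on tropical islands), and are *not*
tuned to test outcomes.

What a green test establishes: that the pipeline recovers planted
structure, that the permutation test is calibrated, and that the
directional signatures (islands homogenize more; distance-decay
flattens) follow from island-biased introductions. What it does not:
the generator has no environmental gradients, no spatial
autocorrelation within realms, no sampling effort heterogeneity, and
independent species — so the tests say nothing about robustness to
under-sampling or to correlated ranges, both real concerns with
empirical ant data.

## Numerical notes and limitations

* All randomness flows through explicit seeds; identical configuration
  and seed give bit-identical worlds and, through the pipeline,
  byte-identical output files.
* Permutation p-values are bounded below by $1/(n_{\mathrm{perm}}+1)$;
  with the default α = 0.05 at least 19 permutations are needed for any
  rejection, and 999 (the source's count) gives a stable cut.
* UPGMA is $O(n^3)$ worst-case but runs in well under a second for the
  ~500-polygon scale this package targets; the permutation test is the
  dominant cost and scales linearly in `n_perm`.
* The realm count from `cut_significant()` depends on the chosen node
  statistic at degenerate configurations (ties at $\beta = 1$); the
  default cohesion statistic handles these, the gap variants are
  provided for sensitivity checks.
* `glmer.nb` occasionally emits convergence warnings on small or sparse
  region structures; fits carry a `converged` flag and
  `select_count_glmm()` skips models that fail outright.
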