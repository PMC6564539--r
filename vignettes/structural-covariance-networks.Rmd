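---
title: "Structural covariance network analysis with scnet: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis with scnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The method

A structural covariance network (SCN) treats the correlation of a
morphometric measure — regional cortical thickness (CT, mm) or local
gyrification index (lGI, unitless) — across subjects as a proxy for shared
anatomical organisation: two regions whose thickness co-varies across a
group are taken to be "connected". `scnet` builds such networks per
subject group and asks whether group membership (here, cognitive profiles
obtained by k-means) is associated with differences in network topology.

The pipeline has five stages.

1. **Cognitive subtyping.** Test scores are aligned so higher always means
   better (error counts are `-log10(x + 1)`-transformed,
   `transform_ided()`), at most one missing test per subject is imputed
   from an age/education regression (`impute_cognitive()`), every test is
   residualized on age and education (`residualize_scores()`), columns are
   z-scored, and subjects are partitioned by Euclidean k-means with 50
   restarts (`kmeans_profiles()`). Labels are relabelled by descending
   mean z-profile so "cluster 1" is always the highest-functioning
   profile; this makes runs comparable across seeds.

2. **Network construction.** Within each group, every ROI is residualized
   by OLS on age, sex, their interaction, and the subject's global measure
   (mean ROI value), so that edges reflect regional covariance beyond
   global anatomy (`residualize_rois()`). The ROI-by-ROI Pearson matrix
   (`correlation_matrix()`) is binarized in two steps: an edge is
   *eligible* only if its correlation is positive and significant at
   `alpha = 0.05` (two-sided t-test; negative correlations are excluded
   because their biological reading differs), and a *density threshold*
   then keeps the `round(d * R(R-1)/2)` eligible edges with the largest
   correlations (`edge_eligibility()`, `threshold_by_density()`). Ties in
   r are broken lexicographically by ROI index, so edge sets are
   deterministic, and they are nested across densities by construction.

3. **Density sweep.** There is no principled single density, so metrics
   are computed along a grid. The sweep starts from the smallest density
   at which *every* group's graph is fully connected
   (`find_min_density()`, scan step 0.01) and ends by default at 0.46;
   densities above 0.5 approach random configurations and are not used.

4. **Graph metrics.** On each binary graph: mean clustering coefficient,
   transitivity, local and global efficiency, characteristic path length,
   node degree and unnormalized Brandes betweenness; Louvain modularity
   with max-Q restart selection (`modularity_louvain()`); and
   small-worldness `sigma = gamma / lambda` against 20 degree-preserving
   Maslov–Sneppen rewired nulls (`small_worldness()`). Conventions:
   nodes of degree < 2 contribute 0 to clustering and local efficiency
   (they are retained, not dropped); path length is defined only on
   connected graphs (guaranteed on the sweep grid); unreachable pairs
   contribute 0 to global efficiency.

5. **Group comparison ("FDA").** Each metric's curve over the density
   grid is integrated by the trapezoidal rule; groups are compared on the
   area between curves. The null distribution reshuffles subject-to-group
   labels, preserving group sizes, and rebuilds everything on the same
   grid (`fda_compare()`); p-values are two-sided percentile positions
   with a +1 small-sample correction, so p is never 0. Regional (per-ROI)
   degree and betweenness tests get a Benjamini–Hochberg correction at
   q = 0.05, applied per metric and group pair (148 tests per family; the
   families are not pooled across pairs). Hubs are nodes whose
   density-integrated degree or betweenness exceeds the cross-node mean by
   2 SD; module composition at minimum density is described per lobe and
   matched across groups by maximal Jaccard overlap.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `alpha` | 0.05 | — | edge eligibility significance |
| `d_max` | 0.46 | density | above 0.5 networks approach random graphs |
| `d_step` | 0.01 | density | grid resolution for curve integration |
| `d_margin` | 0.08 | density | gap between `d_min` and the grid floor (below) |
| `n_perm` | 1000 | count | permutation resolution (min p = 1/1001) |
| `n_null` | 20 | count | nulls for sigma |
| `sd_multiplier` | 2 | SD | hub threshold |
| `kmeans_nstart` | 50 | count | k-means restarts |
| `louvain_restarts` | 20 | count | max-Q selection |
| `max_skip_frac` | 0.10 | fraction | tolerated fragmented permutations |

**Why the grid floor sits above `d_min`.** The minimum connected density
is an extreme-value statistic: it is the largest of the per-group
connectivity thresholds. A permuted cohort redraws those thresholds from
(under the null) the same distribution, so if the grid started exactly at
the observed `d_min`, roughly half of all permutations would fragment at
the lowest grid point. Fragmented permutations are *skipped and counted*
— recomputing a per-permutation `d_min` would change the integration
domain of every permutation and make areas incomparable — and a run in
which more than `max_skip_frac` of permutations are skipped fails loudly
rather than report a null built from a censored sample. A floor of
`d_min + 0.08` keeps measured skip rates in the low percent range while
`d_min` itself is still reported and used for the module description (the
most conservative, strongest-edge network). Both the margin and the skip
policy are configurable.

**Modularity and small-worldness in the comparison.** The five curve
metrics are always compared. `"modularity"` (Louvain max-Q per density)
and `"small_world"` can be added to `metrics =`; sigma multiplies the
cost of the whole permutation sweep by about `n_null + 1` and is therefore
opt-in.

## The synthetic cohort generator

No morphometry data ship with the package; `generate_morphometry()`
creates cohorts in which the *true* covariance topology is known, so every
downstream stage can be validated quantitatively.

ROIs sit on a ring partitioned into `n_blocks` contiguous blocks. Each
block contributes one latent factor whose loading profile is a triangular
bump centred on the block and overlapping its neighbours; loadings are
row-normalized and scaled by a factor-variance share `v`, so the planted
correlation between ROIs i and j is `v * (u_i . u_j)`. Two calibration
targets pin the free parameters per group: the *mean* correlation within
blocks equals `within_block_r` and the *mean* correlation between blocks
equals `between_block_r` (`target_correlation()` returns the exact planted
matrix). Linear age, sex and age-by-sex effects and the overall scale
(`noise_sd`, 0.10 mm around a 2.5 mm baseline for CT) are added on top;
age is uniform on 25–60 years and sex is Bernoulli(0.8), defaults chosen
to resemble a middle-aged, predominantly male clinical cohort.

The bump *overlap* is not cosmetic. The pipeline regresses every ROI on
the subject's global measure, and that regression annihilates any
covariance component that is common to all regions: a generator with
hard-edged blocks plus a uniform between-block correlation loses its
entire cross-block structure to the global regression (the per-ROI OLS
slope removes each region's share of a single shared factor exactly,
leaving between-block residual correlations uniformly negative). Since
only positive, significant correlations are eligible as edges, such a
cohort can never form a fully connected graph at any density. Real
cortical networks survive global-signal removal because covariance is
organised in overlapping gradients rather than disjoint blocks; the ring
overlap reproduces exactly that property — boundary regions load on two
factors and provide the bridges that keep the thresholded graph
connected.

`plant_topology_contrast()` raises one group's `within_block_r`. At fixed
density this concentrates that group's edges inside blocks: clustering
and transitivity rise, between-block paths lengthen, global efficiency
falls — a segregation/integration contrast with a known direction, which
the comparison stage must detect.

**What the generator does not emulate:** cortical surfaces and vertex
data, scanner noise and site effects, non-Gaussian morphometry
distributions, spatial autocorrelation within blocks beyond the ring
gradient, realistic effect sizes of clinical cohorts, and lobe-structured
anatomy (generic cohorts get arbitrary ROI names; the Destrieux names and
lobe map apply only to 148-ROI cohorts). Passing validation on these
cohorts therefore demonstrates correctness of the machinery and
calibration of the tests under a known truth — not that any particular
real-data effect will replicate.

## Validation studies and the problem sizes used

The test suite runs four simulation studies, scaled to desktop runtimes:

* **Metric correctness**: every metric equals a brute-force oracle
  (Floyd–Warshall distances, exhaustive triangle counting, matrix-power
  shortest-path counting) on 200 random graphs of up to 12 nodes, to
  1e-10, plus exact closed forms on named small graphs.
* **Type-I calibration**: 100 no-contrast cohorts (3 groups x 60
  subjects x 60 ROIs, 3 blocks), 10 grid densities, 200 permutations
  each; the pooled rejection rate at alpha = .05 must lie in the 95%
  binomial interval around 0.05 for 100 replicates, [0.01, 0.10].
* **Directional recovery**: 20 cohorts (3 groups x 60 subjects, 100
  ROIs, 4 blocks) with +0.25 within-block correlation planted in group 3;
  each of clustering, transitivity and path length must be significantly
  higher, and global efficiency lower, in group 3 versus both other
  groups (p < .05) in at least 80% of replicates. 100 ROIs are used here
  because at 60 ROIs the eligible-edge budget of the two control groups
  (~27% of pairs) can fall below the top of the density grid for
  high-`d_min` draws, capping their curves and contaminating the
  efficiency contrasts; at 100 ROIs the whole grid stays inside every
  group's eligibility.
* **Cluster recovery**: k-means on residualized synthetic batteries with
  centroids 3 within-SDs apart recovers the planted labels with adjusted
  Rand index >= 0.9 over 20 seeds.

Simulation grids use 10 densities at step 0.005 from `d_min + 0.08`,
matching the pipeline's default margin; 200 permutations give a minimum
two-sided p of ~0.005, adequate for alpha = .05 decisions.

## Numerical choices and degenerate inputs

* Edge counts use round-half-away-from-zero; base R's `round()`
  half-to-even would make edge counts depend on the parity of the target.
* Correlations of constant ROI columns are undefined; they are set to 0
  with a warning, which makes such edges ineligible.
* If fewer eligible edges exist than a density requests, all are kept and
  the achieved density is attached with a warning.
* A score exactly collinear with the covariates residualizes to zero; a
  design with constant age *and* education is rejected, while constant
  education alone falls back to the informative covariates via the
  pivoted QR.
* k-means restarts that converge to an empty cluster are retried with the
  next seed (up to 5), and the seed actually used is reported.
* Rewired nulls can fragment; their path length is averaged over
  reachable pairs so sigma remains defined. A graph with no legal
  degree-preserving swap (e.g. complete) is its own null, with a warning.
* A constant node statistic yields no hubs (otherwise mean + 2x0 SD would
  flag every node).
* All randomness flows from explicit integer seeds through R's
  Mersenne-Twister generator; per-group and per-permutation child seeds
  are derived deterministically and label shuffles are pre-drawn so the
  Louvain/null streams cannot desynchronise the permutation stream.
  Identical configurations produce byte-identical output files.

## Known limitations

* Weighted, signed and partial-correlation networks are out of scope
  (partial correlations are ill-posed when groups are smaller than the
  ROI count, the usual situation here).
* The permutation test conditions on the observed grid; the skip-and-
  count policy is principled but discards information when fragmentation
  is common — the margin default trades a little sparse-end coverage for
  an unbiased, comparable null.
* Module composition is described, not statistically compared: module
  identity is not stable enough across groups for a principled node-level
  test, so the report gives counts, lobe percentages and Jaccard
  matchings only.
* FDA-integrated curves summarise a whole density range; a real effect
  confined to one narrow density band can be diluted below detection.
* The bundled ROI-to-lobe map is a conventional assignment for reporting;
  BrainNet placeholder coordinates are a synthetic spherical layout, not
  anatomy — supply a centroid file for real renderings.
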