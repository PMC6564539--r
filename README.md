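# scnet — structural covariance network analysis of cortical morphometry

`scnet` asks whether groups of subjects — typically cognitive subtypes —
differ in the *network organisation* of their cortical anatomy. A
structural covariance network (SCN) connects two brain regions when their
morphometry (cortical thickness in mm, or local gyrification index)
correlates across the subjects of a group; differences in the topology of
these networks between groups are read as differences in coordinated
anatomical organisation.

The package is aimed at neuroimaging researchers who have a subjects x
ROIs morphometry table (e.g. FreeSurfer Destrieux-atlas output), basic
covariates, and optionally a neuropsychological battery, and want the
full group-comparison workflow with planted-truth validation.

## The method in brief

1. **Cognitive subtyping** — test scores are residualized on age and
   education, z-scored, and partitioned by k-means
   (`kmeans_profiles()`).
2. **Per-group networks** — each ROI is residualized on age, sex,
   age x sex and the subject's global measure; the ROI x ROI Pearson
   matrix is binarized by keeping, at each target density *d*, the
   `round(d * R(R-1)/2)` positive and significant (p < .05) correlations
   with the largest r (`threshold_by_density()`).
3. **Density sweep** — from the smallest density at which every group's
   graph is fully connected (`find_min_density()`) upward.
4. **Graph metrics** — clustering coefficient C, transitivity T, local
   and global efficiency E_loc / E_glob, characteristic path length L,
   degree and betweenness, Louvain modularity Q (max over restarts), and
   small-worldness sigma = gamma / lambda against 20 degree-preserving
   nulls.
5. **FDA comparison** — each metric's curve over the density grid is
   integrated (area under the curve); the area difference between groups
   is tested against a null built by reshuffling subject-to-group labels
   (group sizes preserved), with percentile p-values and
   Benjamini–Hochberg correction for the per-ROI tests
   (`fda_compare()`). Hubs are nodes whose integrated degree or
   betweenness exceeds the mean by 2 SD; modules at minimum density are
   described per lobe and matched across groups by Jaccard overlap.

A synthetic-cohort generator (`generate_morphometry()`,
`generate_cognitive()`, `plant_topology_contrast()`) plants known
covariance topology and cluster structure, so the whole pipeline is
testable without any imaging data. See the methods vignette
(`vignettes/structural-covariance-networks.Rmd`) for the model, every
tunable parameter, and the validation studies.

## Worked example

Three groups of 60 subjects, 100 ROIs in four covariance blocks; group 3
carries a planted +0.25 within-block correlation contrast — the
segregation/integration signature the comparison stage must detect:

```r
library(scnet)

base <- cohort_spec(n_groups = 3, group_sizes = c(60, 60, 60),
                    n_rois = 100, n_blocks = 4,
                    within_block_r = 0.6, between_block_r = 0.25, seed = 2)
spec  <- plant_topology_contrast(base, delta_within_r = 0.25, target_group = 3)
morph <- generate_morphometry(spec)

cfg <- run_config(morph, k = 3, d_step = 0.005, n_densities = 10,
                  metrics = c("clustering", "transitivity",
                              "global_efficiency", "path_length"),
                  n_perm = 200, regional = FALSE, seed = 2)
res <- run_pipeline(cfg)
res
```

```
SCN pipeline result: 3 groups (1/2/3), d_min = 0.100, grid [0.180, 0.225] x 10
  group 1: 5 modules (Q = 0.626), sigma(d_min) = 2.84
  group 2: 5 modules (Q = 0.599), sigma(d_min) = 2.33
  group 3: 5 modules (Q = 0.683), sigma(d_min) = 2.49
FDA permutation comparison: 3 groups, 10 densities [0.180, 0.225], 185/200 valid permutations (15 skipped)
              metric   pair   auc_1   auc_2   fda_diff        p
1         clustering 1 vs 2 0.03006 0.03023 -1.739e-04 0.790323
2       transitivity 1 vs 2 0.02986 0.02998 -1.173e-04 0.935484
3  global_efficiency 1 vs 2 0.02219 0.02219  4.242e-06 1.000000
4        path_length 1 vs 2 0.11631 0.11646 -1.510e-04 0.994624
5         clustering 1 vs 3 0.03006 0.03312 -3.061e-03 0.005376
6       transitivity 1 vs 3 0.02986 0.03328 -3.423e-03 0.005376
7  global_efficiency 1 vs 3 0.02219 0.02023  1.959e-03 0.005376
8        path_length 1 vs 3 0.11631 0.14122 -2.492e-02 0.005376
9         clustering 2 vs 3 0.03023 0.03312 -2.887e-03 0.010753
10      transitivity 2 vs 3 0.02998 0.03328 -3.306e-03 0.010753
11 global_efficiency 2 vs 3 0.02219 0.02023  1.955e-03 0.005376
12       path_length 2 vs 3 0.11646 0.14122 -2.476e-02 0.005376
```

Reading: `d_min = 0.100` is the sparsest density at which all three
networks are fully connected; every group shows small-world organisation
(sigma well above 1) and five modules at that density. The planted group
3 has *higher* density-integrated clustering, transitivity and path
length than both other groups (`fda_diff = auc_other - auc_3 < 0`) and
*lower* global efficiency, all at or near the permutation floor
p ~ 0.005, while the two unmodified groups (pair "1 vs 2") do not differ
on anything — the known truth is recovered with the correct direction.
The 15 skipped permutations are label reshuffles whose networks
fragmented at the sparsest grid density; they are counted, excluded from
the null, and capped at 10% by default.

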