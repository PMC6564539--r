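# shared fixtures for synthetic-cohort tests: small, fast study conditions

small_cohort <- function(seed = 1, n_rois = 60, n = 60, groups = 3,
                         w = 0.6, b = 0.25, K = 3) {
  cohort_spec(n_groups = groups, group_sizes = rep(n, groups),
              n_rois = n_rois, n_blocks = K,
              within_block_r = w, between_block_r = b, seed = seed)
}

# density grid used by the simulation studies: 10 points, step 0.005,
# floor d_min + 0.08 (see the methods vignette)
study_grid <- function(morph, margin = 0.08, step = 0.005, npts = 10) {
  groups <- sort(unique(morph$group))
  crs <- lapply(groups, function(g) correlation_matrix(residualize_rois(morph, g)))
  mks <- lapply(crs, edge_eligibility)
  dmin <- find_min_density(crs, mks)
  list(densities = round(dmin + margin + step * (0:(npts - 1)), 10),
       dmin = dmin)
}

# well-separated cognitive spec: centroid rows 3 within-SDs apart per test
separated_cognitive_spec <- function(seed = 1, sd = 0.5, gap = 3) {
  step <- gap * sd
  cognitive_spec(centroids = rbind(rep(0, 6), rep(step, 6), rep(2 * step, 6)),
                 within_cluster_sd = sd, seed = seed)
}
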