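# End-to-end orchestration: clustering -> per-group network stacks ->
# metric curves -> FDA comparisons -> hubs and modules -> exported tables.

#' Assemble and validate a pipeline configuration
#'
#' Collects every analysis choice in one object so a run is fully
#' reproducible from its configuration and seed. Each argument is a
#' documented default of the method, not a hidden constant.
#'
#' @param morphometry Morphometry data.frame or path to a tab-delimited
#'   table (`subject_id`, optional `group`, `age`, `sex`, ROI columns).
#' @param cognitive Optional cognitive data.frame or path (`subject_id`,
#'   `age`, `education`, six test columns). When given, group labels come
#'   from k-means clustering; otherwise from `labels` or the morphometry
#'   `group` column.
#' @param labels Optional explicit group label per morphometry row.
#' @param k Number of cognitive clusters (default 3).
#' @param transform_ided Apply [transform_ided()] to the `ided_total`
#'   column before clustering (for raw error counts; default FALSE, which
#'   assumes scores are already aligned so higher = better).
#' @param alpha Edge-eligibility significance level.
#' @param d_max Density-grid ceiling (default 0.46; densities above 0.5 are
#'   not considered meaningful).
#' @param d_step Density-grid step (default 0.01).
#' @param d_margin Gap between the minimum connected density and the grid
#'   floor (default 0.08). The floor sits above `d_min` so that permuted
#'   cohorts, which redraw the connectivity threshold, rarely fragment;
#'   `d_min` itself is still found, reported, and used for the module
#'   description.
#' @param densities Optional explicit density grid overriding the
#'   `d_margin`/`d_step`/`d_max` construction.
#' @param n_densities Optional fixed number of grid points; when given the
#'   grid is `floor + d_step * (0:(n_densities - 1))` (still capped by
#'   `d_max`), which keeps the sweep inside the eligible-edge budget of
#'   sparse cohorts.
#' @param metrics Global metrics for the FDA comparison (see
#'   [fda_compare()]).
#' @param n_perm Permutations for the FDA null (default 1000).
#' @param n_null Null networks for small-worldness (default 20).
#' @param sd_multiplier Hub threshold multiplier (default 2).
#' @param kmeans_nstart k-means restarts (default 50).
#' @param louvain_restarts Louvain restarts for the reported partitions
#'   (default 20).
#' @param regional Run regional (per-ROI) permutation tests (default TRUE).
#' @param max_skip_frac Tolerated fraction of skipped (fragmented)
#'   permutations (default 0.10).
#' @param lobe_map Named ROI-to-lobe vector; defaults to
#'   [destrieux_lobes()] when the ROI names match, else module reports are
#'   skipped.
#' @param coordinates Optional ROI coordinate matrix for BrainNet export;
#'   defaults to the synthetic [sphere_layout()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional output directory; when given, all result tables
#'   are written there as tab-delimited text plus a JSON manifest.
#' @return List of class `"scn_config"`.
#' @export
run_config <- function(morphometry, cognitive = NULL, labels = NULL,
                       k = 3L, transform_ided = FALSE, alpha = 0.05,
                       d_max = 0.46, d_step = 0.01, d_margin = 0.08,
                       densities = NULL, n_densities = NULL,
                       metrics = c(GLOBAL_METRICS, "modularity"),
                       n_perm = 1000L, n_null = 20L, sd_multiplier = 2,
                       kmeans_nstart = 50L, louvain_restarts = 20L,
                       regional = TRUE, max_skip_frac = 0.10,
                       lobe_map = NULL, coordinates = NULL,
                       seed = 1L, out_dir = NULL) {
  if (is.character(morphometry)) {
    if (!file.exists(morphometry)) stop("morphometry file not found: ", morphometry)
  }
  if (is.character(cognitive) && !file.exists(cognitive))
    stop("cognitive file not found: ", cognitive)
  stopifnot(k >= 1, alpha > 0, alpha < 1, d_max > 0, d_max <= 0.5,
            d_step > 0, d_margin >= 0, n_perm >= 0, n_null >= 1)
  cfg <- list(morphometry = morphometry, cognitive = cognitive,
              labels = labels, k = as.integer(k),
              transform_ided = transform_ided, alpha = alpha,
              d_max = d_max, d_step = d_step, d_margin = d_margin,
              densities = densities, n_densities = n_densities,
              metrics = metrics,
              n_perm = as.integer(n_perm), n_null = as.integer(n_null),
              sd_multiplier = sd_multiplier,
              kmeans_nstart = as.integer(kmeans_nstart),
              louvain_restarts = as.integer(louvain_restarts),
              regional = regional, max_skip_frac = max_skip_frac,
              lobe_map = lobe_map, coordinates = coordinates,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "scn_config"
  cfg
}

load_table <- function(x) if (is.character(x)) read.delim(x, check.names = FALSE) else x

#' Run the full structural covariance network pipeline
#'
#' Sequences the analysis stages: (1) cognitive clustering (transform,
#' impute, residualize on age/education, z-score, k-means) when a cognitive
#' table is supplied; (2) per-group ROI residualization, correlation and
#' eligibility; (3) minimum-density search and density grid; (4) network
#' stacks and global/regional metric curves; (5) FDA permutation
#' comparisons with FDR for regional tests (skipped cleanly when only one
#' group exists); (6) Louvain modules and small-worldness at minimum
#' density, FDA hubs, module composition; (7) optional export of all
#' tables, a BrainNet node/edge file per group, and a JSON run manifest.
#' Reruns with the same configuration are byte-identical.
#'
#' @param config An [run_config()] object.
#' @return List of class `"scn_result"` with elements `clusters`,
#'   `labels`, `d_min`, `densities`, `stacks`, `comparison`, `modules`,
#'   `module_table`, `small_world`, `hubs`, `config`, `skipped`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "scn_config"))
  morph <- load_table(config$morphometry)
  seed <- config$seed

  # --- stage 1: group labels ----------------------------------------------
  clusters <- NULL
  if (!is.null(config$cognitive)) {
    cog <- load_table(config$cognitive)
    if (config$transform_ided)
      cog$ided_total <- transform_ided(cog$ided_total)
    cog <- impute_cognitive(cog)
    res <- residualize_scores(cog)
    clusters <- kmeans_profiles(res, k = config$k,
                                nstart = config$kmeans_nstart,
                                seed = seed + 11L)
    lab_by_subject <- clusters$cluster
    keep <- morph$subject_id %in% names(lab_by_subject)
    if (!all(keep)) {
      message(sum(!keep), " morphometry subject(s) without cognitive data dropped")
      morph <- morph[keep, , drop = FALSE]
    }
    labels <- as.vector(lab_by_subject[morph$subject_id])
  } else if (!is.null(config$labels)) {
    labels <- config$labels
    stopifnot(length(labels) == nrow(morph))
  } else if (!is.null(morph$group)) {
    labels <- morph$group
  } else {
    stop("no group labels: supply a cognitive table, labels, or a group column")
  }
  groups <- sort(unique(labels))

  # --- stage 2: per-group correlation networks ----------------------------
  res_list <- lapply(groups, function(g)
    residualize_rois(morph[labels == g, , drop = FALSE]))
  corr_list <- lapply(res_list, correlation_matrix)
  mask_list <- lapply(corr_list, edge_eligibility, alpha = config$alpha)
  names(corr_list) <- names(mask_list) <- groups

  # --- stage 3: density grid ----------------------------------------------
  d_min <- find_min_density(corr_list, mask_list, d_max = config$d_max)
  if (is.null(config$densities)) {
    floor_d <- round(d_min + config$d_margin, 10)
    if (floor_d >= config$d_max)
      stop(sprintf("grid floor %.3f (d_min %.3f + margin %.3f) reaches d_max %.3f",
                   floor_d, d_min, config$d_margin, config$d_max))
    top_d <- if (!is.null(config$n_densities))
      min(round(floor_d + config$d_step * (config$n_densities - 1), 10),
          config$d_max)
    else config$d_max
    densities <- density_grid(floor_d, top_d, step = config$d_step)
  } else {
    densities <- config$densities
  }

  # --- stage 4: stacks and descriptive structure at d_min -----------------
  stacks <- Map(function(corr, mask, g)
    build_group_networks(corr, mask, densities, group = g),
    corr_list, mask_list, as.list(groups))
  adj_min <- Map(function(corr, mask) threshold_by_density(corr, mask, d_min),
                 corr_list, mask_list)
  modules <- lapply(seq_along(groups), function(k)
    modularity_louvain(adj_min[[k]], seed = seed + 101L + k,
                       restarts = config$louvain_restarts))
  names(modules) <- groups
  sw_min <- lapply(seq_along(groups), function(k)
    small_worldness(adj_min[[k]], n_null = config$n_null,
                    seed = seed + 201L + k))
  names(sw_min) <- groups

  lobe_map <- config$lobe_map
  rois <- roi_columns(morph)
  if (is.null(lobe_map) && all(rois %in% destrieux_rois()))
    lobe_map <- destrieux_lobes()
  module_table <- NULL
  if (!is.null(lobe_map))
    module_table <- module_report(lapply(modules, `[[`, "membership"), lobe_map)

  # --- stage 5: FDA comparison --------------------------------------------
  comparison <- NULL
  if (length(groups) >= 2 && config$n_perm > 0) {
    comparison <- fda_compare(morph, labels, densities,
                              alpha = config$alpha, metrics = config$metrics,
                              n_perm = config$n_perm, seed = seed + 301L,
                              regional = config$regional,
                              sd_multiplier = config$sd_multiplier,
                              max_skip_frac = config$max_skip_frac,
                              n_null = config$n_null)
  } else if (length(groups) < 2) {
    message("single group: nothing to compare, comparison stage skipped")
  }

  out <- list(clusters = clusters, labels = labels, groups = groups,
              d_min = d_min, densities = densities, stacks = stacks,
              corr = corr_list, adj_min = adj_min,
              modules = modules, module_table = module_table,
              small_world = sw_min,
              comparison = comparison,
              hubs = if (!is.null(comparison)) comparison$hubs,
              config = config)
  class(out) <- "scn_result"
  if (!is.null(config$out_dir)) write_results(out, config$out_dir)
  out
}

#' @export
print.scn_result <- function(x, ...) {
  cat(sprintf("SCN pipeline result: %d groups (%s), d_min = %.3f, grid [%.3f, %.3f] x %d\n",
              length(x$groups), paste(x$groups, collapse = "/"),
              x$d_min, min(x$densities), max(x$densities),
              length(x$densities)))
  for (g in names(x$modules))
    cat(sprintf("  group %s: %d modules (Q = %.3f), sigma(d_min) = %.2f\n",
                g, x$modules[[g]]$n_modules, x$modules[[g]]$Q,
                x$small_world[[g]]$sigma))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

# write every result table; stable formats, no timestamps, so identical
# configurations produce identical bytes
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(result$clusters)) {
    write_tsv_full(data.frame(subject_id = names(result$clusters$cluster),
                              cluster = as.vector(result$clusters$cluster)),
                   p("cluster_labels.tsv"))
    write_matrix(result$clusters$z_profile, p("cluster_z_profiles.tsv"))
  }
  for (g in names(result$corr))
    write_matrix(result$corr[[g]], p(sprintf("correlation_group%s.tsv", g)))
  curves <- do.call(rbind, lapply(result$stacks, metric_curves))
  write_tsv_full(curves, p("metric_curves.tsv"))
  if (!is.null(result$comparison)) {
    write_tsv_full(result$comparison$global, p("comparisons_global.tsv"))
    if (!is.null(result$comparison$regional))
      write_tsv_full(result$comparison$regional, p("comparisons_regional.tsv"))
    hub_rows <- list()
    for (g in names(result$hubs))
      for (s in names(result$hubs[[g]])) {
        h <- result$hubs[[g]][[s]]
        if (length(h$hubs))
          hub_rows[[length(hub_rows) + 1L]] <-
            data.frame(group = g, criterion = s, roi = h$hubs,
                       threshold = h$threshold)
      }
    hubs_df <- if (length(hub_rows)) do.call(rbind, hub_rows) else
      data.frame(group = character(), criterion = character(),
                 roi = character(), threshold = numeric())
    write_tsv_full(hubs_df, p("hubs.tsv"))
  }
  if (!is.null(result$module_table))
    write_tsv_full(result$module_table, p("module_composition.tsv"))
  for (g in names(result$modules)) {
    mem <- result$modules[[g]]$membership
    deg <- node_degree(result$adj_min[[g]])
    export_brainnet(mem, deg, coordinates = result$config$coordinates,
                    path = p(sprintf("network_group%s.node", g)),
                    adjacency = result$adj_min[[g]])
  }
  manifest <- list(
    seed = result$config$seed, alpha = result$config$alpha,
    k = result$config$k, d_min = result$d_min,
    densities = result$densities, metrics = result$config$metrics,
    n_perm = result$config$n_perm, n_null = result$config$n_null,
    groups = as.character(result$groups),
    group_sizes = as.vector(table(result$labels)),
    n_valid_perms = if (!is.null(result$comparison)) result$comparison$n_valid,
    n_skipped_perms = if (!is.null(result$comparison)) result$comparison$n_skipped,
    louvain_q = lapply(result$modules, `[[`, "Q"),
    sigma_at_dmin = lapply(result$small_world, `[[`, "sigma"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
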