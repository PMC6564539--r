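# Between-group comparison of network metric curves: integrate each metric
# across the density grid (area under the curve, the "FDA" statistic),
# build permutation nulls by reshuffling subject-to-group labels with group
# sizes preserved, and read off percentile p-values; regional tests get a
# Benjamini-Hochberg correction.

GLOBAL_METRICS <- c("clustering", "transitivity", "local_efficiency",
                    "global_efficiency", "path_length")
EXTRA_METRICS <- c("modularity", "small_world")

#' Trapezoidal area under a metric curve
#'
#' @param values Metric values on the grid.
#' @param densities Strictly increasing density grid (>= 2 points).
#' @return The trapezoidal integral over `[min(densities), max(densities)]`.
#' @examples
#' fda_integrate(rep(2, 5), seq(0.07, 0.46, length.out = 5))  # 0.78
#' @export
fda_integrate <- function(values, densities) {
  stopifnot(length(values) == length(densities), length(values) >= 2,
            !is.unsorted(densities, strictly = TRUE))
  dx <- diff(densities)
  sum(dx * (values[-1] + values[-length(values)]) / 2)
}

#' Global metric curves of a network stack
#'
#' @param stack An `"scn_stack"` from [build_group_networks()].
#' @return Long data.frame: `group`, `density`, `metric`, `value`.
#' @export
metric_curves <- function(stack) {
  stopifnot(inherits(stack, "scn_stack"))
  rows <- lapply(seq_along(stack$densities), function(k) {
    m <- cpp_global_metrics(check_adjacency(stack$adjacency[[k]]))
    data.frame(group = if (is.null(stack$group)) NA else stack$group,
               density = stack$densities[k],
               metric = GLOBAL_METRICS,
               value = as.numeric(m[GLOBAL_METRICS]))
  })
  do.call(rbind, rows)
}

#' Nodal degree and betweenness curves of a network stack
#'
#' @param stack An `"scn_stack"`.
#' @return List of two ROI x density matrices, `degree` and `betweenness`.
#' @export
nodal_curves <- function(stack) {
  stopifnot(inherits(stack, "scn_stack"))
  ed <- edge_ranking(stack$corr, stack$mask)
  R <- nrow(stack$corr)
  npairs <- R * (R - 1) / 2
  mvec <- pmin(round_half_up(stack$densities * npairs), length(ed$r))
  out <- cpp_density_sweep_nodal(R, ed$i, ed$j, as.integer(mvec))
  dimnames(out$degree) <- dimnames(out$betweenness) <-
    list(rownames(stack$corr), format(stack$densities))
  out
}

#' Two-sided permutation percentile p-value
#'
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n)`, ties counted as extreme,
#' so p is always positive and at most 1.
#'
#' @param observed Observed statistic.
#' @param null_values Vector of permutation statistics (>= 1 value).
#' @return The p-value.
#' @export
percentile_pvalue <- function(observed, null_values) {
  stopifnot(length(null_values) >= 1)
  (1 + sum(abs(null_values) >= abs(observed))) / (1 + length(null_values))
}

#' Benjamini-Hochberg step-up correction
#'
#' @param p Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List: `significant` (logical), `p_adjusted` (BH-adjusted
#'   p-values), `q`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  stopifnot(all(p > 0 & p <= 1))
  padj <- p.adjust(p, method = "BH")
  list(significant = padj <= q, p_adjusted = padj, q = q)
}

# --- internal fast path shared by observed and permuted sweeps -------------

# residuals for one group subset, tolerant of rank deficiency (a permuted
# group can, rarely, have constant sex)
.group_residuals <- function(Y, age, sex, global, idx) {
  X <- cbind(1, age[idx], sex[idx], age[idx] * sex[idx], global[idx])
  qr.resid(qr(X), Y[idx, , drop = FALSE])
}

# correlation -> eligibility -> ranked edges -> global metric matrix over
# the density grid (C++ kernel); optionally nodal curves too
.sweep_global <- function(res, mvec, rc, nodal = FALSE) {
  r <- suppressWarnings(cor(res))
  r[is.na(r)] <- 0
  R <- ncol(res)
  keep <- which(upper.tri(r) & r > rc, arr.ind = TRUE)
  rv <- r[keep]
  ord <- order(-rv, keep[, 1], keep[, 2])
  ei <- as.integer(keep[ord, 1]); ej <- as.integer(keep[ord, 2])
  mv <- as.integer(pmin(mvec, length(ord)))
  glob <- cpp_density_sweep(R, ei, ej, mv)
  out <- list(global = glob, connected = all(glob[, "n_components"] == 1),
              edges = list(ei = ei, ej = ej, mvec = mv), n_rois = R)
  if (nodal) out$nodal <- cpp_density_sweep_nodal(R, ei, ej, mv)
  out
}

# materialize the (nested) adjacency stack from ranked edges
.adj_stack <- function(sw) {
  R <- sw$n_rois
  lapply(sw$edges$mvec, function(m) {
    adj <- matrix(0L, R, R)
    if (m > 0) {
      ii <- sw$edges$ei[seq_len(m)]; jj <- sw$edges$ej[seq_len(m)]
      adj[cbind(ii, jj)] <- 1L
      adj[cbind(jj, ii)] <- 1L
    }
    adj
  })
}

#' FDA permutation comparison of group networks
#'
#' The complete comparison stage: per group, ROI residualization,
#' correlation, eligibility, density thresholding and metric curves on a
#' fixed common grid; each global metric curve is integrated over the grid
#' ([fda_integrate()]) and group differences in the integral are tested
#' against a null built by reshuffling subject-to-group labels (group sizes
#' preserved) `n_perm` times. Regional (per-ROI) degree and betweenness
#' curves are tested the same way with a Benjamini-Hochberg correction
#' across ROIs, per metric and group pair. Permutations in which any
#' group's graph fragments at some grid density are skipped and counted; if
#' more than `max_skip_frac` are skipped the run fails rather than report a
#' biased null.
#'
#' The five curve metrics (clustering, transitivity, local and global
#' efficiency, path length) are always available; `"modularity"` (max-Q
#' Louvain per density) and `"small_world"` (sigma against `n_null`
#' degree-preserving nulls per density) can be added to `metrics`, at a
#' run-time cost that for sigma multiplies the whole sweep by roughly
#' `n_null + 1`.
#'
#' @param morph Morphometry data.frame (`subject_id`, `age`, `sex`, ROI
#'   columns; a `group` column is ignored in favour of `labels`).
#' @param labels Group label per row of `morph`.
#' @param densities Common density grid (see [density_grid()]); the
#'   observed networks must be connected at every grid density.
#' @param alpha Edge-eligibility significance level (default 0.05).
#' @param metrics Global metrics to compare; subset of the five curve
#'   metrics plus `"modularity"` and `"small_world"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; label shuffles are pre-drawn from one stream,
#'   and Louvain/null-network streams are derived deterministically per
#'   permutation and density.
#' @param regional Also run per-ROI degree/betweenness tests (default TRUE).
#' @param sd_multiplier Hub threshold multiplier for the FDA-based hub sets.
#' @param max_skip_frac Maximum tolerated fraction of skipped permutations.
#' @param mod_restarts Louvain restarts per graph when `"modularity"` is
#'   compared.
#' @param n_null,swap_factor Null-network settings when `"small_world"` is
#'   compared.
#' @return List of class `"scn_comparison"`: `global` (data.frame with
#'   `metric`, `pair`, `auc_1`, `auc_2`, `fda_diff`, `p`), `regional`
#'   (data.frame with per-ROI stats, BH-adjusted p, `significant`),
#'   `auc_global` (group x metric matrix), `curves` (long data.frame of
#'   observed metric curves), `nodal_auc` (per-group ROI x statistic
#'   matrices), `hubs` (per group, from [fda_hubs()]), `densities`,
#'   `n_perm`, `n_valid`, `n_skipped`.
#' @export
fda_compare <- function(morph, labels = morph$group, densities,
                        alpha = 0.05, metrics = GLOBAL_METRICS,
                        n_perm = 1000L, seed = 1L,
                        regional = TRUE, sd_multiplier = 2,
                        max_skip_frac = 0.10, mod_restarts = 5L,
                        n_null = 20L, swap_factor = 10) {
  stopifnot(length(labels) == nrow(morph), length(densities) >= 2,
            !is.unsorted(densities, strictly = TRUE))
  bad <- setdiff(metrics, c(GLOBAL_METRICS, EXTRA_METRICS))
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  extras <- intersect(metrics, EXTRA_METRICS)
  rois <- roi_columns(morph)
  Y <- as.matrix(morph[rois])
  n <- nrow(Y); R <- ncol(Y)
  age <- morph$age; sex <- morph$sex
  global <- rowMeans(Y)
  groups <- sort(unique(labels))
  if (length(groups) < 2)
    stop("need at least 2 groups to compare; got ", length(groups))
  idx_list <- lapply(groups, function(g) which(labels == g))
  ns <- lengths(idx_list)
  rc_by_size <- vapply(ns, critical_r, numeric(1), alpha = alpha)
  npairs <- R * (R - 1) / 2
  mvec <- round_half_up(densities * npairs)
  nd <- length(densities)
  pairs <- utils::combn(seq_along(groups), 2)
  n_pairs <- ncol(pairs)
  pair_names <- apply(pairs, 2, function(p)
    paste(groups[p[1]], groups[p[2]], sep = " vs "))

  sweep_groups <- function(idxs, nodal) {
    lapply(seq_along(idxs), function(k) {
      res <- .group_residuals(Y, age, sex, global, idxs[[k]])
      .sweep_global(res, mvec, rc_by_size[k], nodal = nodal)
    })
  }
  # full densities x metrics matrix for one group sweep; `stream` seeds the
  # Louvain / rewiring RNG deterministically
  curves_of <- function(sw, stream) {
    M <- sw$global[, intersect(metrics, GLOBAL_METRICS), drop = FALSE]
    if (length(extras)) {
      adjs <- .adj_stack(sw)
      if ("modularity" %in% extras) {
        q <- vapply(seq_len(nd), function(d)
          modularity_louvain(adjs[[d]], seed = stream + 37L * d,
                             restarts = mod_restarts)$Q, numeric(1))
        M <- cbind(M, modularity = q)
      }
      if ("small_world" %in% extras) {
        s <- vapply(seq_len(nd), function(d)
          small_worldness(adjs[[d]], n_null = n_null,
                          seed = stream + 37L * d + 13L,
                          swap_factor = swap_factor)$sigma, numeric(1))
        M <- cbind(M, small_world = s)
      }
    }
    M[, metrics, drop = FALSE]
  }
  auc_of <- function(M) apply(M, 2, fda_integrate, densities = densities)
  nodal_auc_of <- function(sw) {
    cbind(degree = apply(sw$nodal$degree, 1, fda_integrate,
                         densities = densities),
          betweenness = apply(sw$nodal$betweenness, 1, fda_integrate,
                              densities = densities))
  }
  stream_of <- function(perm, group) {
    as.integer((as.numeric(seed) + 499979 * group + 1009 * perm) %% 2147483647)
  }

  obs <- sweep_groups(idx_list, nodal = regional)
  frag <- !vapply(obs, `[[`, logical(1), "connected")
  if (any(frag))
    stop("observed group graph fragmented at some grid density for group(s): ",
         paste(groups[frag], collapse = ", "),
         "; raise the grid floor (see density_grid)")
  obs_curves <- lapply(seq_along(obs), function(k)
    curves_of(obs[[k]], stream_of(0L, k)))
  auc_obs <- t(vapply(obs_curves, auc_of, numeric(length(metrics))))
  rownames(auc_obs) <- as.character(groups)
  obs_diff <- vapply(seq_len(n_pairs), function(k)
    auc_obs[pairs[1, k], ] - auc_obs[pairs[2, k], ], numeric(length(metrics)))
  obs_diff <- matrix(obs_diff, nrow = length(metrics))
  nodal_obs <- NULL
  if (regional) {
    nodal_obs <- lapply(obs, nodal_auc_of)
    names(nodal_obs) <- as.character(groups)
    for (k in seq_along(nodal_obs)) rownames(nodal_obs[[k]]) <- rois
    nodal_diff <- lapply(seq_len(n_pairs), function(k)
      nodal_obs[[pairs[1, k]]] - nodal_obs[[pairs[2, k]]])
  }

  # pre-draw all label shuffles so derived RNG streams cannot interfere
  set.seed(seed)
  shuffles <- if (n_perm > 0)
    matrix(replicate(n_perm, sample(n)), nrow = n) else NULL

  null_glob <- array(NA_real_, c(n_perm, length(metrics), n_pairs))
  if (regional) null_reg <- array(NA_real_, c(n_perm, R, 2L, n_pairs))
  n_skipped <- 0L
  valid <- logical(n_perm)
  for (p in seq_len(n_perm)) {
    shuf <- shuffles[, p]
    idxs <- idx_list
    off <- 0L
    for (k in seq_along(idxs)) {
      idxs[[k]] <- shuf[(off + 1L):(off + ns[k])]
      off <- off + ns[k]
    }
    sw <- sweep_groups(idxs, nodal = regional)
    if (!all(vapply(sw, `[[`, logical(1), "connected"))) {
      n_skipped <- n_skipped + 1L
      next
    }
    valid[p] <- TRUE
    aucs <- t(vapply(seq_along(sw), function(k)
      auc_of(curves_of(sw[[k]], stream_of(p, k))), numeric(length(metrics))))
    for (k in seq_len(n_pairs))
      null_glob[p, , k] <- aucs[pairs[1, k], ] - aucs[pairs[2, k], ]
    if (regional) {
      nas <- lapply(sw, nodal_auc_of)
      for (k in seq_len(n_pairs))
        null_reg[p, , , k] <- nas[[pairs[1, k]]] - nas[[pairs[2, k]]]
    }
  }
  if (n_perm > 0 && n_skipped / n_perm > max_skip_frac)
    stop(sprintf(paste0("%d of %d permutations produced fragmented graphs ",
                        "(> %.0f%% tolerated); use a higher grid floor"),
                 n_skipped, n_perm, 100 * max_skip_frac))
  n_valid <- sum(valid)

  global_df <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    data.frame(metric = metrics, pair = pair_names[k],
               auc_1 = auc_obs[pairs[1, k], ], auc_2 = auc_obs[pairs[2, k], ],
               fda_diff = obs_diff[, k],
               p = vapply(seq_along(metrics), function(m)
                 if (n_valid == 0) NA_real_
                 else percentile_pvalue(obs_diff[m, k], null_glob[valid, m, k]),
                 numeric(1)),
               row.names = NULL)
  }))

  regional_df <- NULL
  hubs <- NULL
  if (regional) {
    regional_df <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
      do.call(rbind, lapply(1:2, function(s) {
        stat_name <- c("degree", "betweenness")[s]
        pv <- vapply(seq_len(R), function(v)
          if (n_valid == 0) NA_real_
          else percentile_pvalue(nodal_diff[[k]][v, s], null_reg[valid, v, s, k]),
          numeric(1))
        fd <- if (n_valid == 0)
          list(significant = rep(NA, R), p_adjusted = pv)
        else fdr_correct(pv)
        data.frame(metric = stat_name, pair = pair_names[k], roi = rois,
                   fda_diff = nodal_diff[[k]][, s], p = pv,
                   p_fdr = fd$p_adjusted, significant = fd$significant,
                   row.names = NULL)
      }))
    }))
    hubs <- fda_hubs(nodal_obs, sd_multiplier = sd_multiplier)
  }

  curves_long <- do.call(rbind, lapply(seq_along(groups), function(k) {
    data.frame(group = groups[k],
               density = rep(densities, times = length(metrics)),
               metric = rep(metrics, each = nd),
               value = as.vector(obs_curves[[k]]))
  }))

  out <- list(global = global_df, regional = regional_df,
              auc_global = auc_obs, curves = curves_long,
              nodal_auc = nodal_obs,
              hubs = hubs, densities = densities, groups = groups,
              metrics = metrics, n_perm = n_perm, n_valid = n_valid,
              n_skipped = n_skipped, alpha = alpha, seed = seed)
  class(out) <- "scn_comparison"
  out
}

#' @export
print.scn_comparison <- function(x, ...) {
  cat(sprintf(
    "FDA permutation comparison: %d groups, %d densities [%.3f, %.3f], %d/%d valid permutations (%d skipped)\n",
    length(x$groups), length(x$densities), min(x$densities),
    max(x$densities), x$n_valid, x$n_perm, x$n_skipped))
  print(x$global, digits = 4)
  if (!is.null(x$regional)) {
    nsig <- sum(x$regional$significant)
    cat(sprintf("regional tests: %d of %d significant after FDR\n",
                nsig, nrow(x$regional)))
  }
  invisible(x)
}

#' Hubs from density-integrated node statistics
#'
#' Applies the mean + k*SD rule ([identify_hubs()]) to FDA-integrated node
#' degree and node betweenness, per group.
#'
#' @param nodal_auc Per-group list of ROI x statistic matrices (columns
#'   `degree`, `betweenness`), as produced by [fda_compare()] in
#'   `$nodal_auc`.
#' @param sd_multiplier Threshold multiplier (default 2).
#' @return Per-group list of per-statistic `"scn_hubs"` objects.
#' @export
fda_hubs <- function(nodal_auc, sd_multiplier = 2) {
  lapply(nodal_auc, function(m)
    lapply(setNames(colnames(m), colnames(m)), function(s)
      identify_hubs(m[, s], sd_multiplier = sd_multiplier)))
}

#' Module composition at minimum density
#'
#' Describes each group's Louvain partition in terms of node counts and
#' lobe composition, and matches modules across groups to the first group's
#' modules by maximum Jaccard overlap of node sets.
#'
#' @param memberships Per-group list of named membership vectors (from
#'   [modularity_louvain()] on the minimum-density graphs).
#' @param lobe_map Named character vector mapping every ROI to a lobe
#'   (see [destrieux_lobes()]). An ROI without a mapping is an error.
#' @return Data.frame: `group`, `module`, `n_nodes`, one `pct_<lobe>`
#'   column per lobe, `dominant_lobe`, and `matched_module` / `jaccard`
#'   against the first (reference) group.
#' @export
module_report <- function(memberships, lobe_map) {
  stopifnot(length(memberships) >= 1)
  lobes <- sort(unique(lobe_map))
  group_names <- names(memberships) %||% as.character(seq_along(memberships))
  ref <- NULL
  rows <- list()
  for (g in seq_along(memberships)) {
    mem <- memberships[[g]]
    rois <- names(mem)
    if (is.null(rois)) stop("membership vectors must be named by ROI")
    missing <- setdiff(rois, names(lobe_map))
    if (length(missing))
      stop("no lobe mapping for ROI(s): ", paste(missing, collapse = ", "))
    for (mod in sort(unique(mem))) {
      nodes <- rois[mem == mod]
      comp <- table(factor(lobe_map[nodes], levels = lobes))
      pct <- 100 * as.vector(comp) / length(nodes)
      row <- data.frame(group = group_names[g], module = mod,
                        n_nodes = length(nodes))
      for (lb in seq_along(lobes)) row[[paste0("pct_", lobes[lb])]] <- pct[lb]
      row$dominant_lobe <- lobes[which.max(pct)]
      if (g == 1) {
        row$matched_module <- mod
        row$jaccard <- 1
      } else {
        jac <- vapply(ref, function(rn)
          length(intersect(nodes, rn)) / length(union(nodes, rn)), numeric(1))
        row$matched_module <- as.integer(names(ref)[which.max(jac)])
        row$jaccard <- max(jac)
      }
      rows[[length(rows) + 1L]] <- row
    }
    if (g == 1)
      ref <- setNames(lapply(sort(unique(mem)), function(mod) rois[mem == mod]),
                      sort(unique(mem)))
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
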