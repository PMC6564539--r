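# Per-group covariance network construction: ROI residualization, Pearson
# correlation, eligibility (positive & significant), density thresholding,
# and minimum-density search.

roi_columns <- function(morph) {
  setdiff(names(morph), c("subject_id", "group", "age", "sex"))
}

#' Residualize ROI morphometry within a group
#'
#' For each ROI, removes by OLS the variance associated with age, sex, the
#' age-by-sex interaction, and the subject's global measure (mean ROI value:
#' mean cortical thickness or mean gyrification), leaving the residuals the
#' correlation matrix is built from.
#'
#' @param morph Morphometry data.frame (`subject_id`, `group`, `age`,
#'   `sex`, then ROI columns), e.g. from [generate_morphometry()] or
#'   [read_morphometry()].
#' @param group Optional group label; when given, only that group's rows
#'   are used.
#' @param global Optional numeric vector overriding the per-subject global
#'   measure (defaults to the row mean over ROI columns).
#' @return Subjects x ROIs residual matrix with attribute `n_subjects`.
#' @export
residualize_rois <- function(morph, group = NULL, global = NULL) {
  if (!is.null(group)) morph <- morph[morph$group == group, , drop = FALSE]
  rois <- roi_columns(morph)
  n <- nrow(morph)
  if (n < 5) stop("need at least 5 subjects to residualize on 5 regressors")
  Y <- as.matrix(morph[rois])
  if (is.null(global)) global <- rowMeans(Y)
  X <- cbind(intercept = 1, age = morph$age, sex = morph$sex,
             age_sex = morph$age * morph$sex, global = global)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_ix <- qx$pivot[(qx$rank + 1):ncol(X)]
    stop("collinear design columns: ", paste(colnames(X)[drop_ix], collapse = ", "))
  }
  res <- qr.resid(qx, Y)
  rownames(res) <- morph$subject_id
  attr(res, "n_subjects") <- n
  res
}

#' Pearson correlation matrix of ROI residuals
#'
#' @param res Subjects x ROIs residual matrix (>= 4 rows).
#' @return ROI x ROI correlation matrix with unit diagonal and attribute
#'   `n_subjects`. Constant columns (undefined correlations) are flagged
#'   with a warning and their correlations set to 0.
#' @export
correlation_matrix <- function(res) {
  res <- as.matrix(res)
  n <- nrow(res)
  if (n < 4) stop("need at least 4 subjects for a correlation network")
  const <- apply(res, 2, function(x) stats::var(x) == 0)
  r <- suppressWarnings(cor(res))
  if (any(const)) {
    warning("constant ROI column(s) set to zero correlation: ",
            paste(colnames(res)[const], collapse = ", "))
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "n_subjects") <- n
  r
}

#' Edge eligibility: significant positive correlations
#'
#' An ROI pair is eligible to become an edge iff its correlation is
#' positive and significant at `alpha` under the usual two-sided t-test,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df. Negative correlations
#' are never eligible.
#'
#' @param corr Correlation matrix from [correlation_matrix()] (or any
#'   symmetric matrix plus `n`).
#' @param alpha Significance level (default 0.05).
#' @param n Number of subjects; defaults to `attr(corr, "n_subjects")`.
#' @return Logical ROI x ROI mask (diagonal FALSE).
#' @export
edge_eligibility <- function(corr, alpha = 0.05, n = attr(corr, "n_subjects")) {
  if (is.null(n)) stop("supply n (subjects used for the correlations)")
  if (n < 4) stop("need at least 4 subjects")
  rc <- critical_r(n, alpha)
  mask <- corr > 0 & corr > rc
  diag(mask) <- FALSE
  mask
}

# smallest positive r significant at alpha (two-sided) for sample size n
critical_r <- function(n, alpha) {
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# eligible upper-triangle edges ordered by decreasing r, ties broken
# lexicographically by (row, column) index
edge_ranking <- function(corr, mask) {
  ut <- upper.tri(corr)
  keep <- which(ut & mask, arr.ind = TRUE)
  r <- corr[keep]
  ord <- order(-r, keep[, 1], keep[, 2])
  list(i = keep[ord, 1], j = keep[ord, 2], r = r[ord])
}

#' Threshold a correlation matrix at a target density
#'
#' Retains the `m = round(density * R * (R - 1) / 2)` eligible edges with
#' the largest correlations (ties broken by ROI index, so the edge set is
#' deterministic). If fewer eligible edges exist, all are kept and a
#' warning reports the achieved density.
#'
#' @param corr Correlation matrix.
#' @param mask Eligibility mask from [edge_eligibility()].
#' @param density Target density in (0, 0.5].
#' @return Binary symmetric adjacency matrix with zero diagonal and
#'   attribute `density_achieved`.
#' @export
threshold_by_density <- function(corr, mask, density) {
  if (density <= 0) stop("density must be positive")
  if (density > 0.5)
    warning("densities above 0.5 approach a random configuration")
  R <- nrow(corr)
  npairs <- R * (R - 1) / 2
  m <- round_half_up(density * npairs)
  ed <- edge_ranking(corr, mask)
  avail <- length(ed$r)
  if (avail < m) {
    warning(sprintf("only %d eligible edges for requested %d (achieved density %.4f)",
                    avail, m, avail / npairs))
    m <- avail
  }
  adj <- matrix(0L, R, R, dimnames = dimnames(corr))
  if (m > 0) {
    ii <- ed$i[seq_len(m)]; jj <- ed$j[seq_len(m)]
    adj[cbind(ii, jj)] <- 1L
    adj[cbind(jj, ii)] <- 1L
  }
  attr(adj, "density_achieved") <- m / npairs
  adj
}

#' Evenly spaced density grid
#'
#' @param d_min,d_max Grid end points in (0, 0.5].
#' @param step Grid step (default 0.01); ignored when `n_points` is given.
#' @param n_points Optional number of evenly spaced points.
#' @return Increasing numeric vector of densities.
#' @export
density_grid <- function(d_min, d_max, step = 0.01, n_points = NULL) {
  stopifnot(d_min > 0, d_min <= d_max, d_max <= 0.5)
  g <- if (!is.null(n_points)) seq(d_min, d_max, length.out = n_points)
       else seq(d_min, d_max, by = step)
  round(g, 10)
}

#' Smallest density rendering every group's graph fully connected
#'
#' Scans densities from `floor` upward in steps of `increment` and returns
#' the first at which each group's thresholded graph has exactly one
#' connected component.
#'
#' @param corr_list List of per-group correlation matrices.
#' @param mask_list List of per-group eligibility masks (same order).
#' @param floor,increment,d_max Scan parameters (defaults 0.01 / 0.01 / 0.5).
#' @return The minimum density. Errors, reporting per-group component
#'   counts at `d_max`, if no density up to `d_max` connects all groups.
#' @export
find_min_density <- function(corr_list, mask_list, floor = 0.01,
                             increment = 0.01, d_max = 0.5) {
  stopifnot(length(corr_list) >= 1, length(corr_list) == length(mask_list))
  grid <- seq(floor, d_max, by = increment)
  ranks <- Map(edge_ranking, corr_list, mask_list)
  R <- nrow(corr_list[[1]])
  npairs <- R * (R - 1) / 2
  comp_at <- function(rank, d) {
    m <- min(round_half_up(d * npairs), length(rank$r))
    adj <- matrix(0L, R, R)
    if (m > 0) {
      adj[cbind(rank$i[seq_len(m)], rank$j[seq_len(m)])] <- 1L
      adj[cbind(rank$j[seq_len(m)], rank$i[seq_len(m)])] <- 1L
    }
    cpp_n_components(adj)
  }
  for (d in grid) {
    ncomp <- vapply(ranks, comp_at, numeric(1), d = d)
    if (all(ncomp == 1)) return(d)
  }
  ncomp <- vapply(ranks, comp_at, numeric(1), d = d_max)
  stop("no density <= ", d_max, " yields fully connected graphs in all groups; ",
       "components at d_max: ", paste(ncomp, collapse = ", "))
}

#' Build a group's binary network stack over a density grid
#'
#' @param corr Correlation matrix for one group.
#' @param mask Eligibility mask.
#' @param densities Density grid (see [density_grid()]).
#' @param group Optional group label carried through.
#' @return Object of class `"scn_stack"`: the correlation matrix, mask,
#'   densities, and the list of binary adjacency matrices (nested across
#'   densities by construction).
#' @export
build_group_networks <- function(corr, mask, densities, group = NULL) {
  stopifnot(all(densities > 0), !is.unsorted(densities, strictly = TRUE))
  adjacency <- lapply(densities, function(d)
    threshold_by_density(corr, mask, d))
  out <- list(group = group, corr = corr, mask = mask,
              densities = densities, adjacency = adjacency,
              n_subjects = attr(corr, "n_subjects"))
  class(out) <- "scn_stack"
  out
}

#' @export
print.scn_stack <- function(x, ...) {
  cat(sprintf("network stack%s: %d ROIs, %d densities [%.3f, %.3f], n = %s\n",
              if (is.null(x$group)) "" else paste0(" (group ", x$group, ")"),
              nrow(x$corr), length(x$densities), min(x$densities),
              max(x$densities),
              if (is.null(x$n_subjects)) "?" else x$n_subjects))
  invisible(x)
}
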