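# Synthetic multi-group cohorts with planted covariance topology.
#
# Generative law: ROIs sit on a ring partitioned into K contiguous blocks;
# each block contributes a latent factor whose loading is a triangular bump
# centred on the block and overlapping its neighbours. Loadings are
# row-normalized, so ROI i's correlation with ROI j is v * (u_i . u_j),
# where v is the factor variance share. The bump half-width and v are
# calibrated per group so that the MEAN correlation within blocks equals
# within_block_r and the MEAN correlation between blocks equals
# between_block_r. The overlap zones matter: they emulate the covariance
# gradients that keep real structural covariance networks connected after
# the pipeline regresses out the subject's global measure (a hard-edged
# block model loses all its cross-block structure to that regression and
# can never form a fully connected positive network).

# triangular ring loadings for a block partition; returns NULL if the
# half-width W leaves some ROI with zero loading
ring_loadings <- function(partition, W) {
  R <- length(partition)
  ord <- order(partition, seq_along(partition))
  pos <- numeric(R)
  pos[ord] <- (seq_len(R) - 0.5) / R
  blocks <- sort(unique(partition))
  centers <- vapply(blocks, function(k) mean(range(pos[partition == k])),
                    numeric(1))
  lam <- vapply(centers, function(c0) {
    d <- abs(pos - c0)
    pmax(0, 1 - pmin(d, 1 - d) / W)
  }, numeric(R))
  lam <- matrix(lam, nrow = R)
  nrm <- sqrt(rowSums(lam^2))
  if (any(nrm == 0)) return(NULL)
  lam / nrm
}

# mean loading dot-products within and between blocks
overlap_means <- function(U, partition) {
  D <- U %*% t(U)
  ut <- upper.tri(D)
  same <- outer(partition, partition, "==")
  c(same = mean(D[ut & same]), diff = mean(D[ut & !same]))
}

# solve bump half-width W and variance share v so that mean within-block
# correlation = w and mean between-block correlation = b
calibrate_blocks <- function(partition, w, b) {
  R <- length(partition)
  sizes <- table(partition)
  K <- length(sizes)
  if (K == 1 || w == 0) {
    U <- ring_loadings(partition, W = 0.5)
    return(list(U = U, v = w, W = 0.5))
  }
  w_min <- max(sizes) / (2 * R)           # smallest width covering own block
  rho_target <- b / w
  rho_of <- function(W) {
    U <- ring_loadings(partition, W)
    if (is.null(U)) return(NA_real_)
    m <- overlap_means(U, partition)
    m["diff"] / m["same"]
  }
  W <- if (b == 0) w_min else {
    hi <- 0.5
    if (rho_of(hi) < rho_target)
      stop(sprintf(paste0("between_block_r = %.3f is too large relative to ",
                          "within_block_r = %.3f for %d blocks (max feasible ",
                          "ratio %.2f)"), b, w, K, rho_of(hi)))
    stats::uniroot(function(W) rho_of(W) - rho_target,
                   lower = w_min * (1 + 1e-9), upper = hi,
                   tol = 1e-10)$root
  }
  U <- ring_loadings(partition, W)
  m <- overlap_means(U, partition)
  v <- w / m[["same"]]
  if (v > 1)
    stop(sprintf(paste0("within_block_r = %.3f with between_block_r = %.3f ",
                        "needs factor variance share %.2f > 1; target ",
                        "correlation not attainable"), w, b, v))
  list(U = U, v = v, W = W)
}

#' Specify a synthetic morphometry cohort
#'
#' Defines the study conditions for [generate_morphometry()]: group sizes,
#' ROI count, the planted block partition and its within/between-block
#' target mean correlations (per group), linear covariate effects, and the
#' per-ROI scale. The planted correlation structure is a ring of
#' overlapping block factors (see [target_correlation()]); overlap is
#' calibrated so the mean within-block and between-block correlations hit
#' the requested targets.
#'
#' @param n_groups Number of groups (cognitive clusters) to simulate.
#' @param group_sizes Integer vector of subjects per group (each >= 4 so
#'   correlation p-values are defined).
#' @param n_rois Number of ROIs; 148 matches the Destrieux parcellation and
#'   gets Destrieux ROI names, other counts get generic names.
#' @param n_blocks Number of planted covariance blocks; ignored when
#'   `block_partition` is given.
#' @param block_partition Integer vector of length `n_rois` assigning each
#'   ROI to a block. Default: `n_blocks` contiguous blocks of near-equal
#'   size.
#' @param within_block_r,between_block_r Target mean Pearson correlation
#'   inside / across blocks, recycled to one value per group. Must satisfy
#'   `0 <= between_block_r <= within_block_r < 1`, and the pair must be
#'   attainable by the overlap model (checked; errors name the offending
#'   values).
#' @param covariate_effects List with elements `age`, `sex`, `age_sex`:
#'   linear coefficients on each ROI (scalar or length-`n_rois`). Units are
#'   measure units per year, per unit sex code, and per year-by-sex.
#' @param noise_sd Per-ROI standard deviation of the measure (mm for
#'   cortical thickness, unitless for gyrification).
#' @param baseline Mean ROI value (default 2.5, a typical cortical
#'   thickness in mm).
#' @param age_range Ages are drawn uniformly on this range (years).
#' @param p_male Probability of sex code 1; the default 0.8 mirrors a
#'   predominantly male cohort.
#' @param seed Integer master seed; per-group child seeds are derived
#'   deterministically from it.
#' @return An object of class `"cohort_spec"`.
#' @seealso [generate_morphometry()], [plant_topology_contrast()]
#' @export
cohort_spec <- function(n_groups = 3, group_sizes = rep(60L, n_groups),
                        n_rois = 148L, n_blocks = 4L, block_partition = NULL,
                        within_block_r = 0.6, between_block_r = 0.25,
                        covariate_effects = list(age = -0.005, sex = 0.02,
                                                 age_sex = 0),
                        noise_sd = 0.10, baseline = 2.5,
                        age_range = c(25, 60), p_male = 0.8, seed = 1L) {
  stopifnot(n_groups >= 1, length(group_sizes) == n_groups, n_rois >= 2)
  if (any(group_sizes < 4))
    stop("all group sizes must be >= 4 (correlation p-values undefined below)")
  if (is.null(block_partition)) {
    stopifnot(n_blocks >= 1, n_blocks <= n_rois)
    block_partition <- sort(rep_len(seq_len(n_blocks), n_rois))
  }
  stopifnot(length(block_partition) == n_rois, !anyNA(block_partition))
  within_block_r <- rep_len(within_block_r, n_groups)
  between_block_r <- rep_len(between_block_r, n_groups)
  for (g in seq_len(n_groups)) {
    wr <- within_block_r[g]; br <- between_block_r[g]
    if (!(wr >= br && br >= 0 && wr < 1))
      stop(sprintf(paste0("group %d: need 0 <= between_block_r (%.3f) <= ",
                          "within_block_r (%.3f) < 1"), g, br, wr))
  }
  loadings <- lapply(seq_len(n_groups), function(g)
    calibrate_blocks(block_partition, within_block_r[g], between_block_r[g]))
  eff <- lapply(covariate_effects[c("age", "sex", "age_sex")],
                function(x) rep_len(if (is.null(x)) 0 else x, n_rois))
  spec <- list(n_groups = n_groups, group_sizes = as.integer(group_sizes),
               n_rois = as.integer(n_rois),
               block_partition = as.integer(block_partition),
               within_block_r = within_block_r,
               between_block_r = between_block_r,
               loadings = loadings,
               covariate_effects = eff, noise_sd = noise_sd,
               baseline = baseline, age_range = age_range, p_male = p_male,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Target ROI correlation matrix planted for one group
#'
#' The factor-model correlation `v * U U'` (unit diagonal), where `U` holds
#' the row-normalized ring loadings and `v` the group's factor variance
#' share. Positive semi-definite by construction; mean within-block and
#' between-block entries equal the spec's `within_block_r` and
#' `between_block_r`.
#'
#' @param spec A [cohort_spec()].
#' @param group Group index.
#' @return The `n_rois` x `n_rois` target correlation matrix.
#' @export
target_correlation <- function(spec, group) {
  stopifnot(inherits(spec, "cohort_spec"), group >= 1, group <= spec$n_groups)
  ld <- spec$loadings[[group]]
  R <- ld$v * (ld$U %*% t(ld$U))
  diag(R) <- 1
  R
}

# deterministic 32-bit child seed per group
child_seed <- function(seed, group) {
  as.integer((as.numeric(seed) * 1009 + 7919 * group) %% 2147483647)
}

#' Generate a synthetic morphometry cohort
#'
#' Draws, for each group, subjects-by-ROI values from the multivariate
#' normal with the planted factor-model correlation
#' ([target_correlation()]), scaled by `noise_sd`, plus linear age, sex and
#' age-by-sex effects; covariates (age uniform on `spec$age_range`, sex
#' Bernoulli(`spec$p_male`)) are attached. Deterministic given
#' `spec$seed`: R's default Mersenne-Twister generator is seeded with a
#' per-group child seed.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns `subject_id`, `group`, `age`, `sex`,
#'   then one column per ROI. Ground truth for tests rides along as
#'   attributes `target_corr` (list of per-group matrices) and
#'   `block_partition`.
#' @examples
#' spec <- cohort_spec(n_groups = 2, group_sizes = c(30, 30), n_rois = 20,
#'                     n_blocks = 2, seed = 7)
#' morph <- generate_morphometry(spec)
#' dim(morph)
#' @export
generate_morphometry <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  roi_names <- if (spec$n_rois == 148L) destrieux_rois()
               else sprintf("ROI_%03d", seq_len(spec$n_rois))
  out <- vector("list", spec$n_groups)
  targets <- vector("list", spec$n_groups)
  for (g in seq_len(spec$n_groups)) {
    n <- spec$group_sizes[g]
    ld <- spec$loadings[[g]]
    targets[[g]] <- target_correlation(spec, g)
    K <- ncol(ld$U)
    set.seed(child_seed(spec$seed, g))
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- rbinom(n, 1, spec$p_male)
    FK <- matrix(rnorm(n * K), n, K)
    E <- matrix(rnorm(n * spec$n_rois), n, spec$n_rois)
    Z <- sqrt(ld$v) * (FK %*% t(ld$U)) + sqrt(1 - ld$v) * E
    Y <- spec$baseline + spec$noise_sd * Z
    eff <- spec$covariate_effects
    Y <- Y + outer(age, eff$age) + outer(sex, eff$sex) +
      outer(age * sex, eff$age_sex)
    colnames(Y) <- roi_names
    out[[g]] <- data.frame(
      subject_id = sprintf("G%d_S%03d", g, seq_len(n)),
      group = g, age = age, sex = sex, Y,
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  morph <- do.call(rbind, out)
  rownames(morph) <- NULL
  attr(morph, "target_corr") <- targets
  attr(morph, "block_partition") <- setNames(spec$block_partition, roi_names)
  morph
}

#' Raise one group's within-block correlation
#'
#' Returns a spec identical to `base` except that `target_group`'s
#' within-block correlation is increased by `delta_within_r`, planting the
#' segregation/integration contrast the comparison stage is meant to
#' detect: at fixed network density, stronger within-block covariance
#' concentrates edges inside blocks, raising clustering and transitivity
#' while lengthening between-block paths and lowering global efficiency.
#'
#' @param base A [cohort_spec()].
#' @param delta_within_r Amount to add to the target group's within-block
#'   correlation; the result must stay below 1.
#' @param target_group Index of the group to modify.
#' @return A new `cohort_spec`.
#' @export
plant_topology_contrast <- function(base, delta_within_r, target_group) {
  stopifnot(inherits(base, "cohort_spec"),
            target_group >= 1, target_group <= base$n_groups)
  new_r <- base$within_block_r[target_group] + delta_within_r
  if (new_r >= 1)
    stop(sprintf("within_block_r would become %.3f >= 1 for group %d",
                 new_r, target_group))
  wr <- base$within_block_r
  wr[target_group] <- new_r
  cohort_spec(n_groups = base$n_groups, group_sizes = base$group_sizes,
              n_rois = base$n_rois, block_partition = base$block_partition,
              within_block_r = wr, between_block_r = base$between_block_r,
              covariate_effects = base$covariate_effects,
              noise_sd = base$noise_sd, baseline = base$baseline,
              age_range = base$age_range, p_male = base$p_male,
              seed = base$seed)
}

#' Specify synthetic cognitive test scores
#'
#' @param centroids K x 6 matrix of per-cluster mean scores in z-units, one
#'   column per test. Rows must be pairwise distinct. The default plants
#'   three profiles: high-functioning, average-with-executive-weakness, and
#'   globally low with relatively spared decision-making.
#' @param within_cluster_sd Within-cluster standard deviation per test
#'   (scalar or length 6); must be > 0.
#' @param age_effect,education_effect Linear coefficients per test (z-units
#'   per year), applied to centred age/education.
#' @param age_range,education_range Uniform sampling ranges (years).
#' @param seed Integer seed.
#' @return An object of class `"cognitive_spec"`.
#' @export
cognitive_spec <- function(centroids = NULL, within_cluster_sd = 0.7,
                           age_effect = 0, education_effect = 0,
                           age_range = c(25, 60), education_range = c(8, 16),
                           seed = 1L) {
  tests <- cognitive_tests()
  if (is.null(centroids)) {
    centroids <- rbind(
      c(0.8,  0.8,  0.6,  0.7,  0.7,  0.3),
      c(0.0,  0.1,  0.0,  0.0, -0.7, -0.4),
      c(-0.8, -0.9, -0.7, -0.8, -0.6,  0.3))
  }
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 6) stop("centroids must have 6 columns (tests)")
  colnames(centroids) <- tests
  if (nrow(unique(centroids)) < nrow(centroids))
    stop("centroid rows must be pairwise distinct")
  within_cluster_sd <- rep_len(within_cluster_sd, 6)
  if (any(within_cluster_sd <= 0)) stop("within_cluster_sd must be > 0")
  spec <- list(centroids = centroids,
               within_cluster_sd = within_cluster_sd,
               age_effect = rep_len(age_effect, 6),
               education_effect = rep_len(education_effect, 6),
               age_range = age_range, education_range = education_range,
               tests = tests, seed = as.integer(seed))
  class(spec) <- "cognitive_spec"
  spec
}

#' Generate synthetic cognitive scores with known cluster structure
#'
#' Scores are cluster centroid plus linear (centred) age and education
#' effects plus Gaussian noise. True cluster labels are returned in the
#' `cluster_true` column for recovery testing.
#'
#' @param spec A [cognitive_spec()].
#' @param group_sizes Subjects per true cluster (length = rows of
#'   `spec$centroids`, all > 0).
#' @return Data.frame with `subject_id`, `cluster_true`, `age`, `education`
#'   and the six test columns.
#' @export
generate_cognitive <- function(spec, group_sizes) {
  stopifnot(inherits(spec, "cognitive_spec"))
  k <- nrow(spec$centroids)
  if (length(group_sizes) != k) stop("need one group size per centroid row")
  if (any(group_sizes <= 0)) stop("all cluster sizes must be > 0")
  set.seed(spec$seed)
  n <- sum(group_sizes)
  lab <- rep(seq_len(k), times = group_sizes)
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  edu <- runif(n, spec$education_range[1], spec$education_range[2])
  age_c <- age - mean(spec$age_range)
  edu_c <- edu - mean(spec$education_range)
  scores <- spec$centroids[lab, , drop = FALSE] +
    outer(age_c, spec$age_effect) + outer(edu_c, spec$education_effect) +
    matrix(rnorm(n * 6), n, 6) %*% diag(spec$within_cluster_sd)
  colnames(scores) <- spec$tests
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             cluster_true = lab, age = age, education = edu, scores,
             check.names = FALSE, stringsAsFactors = FALSE)
}
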