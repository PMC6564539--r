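# Cognitive subtyping: transform -> impute -> residualize on age/education
# -> z-score -> k-means.

#' Log-transform and sign-flip an error count score
#'
#' Set-shifting error counts are strongly right-skewed; they are
#' log-transformed and multiplied by -1 so that, like the other tests,
#' higher values mean better performance. Base 10 with a +1 offset is used
#' so that zero errors map to zero.
#'
#' @param errors Non-negative numeric vector of error counts.
#' @param offset Added before the log so zero counts are defined.
#' @param base Logarithm base.
#' @return `-log(errors + offset, base)`, same length as input.
#' @examples
#' transform_ided(c(0, 9, 99))  # 0, -1, -2
#' @export
transform_ided <- function(errors, offset = 1, base = 10) {
  if (any(errors < 0, na.rm = TRUE))
    stop("error counts must be non-negative")
  -log(errors + offset, base = base)
}

#' Impute at most one missing test score per subject
#'
#' Subjects missing more than `max_missing` tests are dropped (the
#' inclusion rule); a single missing score is replaced by the prediction of
#' an OLS regression of that test on age and education fitted on complete
#' cases.
#'
#' @param tbl Data.frame with `age`, `education` and the test columns.
#' @param tests Character vector of test column names.
#' @param max_missing Maximum missing tests tolerated per subject.
#' @return `tbl` with missing scores imputed and excluded subjects removed;
#'   the number dropped is reported via `attr(, "n_dropped")`.
#' @export
impute_cognitive <- function(tbl, tests = cognitive_tests(), max_missing = 1) {
  stopifnot(all(tests %in% names(tbl)), all(c("age", "education") %in% names(tbl)))
  miss <- rowSums(is.na(tbl[tests]))
  dropped <- sum(miss > max_missing)
  tbl <- tbl[miss <= max_missing, , drop = FALSE]
  for (tv in tests) {
    na <- is.na(tbl[[tv]])
    if (!any(na)) next
    fit <- stats::lm(y ~ age + education,
                     data = data.frame(y = tbl[[tv]], age = tbl$age,
                                       education = tbl$education))
    tbl[[tv]][na] <- stats::predict(fit, newdata = tbl[na, c("age", "education")])
  }
  attr(tbl, "n_dropped") <- dropped
  tbl
}

#' Canonical cognitive test battery column names
#' @return Character vector of the six test column names used throughout.
#' @export
cognitive_tests <- function() {
  c("premorbid_fsiq", "hvlt_immediate", "rvip_aprime",
    "stroop_cw", "ided_total", "igt_net")
}

#' Residualize test scores on age and education
#'
#' Each test column is replaced by the residuals of an OLS fit on intercept
#' + age + education. Residuals are exactly orthogonal to both covariates.
#'
#' @param tbl Data.frame with `age`, `education` and the test columns
#'   (complete; see [impute_cognitive()]).
#' @param tests Test column names.
#' @return Numeric matrix (subjects x tests) of residuals, with
#'   `rownames` = `tbl$subject_id` when present.
#' @export
residualize_scores <- function(tbl, tests = cognitive_tests()) {
  stopifnot(all(tests %in% names(tbl)))
  if (anyNA(tbl[tests])) stop("missing scores; run impute_cognitive() first")
  X <- cbind(1, age = tbl$age, education = tbl$education)
  qx <- qr(X)
  if (qx$rank < 2)
    stop("rank-deficient design: age and education are both constant")
  Y <- as.matrix(tbl[tests])
  res <- qr.resid(qx, Y)
  rownames(res) <- if (!is.null(tbl$subject_id)) tbl$subject_id
  res
}

#' k-means cognitive profiles on residualized scores
#'
#' Columns are z-scored (the tests are on incommensurate scales) and
#' partitioned by Euclidean k-means with multiple random restarts. Cluster
#' labels are relabelled deterministically by descending mean z-profile, so
#' cluster 1 is always the highest-functioning profile. If the k-means fit
#' degenerates (empty cluster), it is re-run with the next restart seed.
#'
#' @param residuals Subjects x tests matrix from [residualize_scores()].
#' @param k Number of clusters (>= 1; `n >= k` required).
#' @param nstart Random restarts handed to [stats::kmeans()].
#' @param seed Integer seed controlling the restarts.
#' @param scale_cols Z-score columns first (default TRUE).
#' @return List of class `"scn_clusters"`: `cluster` (integer labels named
#'   by subject), `centers` (k x tests, residual space), `z_profile`
#'   (k x tests mean z-scores, sample-referenced), `sizes`, `wcss`
#'   (total within-cluster sum of squares), `tss`, and `seed_used`.
#' @export
kmeans_profiles <- function(residuals, k = 3, nstart = 50, seed = 1L,
                            scale_cols = TRUE) {
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  stopifnot(k >= 1, n >= k)
  Z <- scale(residuals)
  # a column with zero variance carries no information; keep it as zeros
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  X <- if (scale_cols) Z else residuals
  fit <- NULL
  seed_used <- seed
  for (attempt in 0:4) {
    seed_used <- seed + attempt
    set.seed(seed_used)
    fit <- tryCatch(
      stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && all(fit$size > 0)) break
  }
  if (is.null(fit)) stop("k-means failed to converge after 5 restart seeds")
  # relabel by descending mean profile (cluster 1 = best overall function)
  zc <- rowsum(Z, fit$cluster) / as.vector(table(fit$cluster))
  ord <- order(rowMeans(zc), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  cl <- relabel[fit$cluster]
  names(cl) <- rownames(residuals)
  zp <- rowsum(Z, cl) / as.vector(table(cl))
  centers <- rowsum(residuals, cl) / as.vector(table(cl))
  rownames(zp) <- rownames(centers) <- seq_len(k)
  out <- list(cluster = cl, centers = centers, z_profile = zp,
              sizes = as.vector(table(cl)), wcss = fit$tot.withinss,
              tss = fit$totss, k = k, seed_used = seed_used)
  class(out) <- "scn_clusters"
  out
}

#' @export
print.scn_clusters <- function(x, ...) {
  cat(sprintf("k-means cognitive profiles: k = %d, sizes = %s, WCSS = %.3f\n",
              x$k, paste(x$sizes, collapse = "/"), x$wcss))
  cat("mean z-profiles (cluster 1 = highest functioning):\n")
  print(round(x$z_profile, 2))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions, 1 for identical
#' partitions and ~0 for independent ones. Used to score recovery of
#' planted cluster structure.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
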