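# ROI residualization, correlation, eligibility, density thresholding and
# minimum-density search.

make_morph <- function(n, R, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%02d", 1:n), group = 1,
             age = runif(n, 25, 60), sex = rep_len(c(0, 1, 1, 1), n),
             matrix(rnorm(n * R), n, R,
                    dimnames = list(NULL, sprintf("ROI_%02d", 1:R))),
             check.names = FALSE)
}

test_that("ROI residualization matches a brute-force normal-equations fit", {
  m <- make_morph(6, 4, seed = 2)
  res <- residualize_rois(m)
  Y <- as.matrix(m[, -(1:4)])
  X <- cbind(1, m$age, m$sex, m$age * m$sex, rowMeans(Y))
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(unname(res), unname(Y - X %*% beta), tolerance = 1e-10,
               ignore_attr = TRUE)
  # orthogonality to every design column
  expect_lt(max(abs(t(X) %*% res)), 1e-8)
})

test_that("an ROI equal to the global measure residualizes to zero", {
  m <- make_morph(10, 3, seed = 3)
  g <- rowMeans(as.matrix(m[, -(1:4)]))
  m$ROI_01 <- g
  res <- residualize_rois(m, global = g)
  expect_lt(max(abs(res[, "ROI_01"])), 1e-10)
})

test_that("collinear designs are rejected naming the columns", {
  m <- make_morph(10, 3, seed = 4)
  m$sex <- 1  # sex constant makes age_sex collinear with age
  expect_error(residualize_rois(m), "collinear")
  expect_error(residualize_rois(make_morph(4, 3)), "5 subjects")
})

test_that("correlation matrix matches the textbook formula", {
  set.seed(5)
  x <- matrix(rnorm(15), 5, 3)
  cm <- correlation_matrix(x)
  for (i in 1:3) for (j in 1:3) {
    num <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j])))
    den <- sqrt(sum((x[, i] - mean(x[, i]))^2) * sum((x[, j] - mean(x[, j]))^2))
    expect_equal(cm[i, j], num / den, tolerance = 1e-12)
  }
  y <- cbind(x, x[, 1], -x[, 2])
  cm2 <- correlation_matrix(y)
  expect_equal(cm2[1, 4], 1)
  expect_equal(cm2[2, 5], -1)
  expect_error(correlation_matrix(x[1:3, ]), "at least 4")
  const <- x; const[, 2] <- 7
  expect_warning(cm3 <- correlation_matrix(const), "constant")
  expect_true(all(cm3[2, -2] == 0))
})

test_that("edge eligibility applies the positive significant-r rule", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.3
  r[1, 3] <- r[3, 1] <- -0.9
  r[2, 3] <- r[3, 2] <- 0
  # r = 0.3, n = 67: t = 2.5355 on 65 df, p = 0.0137 < .05 (t-CDF oracle)
  tval <- 0.3 * sqrt(65 / (1 - 0.09))
  expect_equal(tval, 2.5355, tolerance = 1e-4)
  expect_lt(2 * pt(-tval, 65), 0.05)
  mask <- edge_eligibility(r, n = 67)
  expect_true(mask[1, 2])
  expect_false(mask[1, 3])   # negative, however strong
  expect_false(mask[2, 3])   # r = 0 has p = 1
  # just-below-threshold r is ineligible
  r[1, 2] <- r[2, 1] <- 0.2
  expect_false(edge_eligibility(r, n = 67)[1, 2])
})

test_that("density thresholding keeps the right edge count", {
  set.seed(6)
  R <- 148
  r <- matrix(runif(R * R, 0.3, 0.9), R, R)
  r <- (r + t(r)) / 2; diag(r) <- 1
  mask <- matrix(TRUE, R, R); diag(mask) <- FALSE
  adj <- threshold_by_density(r, mask, 0.07)
  expect_equal(sum(adj) / 2, 761)  # round(0.07 * 148*147/2) = round(761.46)
  expect_true(all(adj == t(adj)))
  expect_true(all(diag(adj) == 0))
  # m = 1: the single largest eligible r survives
  tiny <- threshold_by_density(r, mask, 1 / (R * (R - 1) / 2))
  expect_equal(sum(tiny) / 2, 1)
  ix <- which(upper.tri(r) & tiny == 1)
  expect_equal(r[ix], max(r[upper.tri(r)]))
  expect_error(threshold_by_density(r, mask, 0), "positive")
})

test_that("insufficient eligible edges cap the density with a warning", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.9
  r[3, 4] <- r[4, 3] <- 0.8
  mask <- r > 0.5 & !diag(4)
  expect_warning(adj <- threshold_by_density(r, mask, 0.5), "eligible")
  expect_equal(sum(adj) / 2, 2)
  expect_equal(attr(adj, "density_achieved"), 2 / 6)
})

test_that("ties at the cut are broken lexicographically and deterministically", {
  R <- 6
  r <- matrix(0.5, R, R); diag(r) <- 1  # all off-diagonal r identical
  mask <- matrix(TRUE, R, R); diag(mask) <- FALSE
  adj1 <- threshold_by_density(r, mask, 0.2)   # m = 3 of 15
  adj2 <- threshold_by_density(r, mask, 0.2)
  expect_identical(adj1, adj2)
  # lexicographic (row, col) order keeps (1,2), (1,3), (1,4)
  expect_equal(which(adj1[1, ] == 1), 2:4)
  expect_equal(sum(adj1) / 2, 3)
})

test_that("edge sets are nested across the density grid", {
  set.seed(7)
  m <- small_cohort(seed = 7, n_rois = 40, n = 50, groups = 1)
  morph <- generate_morphometry(m)
  cr <- correlation_matrix(residualize_rois(morph, 1))
  msk <- edge_eligibility(cr)
  stack <- build_group_networks(cr, msk, seq(0.1, 0.4, by = 0.05))
  for (k in 2:length(stack$adjacency))
    expect_true(all(stack$adjacency[[k - 1]] <= stack$adjacency[[k]]))
  # achieved density within one edge of requested where eligibility permits
  npairs <- 40 * 39 / 2
  ach <- vapply(stack$adjacency, function(a) sum(a) / 2 / npairs, numeric(1))
  ok <- ach <= stack$densities + 1e-9
  expect_true(all(ok))
  expect_true(all(abs(ach - stack$densities)[ach < max(ach)] <= 1 / npairs + 1e-9))
})

test_that("construction is invariant to per-ROI affine rescaling", {
  m <- make_morph(30, 8, seed = 8)
  g <- rowMeans(as.matrix(m[, -(1:4)]))
  scl <- runif(8, 0.5, 3); off <- runif(8, -2, 2)
  m2 <- m
  for (k in 1:8) m2[[k + 4]] <- m2[[k + 4]] * scl[k] + off[k]
  cr1 <- correlation_matrix(residualize_rois(m, global = g))
  cr2 <- correlation_matrix(residualize_rois(m2, global = g))
  expect_equal(cr1, cr2, tolerance = 1e-10)
  msk <- edge_eligibility(cr1)
  expect_identical(threshold_by_density(cr1, msk, 0.3),
                   threshold_by_density(cr2, edge_eligibility(cr2), 0.3))
})

test_that("minimum density matches hand enumeration on a 4-node matrix", {
  r <- diag(4)
  r[1, 2] <- 0.9; r[1, 3] <- 0.8; r[1, 4] <- 0.7
  r[2, 3] <- 0.6; r[2, 4] <- 0.5; r[3, 4] <- 0.4
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  mask <- matrix(TRUE, 4, 4); diag(mask) <- FALSE
  # sorted r: (1,2) (1,3) (1,4) ...; the top-3 star spans all nodes, so the
  # minimum density is the first grid point with round(6 d) >= 3, i.e. 0.42
  d <- find_min_density(list(r), list(mask), floor = 0.01, increment = 0.01)
  expect_equal(round_half_up(d * 6), 3)
  expect_equal(d, 0.42)
})

test_that("a block-diagonal matrix with no cross-block eligibility is rejected", {
  r <- diag(6)
  r[1:3, 1:3] <- 0.9; r[4:6, 4:6] <- 0.9; diag(r) <- 1
  mask <- r > 0.5; diag(mask) <- FALSE
  mask[1:3, 4:6] <- FALSE; mask[4:6, 1:3] <- FALSE
  expect_error(find_min_density(list(r), list(mask)), "components")
})

test_that("minimum-density search agrees with a brute-force scan", {
  for (s in 1:10) {
    set.seed(s + 100)
    n <- 30; R <- 20
    x <- matrix(rnorm(n * R), n, R) + rnorm(n) * 0.8  # shared signal
    cr <- correlation_matrix(x)
    msk <- edge_eligibility(cr)
    got <- tryCatch(find_min_density(list(cr), list(msk)),
                    error = function(e) NA_real_)
    # oracle: scan the same grid, connectivity via igraph
    brute <- NA_real_
    for (d in seq(0.01, 0.5, by = 0.01)) {
      adj <- suppressWarnings(threshold_by_density(cr, msk, d))
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      if (igraph::components(g)$no == 1) { brute <- d; break }
    }
    expect_equal(got, brute)
  }
})
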