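# Curve integration, permutation machinery, FDR, hubs and module reports.

test_that("trapezoidal integration matches closed forms and a refinement oracle", {
  g <- seq(0.07, 0.46, length.out = 5)
  expect_equal(fda_integrate(rep(2, 5), g), 2 * 0.39)
  expect_equal(fda_integrate(seq(0, 1, length.out = 6), seq(0, 0.5, length.out = 6)),
               0.25)
  # arbitrary 5-point curve: fine-grid Riemann sum over the linear interpolant
  set.seed(1)
  x <- sort(runif(5, 0.1, 0.4)); y <- rnorm(5)
  fine <- seq(min(x), max(x), length.out = 20001)
  mids <- (fine[-1] + fine[-length(fine)]) / 2
  oracle <- sum(approx(x, y, xout = mids)$y * diff(fine))
  expect_equal(fda_integrate(y, x), oracle, tolerance = 1e-6)
  expect_error(fda_integrate(1, 0.1))
  expect_error(fda_integrate(c(1, 2), c(0.3, 0.2)))
})

test_that("percentile p-values count ties as extreme with +1 correction", {
  expect_equal(percentile_pvalue(5, rep(0, 999)), 1 / 1000)
  expect_gte(percentile_pvalue(0, c(-2, -1, 1, 2)), 0.5)
  expect_equal(percentile_pvalue(1, c(1, 2)), 1)          # tie counts as >=
  expect_equal(percentile_pvalue(-3, c(2, -2)), 1 / 3)     # two-sided on |.|
  nulls <- rnorm(100)
  p <- percentile_pvalue(0.5, nulls)
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("Benjamini-Hochberg step-up matches the hand-computed thresholds", {
  fd <- fdr_correct(c(0.001, 0.02, 0.03, 0.5))
  expect_equal(fd$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_correct(rep(1, 6))$significant, rep(FALSE, 6))
  expect_true(fdr_correct(0.04)$significant)   # m = 1 reduces to raw alpha
  expect_false(fdr_correct(0.06)$significant)
  expect_error(fdr_correct(c(0.5, 0)), "p > 0")
})

test_that("FDA hub rule behaves on constructed node curves", {
  flat <- matrix(5, 10, 2, dimnames = list(letters[1:10],
                                           c("degree", "betweenness")))
  h <- fda_hubs(list(g1 = flat))
  expect_length(h$g1$degree$hubs, 0)
  dom <- flat
  dom["c", ] <- 50  # one dominating node
  h2 <- fda_hubs(list(g1 = dom))
  expect_equal(h2$g1$degree$hubs, "c")
  expect_equal(h2$g1$betweenness$hubs, "c")
  # invariance to positive rescaling of every curve
  h3 <- fda_hubs(list(g1 = dom * 17.3))
  expect_equal(h3$g1$degree$hubs, h2$g1$degree$hubs)
})

test_that("module reports give lobe composition and Jaccard matching", {
  lobes <- c(r1 = "occipital", r2 = "occipital", r3 = "frontal",
             r4 = "frontal", r5 = "parietal")
  mem1 <- c(r1 = 1L, r2 = 1L, r3 = 2L, r4 = 2L, r5 = 2L)
  rep1 <- module_report(list(A = mem1), lobes)
  expect_equal(rep1$n_nodes, c(2, 3))
  expect_equal(rep1$pct_occipital[1], 100)
  expect_equal(rep1$dominant_lobe, c("occipital", "frontal"))
  # identical partitions in two groups match with Jaccard 1
  rep2 <- module_report(list(A = mem1, B = mem1), lobes)
  expect_true(all(rep2$jaccard == 1))
  expect_equal(rep2$matched_module, rep2$module)
  mem_bad <- c(rX = 1L)
  expect_error(module_report(list(mem_bad), lobes), "rX")
})

test_that("planted blocks are recovered as modules at low density", {
  spec <- cohort_spec(n_groups = 1, group_sizes = 80, n_rois = 30,
                      n_blocks = 2, within_block_r = 0.6, between_block_r = 0,
                      covariate_effects = list(age = 0, sex = 0, age_sex = 0),
                      seed = 5)
  m <- generate_morphometry(spec)
  cr <- correlation_matrix(as.matrix(m[, -(1:4)]))
  adj <- suppressWarnings(
    threshold_by_density(cr, edge_eligibility(cr), 0.3))
  ml <- modularity_louvain(adj, seed = 1)
  blk <- attr(m, "block_partition")
  # each planted block is recovered by one detected module
  jac <- vapply(unique(blk), function(kk) {
    members <- names(blk)[blk == kk]
    max(vapply(unique(ml$membership), function(mod) {
      nodes <- names(ml$membership)[ml$membership == mod]
      length(intersect(nodes, members)) / length(union(nodes, members))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(jac >= 0.8))
})

test_that("the comparison engine is deterministic and relabel-invariant", {
  spec <- small_cohort(seed = 31, n_rois = 30, n = 60, groups = 2,
                       w = 0.6, b = 0.25, K = 3)
  m <- generate_morphometry(spec)
  sg <- study_grid(m, margin = 0.08, step = 0.01, npts = 4)
  c1 <- fda_compare(m, m$group, sg$densities, n_perm = 4, seed = 3,
                    regional = TRUE, max_skip_frac = 1)
  c2 <- fda_compare(m, m$group, sg$densities, n_perm = 4, seed = 3,
                    regional = TRUE, max_skip_frac = 1)
  expect_identical(c1$global, c2$global)
  expect_identical(c1$regional, c2$regional)
  # relabeling the groups flips signs but keeps p-values
  relab <- ifelse(m$group == 1, 2, 1)
  c3 <- fda_compare(m, relab, sg$densities, n_perm = 4, seed = 3,
                    regional = FALSE, max_skip_frac = 1)
  expect_equal(c3$global$p, c1$global$p)
  expect_equal(c3$global$fda_diff, -c1$global$fda_diff)
})

test_that("observed results are invariant to subject row order", {
  spec <- small_cohort(seed = 33, n_rois = 30, n = 60, groups = 2,
                       w = 0.6, b = 0.25, K = 3)
  m <- generate_morphometry(spec)
  sg <- study_grid(m, margin = 0.08, step = 0.01, npts = 4)
  set.seed(9)
  shuf <- sample(nrow(m))
  c1 <- fda_compare(m, m$group, sg$densities, n_perm = 0, regional = FALSE)
  c2 <- fda_compare(m[shuf, ], m$group[shuf], sg$densities, n_perm = 0,
                    regional = FALSE)
  expect_equal(c1$auc_global, c2$auc_global, tolerance = 1e-12)
})

test_that("optional modularity and small-world metrics join the comparison", {
  spec <- small_cohort(seed = 35, n_rois = 30, n = 60, groups = 2,
                       w = 0.6, b = 0.25, K = 3)
  m <- generate_morphometry(spec)
  sg <- study_grid(m, margin = 0.08, step = 0.01, npts = 3)
  cmp <- fda_compare(m, m$group, sg$densities, n_perm = 3, seed = 5,
                     metrics = c("clustering", "modularity", "small_world"),
                     regional = FALSE, max_skip_frac = 1,
                     mod_restarts = 2, n_null = 3)
  expect_setequal(unique(cmp$global$metric),
                  c("clustering", "modularity", "small_world"))
  expect_true(all(is.finite(cmp$global$fda_diff)))
  expect_error(fda_compare(m, m$group, sg$densities, metrics = "bogus"),
               "unknown metric")
})
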