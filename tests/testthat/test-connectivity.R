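test_that("ICM matches the brute-force nested-loop oracle", {
  ps <- toy_pattern_set(n_roi = 5, n_runs = 3, n_trials = 6, seed = 77)
  rsms <- rsm_stack(ps, "encoding", "all")
  icm <- compute_icm(rsms)
  oracle <- icm_oracle(lapply(rsms, `[[`, "z"))
  expect_equal(unclass(icm), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(is.na(diag(icm))))
  # symmetry, masked-aware
  expect_equal(unclass(icm), t(unclass(icm)))
})

test_that("duplicate ROIs give the clipped maximum edge", {
  ps <- toy_pattern_set(n_roi = 2, n_runs = 3, n_trials = 6, seed = 10)
  ps$encoding$patterns[[2]] <- ps$encoding$patterns[[1]]
  expect_warning(icm <- compute_icm(rsm_stack(ps, "encoding", "all")),
                 "clipped")
  expect_equal(icm[1, 2], atanh(1 - 1e-7), tolerance = 1e-12)
})

test_that("independent pure-noise ROIs give near-zero mean edge z", {
  zs <- sapply(1:25, function(s) {
    ps <- toy_pattern_set(n_roi = 4, n_runs = 3, n_trials = 12, n_vox = 30,
                          seed = 900 + s)
    icm <- compute_icm(rsm_stack(ps, "encoding", "all"))
    mean(icm[upper.tri(icm)])
  })
  expect_lt(abs(mean(zs)), 3 / sqrt(25 * 6))
})

test_that("edge_change subtracts ICMs and flips under argument swap", {
  a <- matrix(c(NA, .2, .2, NA), 2, 2)
  b <- matrix(c(NA, .5, .5, NA), 2, 2)
  class(a) <- class(b) <- c("icm", "matrix")
  expect_equal(edge_change(a, b)[1, 2], 0.3)
  expect_equal(edge_change(b, a)[1, 2], -0.3)
  expect_true(all(edge_change(a, a) == 0, na.rm = TRUE))
  expect_error(edge_change(a, matrix(0, 3, 3)), "different ROI sets")
})

test_that("group contrast is the Welch t against the pooled others", {
  set.seed(31)
  deltas <- matrix(rnorm(12 * 4), 12, 4)
  groups <- rep(c("a", "b", "c"), each = 4)
  t_pkg <- group_edge_contrast(deltas, groups, "b")
  t_ref <- apply(deltas, 2, function(col)
    t.test(col[groups == "b"], col[groups != "b"])$statistic)
  expect_equal(t_pkg, unname(t_ref), tolerance = 1e-12)
  # degenerate: identical values -> t = 0 with warning
  flat <- matrix(1, 12, 2)
  expect_warning(t0 <- group_edge_contrast(flat, groups, "b"), "zero pooled")
  expect_equal(t0, c(0, 0))
  expect_error(group_edge_contrast(deltas, rep("a", 12), "b"), ">= 2")
})

test_that("a strongly shifted edge attains the maximum |t|", {
  hits <- sapply(1:100, function(s) {
    set.seed(1200 + s)
    deltas <- matrix(rnorm(72 * 3), 72, 3)
    groups <- rep(c("x", "y", "z"), each = 24)
    deltas[groups == "y", 2] <- deltas[groups == "y", 2] + 1
    which.max(abs(group_edge_contrast(deltas, groups, "y"))) == 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("permutation p is deterministic, extreme-case exact, and converges to the analytic t", {
  set.seed(55)
  deltas <- matrix(rnorm(12 * 3), 12, 3)
  groups <- rep(c("a", "b", "c"), each = 4)
  p1 <- permutation_null(deltas, groups, "a", n_perm = 200, seed = 9)
  p2 <- permutation_null(deltas, groups, "a", n_perm = 200, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$p > 0 & p1$p <= 1))
  # an overwhelming effect gives the add-one minimum (toy large enough that
  # the identity relabelling never recurs among the draws)
  set.seed(66)
  big <- matrix(rnorm(30 * 2), 30, 2)
  gb <- rep(c("a", "b", "c"), each = 10)
  big[gb == "a", 1] <- big[gb == "a", 1] + 50
  pe <- permutation_null(big, gb, "a", n_perm = 99, seed = 2)
  expect_equal(pe$p[1], 1 / 100)
  # convergence to the analytic Welch p on normal data
  set.seed(77)
  d2 <- matrix(rnorm(30 * 2), 30, 2)
  g2 <- rep(c("a", "b", "c"), each = 10)
  pn <- permutation_null(d2, g2, "a", n_perm = 10000, seed = 3)
  p_analytic <- apply(d2, 2, function(col)
    t.test(col[g2 == "a"], col[g2 != "a"])$p.value)
  expect_lt(max(abs(pn$p - p_analytic)), 0.01)
  expect_error(permutation_null(deltas, groups, "a", n_perm = 0), ">= 1")
})

test_that("permutation p is uniform under the exchangeable null", {
  ps <- unlist(lapply(1:20, function(s) {
    set.seed(2200 + s)
    deltas <- matrix(rnorm(24 * 100), 24, 100)
    groups <- rep(c("a", "b", "c"), each = 8)
    permutation_null(deltas, groups, "b", n_perm = 199, seed = s)$p
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH FDR matches the hand-worked example and the reference implementation", {
  res <- fdr_bh(c(.01, .02, .04, .2), q = .05)
  expect_identical(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$qvalues, p.adjust(c(.01, .02, .04, .2), "BH"),
               tolerance = 1e-12)
  expect_false(any(fdr_bh(rep(1, 5))$reject))
  expect_true(fdr_bh(0.04, q = 0.05)$reject)
  # property: agrees with p.adjust on random vectors
  set.seed(8)
  for (k in 1:10) {
    p <- runif(50)^2
    expect_equal(fdr_bh(p)$qvalues, p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(fdr_bh(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fdr_bh(c(0.5, NA)), "\\(0, 1\\]")
})

test_that("edge_contrast_table assembles ordered, labelled edge results", {
  set.seed(91)
  deltas <- matrix(rnorm(24 * 6), 24, 6)  # 4 ROIs
  groups <- rep(c("a", "b", "c"), each = 8)
  deltas[groups == "b", 2] <- deltas[groups == "b", 2] + 3
  tab <- edge_contrast_table(deltas, groups, "b", n_perm = 199, seed = 4,
                             roi_ids = 11:14)
  expect_equal(nrow(tab), 6)
  # edge 2 in row-major order is (1,3) -> labels (11, 13)
  expect_equal(tab$roi_i[1], 11)
  expect_equal(tab$roi_j[1], 13)
  expect_true(all(diff(abs(tab$t)) <= 1e-12))
  expect_true(all(tab$direction[tab$t < 0] == "post<pre"))
  expect_error(edge_contrast_table(deltas[, 1:5], groups, "b"),
               "upper triangle")
})
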