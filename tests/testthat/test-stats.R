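# Welch tests, PLS-DA, permutation significance, Q2, heat-map matrices.

test_that("Welch t-test matches the textbook formula", {
  r <- t_test_feature(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0213, tolerance = 1e-3)
  # and the reference implementation
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate zero-variance inputs follow the stated conventions", {
  same <- t_test_feature(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  apart <- t_test_feature(c(2, 2, 2), c(3, 3, 3))
  expect_equal(apart$p, 0)
  expect_true(apart$degenerate)
  ident <- t_test_feature(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("Welch p approximates the exact permutation p at small n", {
  # brute-force oracle: all C(8,4) = 70 label assignments
  perm_p <- function(a, b) {
    x <- c(a, b)
    obs <- abs(t_test_feature(a, b)$t)
    splits <- utils::combn(8, 4)
    stats <- apply(splits, 2, function(ii) {
      abs(t_test_feature(x[ii], x[-ii])$t)
    })
    mean(stats >= obs - 1e-12)
  }
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(4)
    b <- rnorm(4, mean = 1)
    expect_lt(abs(perm_p(a, b) - t_test_feature(a, b)$p), 0.15)
  }
})

test_that("differential_features flags by raw alpha with directions", {
  fm <- fixture_fm()
  d <- differential_features(fm, alpha = 0.05)
  expect_true(all(d$significant == (d$p < 0.05)))
  expect_true(all(d$p >= 0 & d$p <= 1))
  counts <- attr(d, "counts")
  expect_equal(sum(counts$n_up), counts$n_significant)
  # alpha 0 kills everything
  d0 <- differential_features(fm, alpha = 0)
  expect_equal(attr(d0, "counts")$n_significant, 0L)
  # constant feature gets p = 1 and a degenerate flag
  vals <- cbind(fm$values[, 1:3], const = 0.5)
  fmc <- feature_matrix(
    vals, fm$cell_ids, fm$conditions,
    c(fm$consensus_mz[1:3], 1499)
  )
  dc <- differential_features(fmc)
  expect_equal(dc$p[4], 1)
  expect_true(dc$degenerate[4])
})

test_that("PLS-DA separates a separable single feature", {
  set.seed(41)
  x <- matrix(c(rnorm(10, -1, 0.1), rnorm(10, 1, 0.1)), ncol = 1)
  fm <- feature_matrix(exp(x), sprintf("c%02d", 1:20),
    rep(c("a", "b"), each = 10), 500
  )
  fit <- plsda_fit(fm, 1)
  s <- fit$scores[, 1]
  expect_true(
    max(s[fm$conditions == "a"]) < min(s[fm$conditions == "b"]) ||
      min(s[fm$conditions == "a"]) > max(s[fm$conditions == "b"])
  )
  expect_equal(mean(s), 0, tolerance = 1e-10)
})

test_that("PLS-DA rejects degenerate inputs", {
  fm <- feature_matrix(matrix(0.5, 6, 3), sprintf("c%d", 1:6),
    rep(c("a", "b"), 3), c(100, 200, 300)
  )
  expect_error(plsda_fit(fm, 1), "no variance|no residual")
  expect_error(plsda_fit(fixture_fm(), 40), "n_components")
})

test_that("PLS-DA is invariant to cell order and loadings stay consistent", {
  fm <- fixture_fm()
  fit <- plsda_fit(fm, 2)
  set.seed(19)
  ord <- sample(length(fm$cell_ids))
  fmp <- feature_matrix(
    fm$values[ord, ], fm$cell_ids[ord], fm$conditions[ord],
    fm$consensus_mz, fm$feature_ids
  )
  fitp <- plsda_fit(fmp, 2)
  expect_equal(fitp$scores, fit$scores[ord, ], tolerance = 1e-8)
  expect_equal(fitp$loadings, fit$loadings, tolerance = 1e-8)
  # weights of successive components are orthogonal under deflation
  w <- fit$weights
  expect_lt(abs(sum(w[, 1] * w[, 2])), 1e-8)
  # scores are uncorrelated across components
  expect_lt(abs(sum(fit$scores[, 1] * fit$scores[, 2])), 1e-6)
})

test_that("PLS-DA scores agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  fm <- fixture_fm()
  fit <- plsda_fit(fm, 2)
  mo <- mixOmics::plsda(fm$values, factor(fm$conditions),
    ncomp = 2, scale = FALSE
  )
  expect_gt(abs(stats::cor(fit$scores[, 1], mo$variates$X[, 1])), 0.9999)
  expect_gt(abs(stats::cor(fit$scores[, 2], mo$variates$X[, 2])), 0.9999)
})

test_that("permutation p is deterministic and floored at 1/(n+1)", {
  fm <- fixture_fm()
  p1 <- plsda_permutation_test(fm, n_permutations = 99, seed = 5)
  p2 <- plsda_permutation_test(fm, n_permutations = 99, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 100)
  p3 <- plsda_permutation_test(fm, n_permutations = 99, seed = 6)
  expect_equal(length(p3$permuted), 99L)
})

test_that("permutation p is roughly uniform on null data", {
  ps <- vapply(1:20, function(s) {
    fm <- simulate_null_matrix(
      n_cells_per_group = 8L, n_features = 60L, rng_seed = 100 + s
    )
    plsda_permutation_test(fm, n_permutations = 39, seed = s)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("Q2 is high for separable data and reproducible under seed", {
  fm <- fixture_fm()
  q <- plsda_q2(fm, seed = 4)
  expect_gt(q, 0.5)
  expect_identical(q, plsda_q2(fm, seed = 4))
  expect_error(plsda_q2(fm, n_components = 40), "n_components")
})

test_that("label shuffling drives Q2 to zero or below in expectation", {
  fm <- fixture_fm()
  q2s <- vapply(1:10, function(s) {
    shuf <- withr::with_seed(300 + s, sample(fm$conditions))
    fs <- feature_matrix(
      fm$values, fm$cell_ids, shuf, fm$consensus_mz, fm$feature_ids
    )
    plsda_q2(fs, seed = s)
  }, numeric(1))
  expect_lt(mean(q2s), 0)
})

test_that("heat-map data z-scores rows and clusters deterministically", {
  vals <- rbind(
    c(1, 3, 0.5, 0.5), # feature values across 2 cells (by column)
    c(2, 4, 0.5, 0.5)
  )
  fm <- feature_matrix(vals, c("c1", "c2"), c("a", "b"),
    c(100, 200, 300, 400)
  )
  hd <- heatmap_data(fm, fm$feature_ids[1:2])
  # hand-computed z-scores: (1,2) -> (-sqrt(1/2), sqrt(1/2)) etc.
  expect_equal(unname(sort(hd$z[1, ])), c(-1, 1) / sqrt(2),
    tolerance = 1e-12
  )
  expect_equal(rowMeans(hd$z), c(0, 0), tolerance = 1e-12,
    ignore_attr = TRUE
  )
  # constant feature: zero row, placed last
  hd2 <- heatmap_data(fm, fm$feature_ids)
  expect_equal(unname(hd2$z[nrow(hd2$z), ]), c(0, 0))
})

test_that("heat-map clustering is invariant to cell order", {
  fm <- fixture_fm()
  d <- differential_features(fm)
  feats <- d$feature_id[order(d$p)][1:12]
  hd <- heatmap_data(fm, feats)
  set.seed(27)
  ord <- sample(length(fm$cell_ids))
  fmp <- feature_matrix(
    fm$values[ord, ], fm$cell_ids[ord], fm$conditions[ord],
    fm$consensus_mz, fm$feature_ids
  )
  hdp <- heatmap_data(fmp, feats)
  expect_identical(rownames(hd$z), rownames(hdp$z))
  expect_identical(colnames(hd$z), colnames(hdp$z))
  expect_equal(hd$z, hdp$z, tolerance = 1e-12)
})
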