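test_that("a noiseless constructed line is recovered exactly", {
  # chi2_j = 1 + 0.5 l_j exactly, n = M: slope 0.5, h2 = 0.5
  l <- rep(seq(1, 4, length.out = 50), each = 4)
  Z <- matrix(sqrt(1 + 0.5 * l), ncol = 1, dimnames = list(NULL, "t1"))
  p <- manual_panel(Z, l, n = 200, M = 200)
  fit <- ldsc_h2(p, "t1", n_blocks = 4)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$est, 0.5, tolerance = 1e-10)
})

test_that("engine regression equals the brute-force weighted oracle", {
  p <- small_panel(k = 2, m = 2000, seed = 6)
  for (pair in list(c("t1", "t1"), c("t1", "t2"))) {
    fit <- ldsc_cross(p, pair[1], pair[2], n_blocks = 10)
    y <- p$Z[, pair[1]] * p$Z[, pair[2]]
    w <- oracle_weights(p$Z[, pair[1]], p$Z[, pair[2]], p$ld)
    ref <- oracle_wls(y, p$ld, w)
    expect_equal(fit$slope, unname(ref["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(ref["intercept"]), tolerance = 1e-10)
  }
})

test_that("cross-trait regression of a trait with itself is the h2 regression", {
  p <- small_panel(k = 2, m = 1500, seed = 7)
  expect_equal(ldsc_cross(p, "t1", "t1", n_blocks = 8)$est,
               ldsc_h2(p, "t1", n_blocks = 8)$est)
})

test_that("the joint jackknife V matches per-block refitting", {
  p <- small_panel(k = 3, m = 1500, seed = 8)
  gc <- ldsc_covariance(p, n_blocks = 8)
  oracle <- oracle_joint_jackknife(p, n_blocks = 8)
  expect_equal(gc$est_del, oracle$est_del, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(gc$V, oracle$V, tolerance = 1e-10, ignore_attr = TRUE)
  # assembled S equals the standalone pairwise regressions bit-for-bit
  expect_equal(gc$S_raw["t1", "t2"], ldsc_cross(p, "t1", "t2", n_blocks = 8)$est,
               tolerance = 1e-12)
  expect_equal(gc$S_raw["t3", "t3"], ldsc_h2(p, "t3", n_blocks = 8)$est,
               tolerance = 1e-12)
})

test_that("permuting trait order permutes S and V consistently", {
  p <- small_panel(k = 3, m = 1500, seed = 9)
  perm <- c(3, 1, 2)
  p2 <- p
  p2$traits <- p$traits[perm]
  p2$Z <- p$Z[, perm]
  p2$n <- p$n[perm]
  g1 <- ldsc_covariance(p, n_blocks = 6)
  g2 <- ldsc_covariance(p2, n_blocks = 6)
  expect_equal(g2$S, g1$S[perm, perm])
  # V rows/cols follow the vech reindexing
  vp <- genomicg:::vech_pairs(3)
  vidx <- matrix(0L, 3, 3)
  vidx[vp] <- seq_len(nrow(vp)); vidx[vp[, c(2, 1)]] <- seq_len(nrow(vp))
  map <- vapply(seq_len(nrow(vp)), function(e) {
    vidx[perm[vp[e, 1]], perm[vp[e, 2]]]
  }, 0L)
  expect_equal(g2$V, g1$V[map, map], tolerance = 1e-12)
})

test_that("a single-trait panel degenerates to [h2] and its jackknife variance", {
  p <- small_panel(k = 1, m = 1000, seed = 10, loadings = 0.5)
  gc <- ldsc_covariance(p, n_blocks = 5)
  fit <- ldsc_h2(p, "t1", n_blocks = 5)
  expect_equal(dim(gc$S), c(1, 1))
  expect_equal(gc$S[1, 1], fit$est)
  expect_equal(sqrt(gc$V[1, 1]), fit$se, tolerance = 1e-12)
})

test_that("genetic correlations follow their closed forms", {
  g1 <- fake_gcov(diag(3), paste0("t", 1:3))
  r1 <- rg_matrix(g1)
  expect_equal(r1$rg, diag(3), ignore_attr = TRUE)

  S <- matrix(c(0.2, 0.1, 0.1, 0.2), 2)
  r2 <- rg_matrix(fake_gcov(S, c("a", "b")))
  expect_equal(r2$rg["a", "b"], 0.5)
  expect_equal(diag(r2$rg), c(a = 1, b = 1))

  # non-positive diagonal: undefined, flagged, never fabricated
  S3 <- matrix(c(-0.05, 0.1, 0.1, 0.2), 2)
  r3 <- rg_matrix(fake_gcov(S3, c("a", "b")))
  expect_true(is.na(r3$rg["a", "b"]))
  expect_equal(r3$undefined, "a")
})

test_that("negative heritability estimates are reported with a warning", {
  set.seed(99)
  l <- rep(seq(1, 3, length.out = 100), each = 5)
  # chi2 decreasing in l forces a negative slope
  Z <- matrix(sqrt(pmax(2 - 0.3 * l, 0.1)), ncol = 1, dimnames = list(NULL, "t1"))
  p <- manual_panel(Z, l, n = 500, M = 500)
  expect_warning(fit <- ldsc_h2(p, "t1", n_blocks = 5), "negative h2")
  expect_lt(fit$est, 0)
})

test_that("PSD smoothing floors eigenvalues and logs the change", {
  A <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  out <- genomicg:::nearest_psd(A)
  expect_true(out$smoothed)
  expect_gte(min(eigen(out$mat, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  expect_gt(out$max_change, 0)
  B <- diag(3)
  expect_false(genomicg:::nearest_psd(B)$smoothed)
  expect_equal(genomicg:::nearest_psd(B)$mat, B)
})

test_that("estimator recovery: h2 and rg near truth on a small panel", {
  p <- small_panel(k = 2, m = 8000, seed = 13, loadings = c(0.7, 0.7),
                   h2 = 0.25, n = 3e4)
  gc <- ldsc_covariance(p)
  expect_lt(max(abs(diag(gc$S) - 0.25)), 0.08)
  expect_lt(abs(rg_matrix(gc)$rg[1, 2] - 0.49), 0.15)
  # jackknife SEs are positive and finite
  expect_true(all(gc$se > 0))
})
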