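mat3 <- function(lower, traits = c("a", "b", "c")) {
  M <- diag(3)
  M[lower.tri(M)] <- lower
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  dimnames(M) <- list(traits, traits)
  M
}

test_that("comparing a landscape with itself is the zero comparison", {
  M <- mat3(c(0.5, 0.3, 0.2))
  cmp <- compare_landscapes(M, M)
  expect_equal(cmp$delta, M * 0, ignore_attr = TRUE)
  expect_equal(cmp$sign_flips_raw, 0)
  expect_equal(cmp$mean_delta, 0)
})

test_that("delta statistics follow the arithmetic on a worked 3-trait case", {
  # lower-triangle order (b,a), (c,a), (c,b)
  pre <- mat3(c(0.6, 0.4, 0.2))
  post <- mat3(c(-0.3, 0.4, -0.1))
  cmp <- compare_landscapes(pre, post)
  expect_equal(cmp$mean_pre, 0.4)
  expect_equal(cmp$mean_post, 0.0)
  expect_equal(cmp$sign_flips_raw, 2)
  expect_equal(cmp$pairs$delta, c(-0.9, 0, -0.3))
  expect_equal(diag(cmp$delta), rep(0, 3), ignore_attr = TRUE)
  expect_equal(cmp$delta, t(cmp$delta))
  # profile rows are the matrix rows minus the diagonal
  prof_a <- dplyr::filter(cmp$profiles, test == "a", stage == "pre")
  expect_equal(sort(prof_a$rg), sort(pre["a", c("b", "c")]), ignore_attr = TRUE)

  expect_error(compare_landscapes(pre, mat3(c(0, 0, 0), traits = c("x", "y", "z"))),
               "trait labels")
})

test_that("equal loadings make the loading-delta test degenerate, not numeric", {
  pre <- mat3(c(0.6, 0.4, 0.2))
  post <- mat3(c(0.1, 0.0, -0.2))
  cmp <- compare_landscapes(pre, post)
  sol <- fake_solution(c(a = 0.7, b = 0.7, c = 0.7))
  out <- loading_delta_test(sol, cmp)
  expect_true(out$degenerate)
  expect_true(is.na(out$estimate))
})

test_that("deltas proportional to loading differences give |correlation| near 1", {
  k <- 6
  lam <- seq(0.3, 0.9, length.out = k)
  traits <- paste0("t", 1:k)
  pre <- tcrossprod(lam); diag(pre) <- 1
  dimnames(pre) <- list(traits, traits)
  dl <- abs(outer(lam, lam, "-"))
  post <- pre - 0.5 * dl
  diag(post) <- 1
  cmp <- compare_landscapes(pre, post)
  out <- loading_delta_test(fake_solution(stats::setNames(lam, traits)), cmp)
  expect_false(out$degenerate)
  expect_equal(out$n_pairs, k * (k - 1) / 2)
  expect_lt(out$estimate, -0.99)
})

test_that("the loading-delta test is invariant to relabelling and factor sign", {
  k <- 5
  lam <- c(0.3, 0.5, 0.6, 0.8, 0.9)
  traits <- paste0("t", 1:k)
  pre <- tcrossprod(lam); diag(pre) <- 1; dimnames(pre) <- list(traits, traits)
  set.seed(31)
  noise <- matrix(rnorm(k * k, 0, 0.1), k); noise <- (noise + t(noise)) / 2
  post <- pre - tcrossprod(lam) * 0.9 + noise
  diag(post) <- 1
  cmp <- compare_landscapes(pre, post)
  r1 <- loading_delta_test(fake_solution(stats::setNames(lam, traits)), cmp)
  # global sign flip of the factor
  r2 <- loading_delta_test(fake_solution(stats::setNames(-lam, traits)), cmp)
  expect_equal(r1$estimate, r2$estimate)
  # relabelling traits (consistently in both inputs)
  perm <- c(4, 2, 5, 1, 3)
  pre_p <- pre[perm, perm]; post_p <- post[perm, perm]
  cmp_p <- compare_landscapes(pre_p, post_p)
  r3 <- loading_delta_test(fake_solution(stats::setNames(lam[perm], traits[perm])), cmp_p)
  expect_equal(r3$estimate, r1$estimate, tolerance = 1e-12)
})

test_that("an external copy of a panel trait correlates ~1 before correction", {
  p <- small_panel(k = 3, m = 4000, seed = 32, h2 = 0.3, n = 3e4)
  fit <- fit_common_factor(ldsc_covariance(p))
  corrected <- correct_all_traits(p, fit)
  ext <- dplyr::mutate(p$variants, z = p$Z[, "t1"], n = unname(p$n[["t1"]]),
                       info = NA_real_, .after = "a2")
  prof <- external_profile(p, corrected, ext, min_overlap = 100)
  expect_equal(prof$rg_pre[prof$test == "t1"], 1, tolerance = 0.05)
})

test_that("a g-only external trait attenuates after correction", {
  tr <- truth_set(k = 4, loadings = c(0.8, 0.75, 0.7, 0.65), h2 = 0.25, n = 3e4,
                  m = 10000, block_size = 5, rho = c(0.1, 0.8),
                  traits = paste0("t", 1:4))
  p <- simulate_panel(tr, seed = 33)
  fit <- fit_common_factor(ldsc_covariance(p))
  corrected <- correct_all_traits(p, fit)
  ext_g <- simulate_external_trait(p, g_corr = 0.6, h2 = 0.3, n = 8e4, seed = 5)
  prof <- external_profile(p, corrected, ext_g, min_overlap = 100)
  expect_gt(mean(prof$rg_pre), 0.25)           # clearly positive before
  expect_lt(mean(abs(prof$rg_post)), 0.15)     # near zero after

  # residual-specific external association survives the correction
  ext_r <- simulate_external_trait(p, g_corr = 0, specific_corr = c(t2 = 0.6),
                                   h2 = 0.3, n = 8e4, seed = 6)
  prof2 <- external_profile(p, corrected, ext_r, min_overlap = 100)
  expect_gt(prof2$rg_post[prof2$test == "t2"], 0.15)
})
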