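test_that("SNP-trait covariances are z / sqrt(n)", {
  p <- small_panel(k = 2, m = 500, seed = 16)
  C <- snp_trait_covariances(p)
  expect_equal(C[1, ], p$Z[, 1] / sqrt(p$n[[1]]), ignore_attr = TRUE)
  p$Z[5, 1] <- 2; p$n[1] <- 10000
  expect_equal(unname(snp_trait_covariances(p)[1, 5]), 0.02)
  p$Z[6, ] <- 0
  expect_equal(unname(snp_trait_covariances(p)[, 6]), c(0, 0))
})

test_that("constructed pure-g and pure-residual variants are solved exactly", {
  lam <- c(0.6, 0.7, 0.8)
  S <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(S) <- list(paste0("t", 1:3), paste0("t", 1:3))
  fit <- fit_common_factor(list(S = S))
  n <- stats::setNames(rep(2e4, 3), paste0("t", 1:3))

  cv_g <- unname(fit$loadings_cov) * 0.05          # SNP acting only through g
  sol <- fit_snp_paths(cv_g, n, fit, "t2")
  expect_equal(unname(sol$b_g), 0.05, tolerance = 1e-8)
  expect_equal(unname(sol$b_resid), 0, tolerance = 1e-8)

  cv_r <- c(0, 0.04, 0)                             # only the target residual
  sol2 <- fit_snp_paths(cv_r, n, fit, "t2")
  expect_equal(unname(sol2$b_resid), 0.04, tolerance = 1e-8)
  expect_equal(unname(sol2$b_g), 0, tolerance = 1e-8)
})

test_that("corrected effects track the simulated residual signal", {
  tr <- truth_set(k = 4, loadings = c(0.8, 0.7, 0.6, 0.5), h2 = 0.25, n = 3e4,
                  m = 8000, block_size = 5, rho = c(0.1, 0.8),
                  traits = paste0("t", 1:4))
  p <- simulate_panel(tr, seed = 17)
  fit <- fit_common_factor(ldsc_covariance(p))
  cs <- correct_trait(p, fit, "t1")
  eff <- attr(p, "effects")
  ld <- attr(p, "ld_blocks")
  true_resid <- sqrt(tr$h2[1] * tr$u[1]) *
    as.vector(genomicg:::ld_convolve(ld, eff$delta[, 1]))
  expect_gt(stats::cor(cs$b_std, true_resid), 0.5)
  # among the strongest residual variants the sign is recovered reliably
  top <- order(-abs(true_resid))[1:200]
  expect_gt(mean(sign(cs$b_std[top]) == sign(true_resid[top])), 0.9)
})

test_that("forcing a zero loading reproduces the original statistics", {
  p <- small_panel(k = 3, m = 3000, seed = 18)
  fit <- fit_common_factor(ldsc_covariance(p))
  fit0 <- fit
  fit0$loadings_cov["t2"] <- 0
  fit0$vcov <- matrix(0, 6, 6)
  cs <- correct_trait(p, fit0, "t2")
  expect_equal(cs$b_std, p$Z[, "t2"] / sqrt(p$n[["t2"]]), tolerance = 1e-10,
               ignore_attr = TRUE)
  # and the effective sample size is the original n
  expect_equal(attr(cs, "n_eff"), unname(p$n[["t2"]]), tolerance = 0.02 * p$n[["t2"]])
})

test_that("effective sample size follows its scaling laws", {
  x <- tibble::tibble(freq = runif(200, 0.15, 0.35),
                      beta = rnorm(200, 0, 0.05))
  x$se <- 0.02
  x$z <- x$beta / x$se
  n1 <- estimate_effective_n(x)
  x2 <- dplyr::mutate(x, se = 2 * se, z = beta / se)
  expect_equal(estimate_effective_n(x2), n1 / 4, tolerance = 1e-10)
  # allele relabelling: flip effect allele and sign
  x3 <- dplyr::mutate(x, freq = 1 - freq, beta = -beta, z = -z)
  expect_equal(estimate_effective_n(x3), n1, tolerance = 1e-10)
  # outside the window: falls back to the median with a message
  x4 <- dplyr::mutate(x, freq = 0.05)
  expect_message(n4 <- estimate_effective_n(x4), "median")
  expect_true(is.finite(n4))
})

test_that("fast fixed-measurement solve matches the full per-SNP refit", {
  lam <- c(0.8, 0.7, 0.6)
  tr <- truth_set(k = 3, loadings = lam, h2 = 0.3, n = 2e4, m = 200,
                  block_size = 5, rho = c(0.1, 0.7), traits = paste0("t", 1:3))
  S <- tr$cov_g; dimnames(S) <- list(tr$traits, tr$traits)
  fit <- fit_common_factor(list(S = S, V = diag(1e-8, 6), traits = tr$traits))
  p <- simulate_panel(tr, seed = 11)
  cf <- correct_trait(p, fit, "t2", mode = "fixed")
  cr <- correct_trait(p, fit, "t2", mode = "refit")
  expect_lt(max(abs(cf$b_std - cr$b_std)), 1e-3)
  expect_lt(max(abs(cf$b_g - cr$b_g)), 1e-3)
})

test_that("correction is order-independent across targets and counts skips", {
  p <- small_panel(k = 3, m = 2000, seed = 19)
  fit <- fit_common_factor(ldsc_covariance(p))
  all1 <- correct_all_traits(p, fit)
  direct <- correct_trait(p, fit, "t3")
  expect_equal(all1[["t3"]]$b_std, direct$b_std)

  # missing statistics: skipped and counted; over half missing is fatal
  p2 <- p
  p2$Z[1:10, 2] <- NA
  cs <- correct_trait(p2, fit, "t1")
  expect_equal(attr(cs, "skipped"), 10)
  expect_equal(nrow(cs), 1990)
  p3 <- p
  p3$Z[1:1500, 2] <- NA
  expect_error(correct_trait(p3, fit, "t1"), "50%")
})

test_that("the factor GWAS and a corrected trait are written and readable", {
  p <- small_panel(k = 3, m = 2000, seed = 20)
  fit <- fit_common_factor(ldsc_covariance(p))
  g <- factor_gwas(p, fit)
  expect_equal(nrow(g), 2000)
  expect_true(all(is.finite(g$z)))
  f <- withr::local_tempfile()
  correct_trait(p, fit, "t1", path = f)
  back <- read_sumstats(f, corrected_column_map())
  expect_equal(nrow(back), 2000)
})
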