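#' Generative truth for a multi-trait summary-statistic panel
#'
#' Defines a one-factor genetic architecture on the standardized scale: each
#' trait's additive genetic value is `sqrt(h2) * (lambda * g + sqrt(1 -
#' lambda^2) * s)` with a shared factor `g` and a trait-specific component
#' `s`, all unit variance. The implied genetic correlation between traits a
#' and b is `lambda_a * lambda_b` (plus any specified residual correlation),
#' and the genetic covariance is that correlation scaled by
#' `sqrt(h2_a * h2_b)`.
#'
#' The defaults describe a 12-test cognitive panel: standardized loadings
#' spanning 0.26 to 0.92 (mean 0.66, mean squared loading 0.47, i.e. the
#' factor carries just under half the genetic variance), SNP heritabilities
#' averaging 0.16, GWAS sample sizes between 15,000 and 35,000, and 20,000
#' variants in exchangeable LD blocks of 10 whose within-block correlation
#' spreads evenly over 0.2-0.8 across blocks (the spread gives the LD-score
#' regression a non-degenerate regressor; see [make_ld_blocks()]).
#'
#' @param k Number of traits.
#' @param loadings Standardized factor loadings, in `[-1, 1]`.
#' @param h2 Total SNP heritability per trait, in `(0, 1)`.
#' @param n GWAS sample size per trait.
#' @param m Number of variants.
#' @param block_size,rho LD-block parameters (see [make_ld_blocks()]).
#' @param resid_cor Optional k x k correlation matrix among the
#'   trait-specific genetic components (unit diagonal). Default: identity
#'   (independent residuals).
#' @param traits Trait labels.
#' @return A `truth_set` object.
#' @export
truth_set <- function(k = 12,
                      loadings = default_loadings(k),
                      h2 = default_h2(k),
                      n = round(seq(15000, 35000, length.out = k)),
                      m = 20000, block_size = 10, rho = c(0.2, 0.8),
                      resid_cor = NULL,
                      traits = sprintf("test%02d", seq_len(k))) {
  loadings <- rep_len(loadings, k)
  h2 <- rep_len(h2, k)
  n <- rep_len(n, k)
  if (any(abs(loadings) > 1)) abort("loadings exceed unit variance")
  if (any(h2 <= 0 | h2 >= 1)) abort("h2 must lie in (0, 1)")
  u <- 1 - loadings^2
  if (is.null(resid_cor)) resid_cor <- diag(k)
  stopifnot(nrow(resid_cor) == k, isTRUE(all.equal(diag(resid_cor), rep(1, k))))
  G <- tcrossprod(loadings) + diag(sqrt(u), k) %*% resid_cor %*% diag(sqrt(u), k)
  diag(G) <- 1
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("implied genetic correlation matrix is not positive semi-definite")
  }
  structure(list(
    k = k, traits = traits, loadings = loadings, u = u, h2 = h2, n = n,
    m = m, block_size = block_size, rho = rho, resid_cor = resid_cor,
    cor_g = G,
    cov_g = diag(sqrt(h2), k) %*% G %*% diag(sqrt(h2), k)
  ), class = "truth_set")
}

#' @rdname truth_set
#' @export
default_loadings <- function(k = 12) {
  base <- c(0.26, 0.44, 0.52, 0.58, 0.63, 0.68, 0.70, 0.74, 0.77, 0.81, 0.85, 0.92)
  if (k == 12) base else seq(0.3, 0.9, length.out = k)
}

#' @rdname truth_set
#' @export
default_h2 <- function(k = 12) {
  base <- c(0.10, 0.25, 0.12, 0.14, 0.24, 0.16, 0.12, 0.18, 0.10, 0.15, 0.14, 0.22)
  if (k == 12) base else rep_len(0.16, k)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d traits, %d variants (blocks of %d, rho %s)\n",
              x$k, x$m, x$block_size, paste(format(x$rho, digits = 2), collapse = "-")))
  cat(sprintf("loadings %s\n", paste(format(x$loadings, digits = 2), collapse = " ")))
  cat(sprintf("h2       %s\n", paste(format(x$h2, digits = 2), collapse = " ")))
  invisible(x)
}

#' Simulate a multi-trait GWAS summary-statistic panel with known truth
#'
#' Draws per-variant causal effects under the one-factor architecture of a
#' [truth_set()] and produces observed Z-scores through the LD structure:
#' factor effects `alpha_j ~ N(0, 1/m)`, specific effects
#' `delta_tj ~ N(0, 1/m)`, standardized causal effect
#' `beta_tj = sqrt(h2_t) * (lambda_t * alpha_j + sqrt(u_t) * delta_tj)`
#' (so the causal effects sum to `h2_t` in expectation), marginal effects by
#' within-block LD convolution `R beta`, and
#' `z_tj = sqrt(n_t) * (R beta_t)_j + eps_tj` with noise covariance `R`
#' within a block and independence across traits (non-overlapping samples).
#' Effect-allele frequencies are drawn Uniform(0.05, 0.5) and used only for
#' effective-sample-size computations downstream.
#'
#' @param truth A [truth_set()].
#' @param seed Integer seed; the draw is reproducible given (truth, seed).
#' @param ld Optional [make_ld_blocks()] structure; defaults to the one the
#'   truth describes.
#' @param dir Optional directory: when given, writes one sumstats file per
#'   trait, the LD-score table (with `.M` sidecar), and a `truth.json`.
#' @return A `sumstats_panel` with the truth in `attr(, "truth")` and the
#'   causal draws (`alpha`, `delta`, `beta`, `marginal`) in
#'   `attr(, "effects")`.
#' @export
simulate_panel <- function(truth, seed, ld = NULL, dir = NULL) {
  seed <- check_seed(seed)
  if (is.null(ld)) ld <- make_ld_blocks(truth$m, truth$block_size, truth$rho)
  stopifnot(ld$m == truth$m)
  k <- truth$k
  m <- truth$m

  set.seed(seed)
  alpha <- stats::rnorm(m) / sqrt(m)
  Delta <- matrix(stats::rnorm(m * k), m, k) / sqrt(m)
  if (any(truth$resid_cor[lower.tri(truth$resid_cor)] != 0)) {
    Delta <- Delta %*% chol(truth$resid_cor)
  }
  B <- sweep(outer(alpha, truth$loadings) + sweep(Delta, 2, sqrt(truth$u), "*"),
             2, sqrt(truth$h2), "*")
  marginal <- ld_convolve(ld, B)
  Z <- sweep(marginal, 2, sqrt(truth$n), "*") + ld_noise(ld, k)
  colnames(Z) <- truth$traits

  freq <- stats::runif(m, 0.05, 0.5)
  pairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                    "G","A", "G","T", "T","C", "T","G"),
                  ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), m, replace = TRUE)

  variants <- tibble(
    variant_id = paste0("rs", seq_len(m)),
    chrom = as.character(1 + (ld$block - 1) %% 22),
    pos = as.numeric(seq_len(m) * 1000),
    a1 = pairs[pick, 1], a2 = pairs[pick, 2],
    freq = freq
  )

  panel <- structure(list(
    traits = truth$traits, variants = variants, Z = Z,
    n = setNames(as.numeric(truth$n), truth$traits),
    ld = ld$l2, M = m,
    log = list(sprintf("simulated from truth_set (seed %d)", seed))
  ), class = "sumstats_panel")
  attr(panel, "truth") <- truth
  attr(panel, "effects") <- list(alpha = alpha, delta = Delta, beta = B, marginal = marginal)
  attr(panel, "ld_blocks") <- ld

  if (!is.null(dir)) write_panel_files(panel, dir)
  panel
}

#' @rdname simulate_panel
#' @param panel A simulated `sumstats_panel`.
#' @export
write_panel_files <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in panel$traits) {
    rec <- panel_records(panel, t)
    readr::write_tsv(
      tibble(SNP = rec$variant_id, CHR = rec$chrom, BP = rec$pos,
             A1 = rec$a1, A2 = rec$a2, Z = rec$z, N = rec$n, FREQ = rec$freq),
      file.path(dir, paste0(t, ".sumstats.tsv")), progress = FALSE)
  }
  write_ld_scores(ld_score_table(tibble(variant_id = panel$variants$variant_id,
                                        l2 = panel$ld), M = panel$M),
                  file.path(dir, "ldscores.tsv"))
  truth <- attr(panel, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(k = truth$k, traits = truth$traits, loadings = truth$loadings,
           u = truth$u, h2 = truth$h2, n = truth$n, m = truth$m,
           block_size = truth$block_size, rho = truth$rho,
           resid_cor = truth$resid_cor),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Simulate an external trait with stated genetic overlap with the panel
#'
#' Builds a single-trait set of summary statistics whose additive genetic
#' value correlates `g_corr` with the panel's common factor and
#' `specific_corr[t]` with trait t's specific genetic component, using the
#' panel's own causal draws so that the realized genetic covariances follow
#' the stated structure. The remaining variance goes to an independent
#' component; `g_corr^2 + sum(specific_corr^2)` must not exceed 1.
#'
#' @param panel A panel from [simulate_panel()] (must carry its causal
#'   draws).
#' @param g_corr Genetic correlation between the external trait and the
#'   factor.
#' @param specific_corr Named vector of correlations with specific genetic
#'   components, names drawn from `panel$traits`. Default: none.
#' @param h2 SNP heritability of the external trait.
#' @param n GWAS sample size.
#' @param seed Integer seed.
#' @param path Optional file path; when given the records are written in the
#'   `SNP CHR BP A1 A2 Z N FREQ` dialect.
#' @return A record tibble in the [read_sumstats()] layout (Z on the panel's
#'   allele orientation), with the generative parameters in
#'   `attr(, "external_truth")`.
#' @export
simulate_external_trait <- function(panel, g_corr, specific_corr = NULL,
                                    h2 = 0.2, n = 50000, seed = 1,
                                    path = NULL) {
  seed <- check_seed(seed)
  eff <- attr(panel, "effects")
  ld <- attr(panel, "ld_blocks")
  truth <- attr(panel, "truth")
  if (is.null(eff) || is.null(ld)) {
    abort("`panel` must come from simulate_panel() (causal draws are required)")
  }
  cvec <- setNames(rep(0, length(panel$traits)), panel$traits)
  if (!is.null(specific_corr)) {
    bad <- setdiff(names(specific_corr), panel$traits)
    if (length(bad) > 0) abort(sprintf("unknown trait(s) in specific_corr: %s", paste(bad, collapse = ", ")))
    cvec[names(specific_corr)] <- specific_corr
  }
  rem <- 1 - g_corr^2 - sum(cvec^2)
  if (rem < -1e-12) abort("implied covariance matrix is not positive semi-definite")
  m <- panel$M
  set.seed(seed + 1000003L)
  gamma <- g_corr * eff$alpha +
    as.vector(eff$delta %*% cvec) +
    sqrt(max(rem, 0)) * stats::rnorm(m) / sqrt(m)
  beta <- sqrt(h2) * gamma
  z <- sqrt(n) * as.vector(ld_convolve(ld, beta)) + as.vector(ld_noise(ld, 1))

  out <- dplyr::mutate(panel$variants, z = z, n = as.numeric(n), info = NA_real_,
                       .after = "a2")
  attr(out, "external_truth") <- list(
    g_corr = g_corr, specific_corr = cvec, h2 = h2, n = n, seed = seed,
    # implied genetic correlation with each panel trait
    rg_panel = setNames(g_corr * truth$loadings + cvec * sqrt(truth$u), panel$traits)
  )
  if (!is.null(path)) {
    readr::write_tsv(
      tibble(SNP = out$variant_id, CHR = out$chrom, BP = out$pos,
             A1 = out$a1, A2 = out$a2, Z = out$z, N = out$n, FREQ = out$freq),
      path, progress = FALSE)
  }
  out
}
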