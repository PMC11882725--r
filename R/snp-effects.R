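# Per-SNP structural paths: with the measurement model (loadings, residual
# variances) held at its panel-level estimates, each variant gets a path to
# the common factor and a path to one target trait's residual. The residual
# path is the g-corrected association; run once per trait this is
# GWAS-by-subtraction.

#' Standardized SNP-trait covariances for every variant
#'
#' On the standardized scale the covariance between a variant and trait t is
#' `z_t / sqrt(n_t)`, with sampling variance approximately `1 / n_t`. These
#' are the per-variant inputs to the expanded (k+1) x (k+1) system.
#'
#' @param panel A `sumstats_panel`.
#' @return A k x m matrix of covariances (traits in rows); variants with a
#'   missing Z in any trait give `NA` columns.
#' @export
snp_trait_covariances <- function(panel) {
  t(sweep(panel$Z, 2, sqrt(panel$n), "/"))
}

# Weighted solve shared by the fixed-measurement path fitter. X is k x q,
# weights are the inverse sampling variances n_t.
path_solver <- function(X, n) {
  XtW <- t(X) * rep(n, each = ncol(X))
  G <- XtW %*% X
  Gi <- solve(G)
  list(A = Gi %*% XtW, cov = Gi)
}

#' Fit the SNP-to-g and SNP-to-residual paths for one variant
#'
#' Solves the k covariance equations
#' `cov(SNP, trait_t) = lambda_t * b_g + [t == target] * b_resid`
#' by weighted least squares with weights `n_t` (the inverse sampling
#' variances of the covariances, cross-trait sampling covariance ignored
#' under the non-overlap assumption). Standard errors combine the weighted
#' solve with the measurement-parameter uncertainty propagated by the delta
#' method.
#'
#' @param cov_vec k-vector of standardized SNP-trait covariances.
#' @param n Per-trait sample sizes (the weights).
#' @param solution A `factor_solution` (covariance-scale loadings are used).
#' @param target Target trait label.
#' @return A list: `b_g`, `se_g`, `b_resid`, `se_resid`.
#' @export
fit_snp_paths <- function(cov_vec, n, solution, target) {
  k <- length(solution$traits)
  if (k < 2) abort("per-SNP paths are not identified with a single trait")
  ti <- match(target, solution$traits)
  if (is.na(ti)) abort(sprintf("target trait %s not in solution", target))
  X <- cbind(g = unname(solution$loadings_cov), resid = as.numeric(seq_len(k) == ti))
  sol <- path_solver(X, n)
  theta <- drop(sol$A %*% cov_vec)
  dA <- path_solver_dlambda(X, n, sol)
  extra <- path_delta_var(dA, cov_vec, solution$vcov[seq_len(k), seq_len(k), drop = FALSE])
  se <- sqrt(diag(sol$cov) + extra)
  list(b_g = theta[1], se_g = se[1], b_resid = theta[2], se_resid = se[2])
}

# dA/dlambda_s for the 2-column design X = [lambda, e_target]:
# returns a list of q x k matrices.
path_solver_dlambda <- function(X, n, sol) {
  k <- nrow(X)
  lapply(seq_len(k), function(s) {
    dX <- matrix(0, k, ncol(X))
    dX[s, 1] <- 1
    dXtW <- t(dX) * rep(n, each = ncol(X))
    XtW <- t(X) * rep(n, each = ncol(X))
    dG <- dXtW %*% X + XtW %*% dX
    -sol$cov %*% dG %*% sol$A + sol$cov %*% dXtW
  })
}

# Delta-method variance contribution from measurement uncertainty, per path.
path_delta_var <- function(dA, cov_vec, vcov_lambda) {
  q <- nrow(dA[[1]])
  vapply(seq_len(q), function(i) {
    g <- vapply(dA, function(D) drop(D[i, ] %*% cov_vec), 0)
    drop(t(g) %*% vcov_lambda %*% g)
  }, 0)
}

#' g-corrected summary statistics for one target trait
#'
#' Applies [fit_snp_paths()] to every variant with the measurement model
#' fixed at its panel-level estimates (`mode = "fixed"`, the default;
#' `mode = "refit"` re-estimates the full expanded model per variant as an
#' audit and is only practical on small panels). Variants with a missing
#' statistic in any trait are skipped and counted; more than 50% skipped is
#' fatal. The corrected effect is reported on the per-allele scale
#' (`beta = b / sqrt(2 p (1 - p))`), together with its SE, Z, and the
#' effective sample size from [estimate_effective_n()].
#'
#' @param panel A `sumstats_panel`.
#' @param solution A `factor_solution` fitted to the panel's genetic
#'   covariance.
#' @param target Target trait label.
#' @param mode `"fixed"` or `"refit"`.
#' @param path Optional file path; when given the result is written via
#'   [write_corrected_sumstats()].
#' @return A `corrected_sumstats` tibble: `variant_id`, `chrom`, `pos`,
#'   `a1`, `a2`, `freq`, `beta`, `se`, `z`, `b_std`, `se_std`, `b_g`,
#'   `se_g`, with attributes `trait`, `n_eff`, `skipped`, `mode`.
#' @export
correct_trait <- function(panel, solution, target, mode = c("fixed", "refit"),
                          path = NULL) {
  mode <- match.arg(mode)
  stopifnot(target %in% panel$traits)
  k <- length(panel$traits)
  C <- snp_trait_covariances(panel)
  complete <- colSums(!is.finite(C)) == 0
  skipped <- sum(!complete)
  if (skipped > 0.5 * ncol(C)) {
    abort(sprintf("%d of %d variants missing a statistic in some trait (> 50%%)",
                  skipped, ncol(C)))
  }
  ti <- match(target, solution$traits)
  X <- cbind(g = unname(solution$loadings_cov), resid = as.numeric(seq_len(k) == ti))
  n <- panel$n

  if (mode == "fixed") {
    sol <- path_solver(X, n)
    Theta <- sol$A %*% ifelse(is.finite(C), C, 0)  # 2 x m
    Theta[, !complete] <- NA_real_
    Vl <- solution$vcov[seq_len(k), seq_len(k), drop = FALSE]
    dA <- path_solver_dlambda(X, n, sol)
    # stack the per-parameter rows: Q_i[s, j] = dA_s[i, ] %*% C[, j]
    extra <- vapply(1:2, function(i) {
      Qi <- do.call(rbind, lapply(dA, function(D) drop(D[i, , drop = FALSE] %*% ifelse(is.finite(C), C, 0))))
      colSums(Qi * (Vl %*% Qi))
    }, numeric(ncol(C)))
    se_g <- sqrt(sol$cov[1, 1] + extra[, 1])
    se_r <- sqrt(sol$cov[2, 2] + extra[, 2])
    b_g <- Theta[1, ]
    b_r <- Theta[2, ]
  } else {
    res <- apply(C, 2, function(cv) {
      if (any(!is.finite(cv))) return(c(NA, NA, NA, NA))
      f <- refit_snp_model(cv, n, solution, ti)
      c(f$b_g, f$se_g, f$b_resid, f$se_resid)
    })
    b_g <- res[1, ]; se_g <- res[2, ]; b_r <- res[3, ]; se_r <- res[4, ]
  }

  scale <- sqrt(2 * panel$variants$freq * (1 - panel$variants$freq))
  out <- dplyr::mutate(panel$variants,
                       beta = b_r / scale, se = se_r / scale, z = b_r / se_r,
                       b_std = b_r, se_std = se_r, b_g = b_g, se_g = se_g)
  out <- out[complete, , drop = FALSE]
  n_eff <- estimate_effective_n(out)
  out <- dplyr::mutate(out, n_eff = n_eff)
  class(out) <- c("corrected_sumstats", class(out))
  attr(out, "trait") <- target
  attr(out, "n_eff") <- n_eff
  attr(out, "skipped") <- skipped
  attr(out, "mode") <- mode
  if (!is.null(path)) write_corrected_sumstats(out, path)
  out
}

# Exact audit mode: re-estimate loadings, residual variances and both SNP
# paths jointly for one variant, minimizing the DWLS discrepancy over the
# measurement part plus the n_t-weighted discrepancy over the SNP-covariance
# equations. The conditionally linear SNP paths are profiled out, so the
# optimizer only sees the measurement parameters, started at the panel-level
# solution.
refit_snp_model <- function(cov_vec, n, solution, target_index) {
  k <- length(n)
  S <- solution$S_obs
  if (is.null(S)) {
    S <- tcrossprod(unname(solution$loadings_cov)) + diag(unname(solution$u_cov), k)
  }
  w_S <- solution$w_S %||% rep(1, k * (k + 1) / 2)
  s_obs <- vech(S)
  e_t <- as.numeric(seq_len(k) == target_index)
  paths_given <- function(lam) {
    drop(path_solver(cbind(lam, e_t), n)$A %*% cov_vec)
  }
  obj <- function(th) {
    lam <- th[seq_len(k)]; u <- th[k + seq_len(k)]
    r1 <- s_obs - model_sigma_vech(c(lam, u), k)
    b <- paths_given(lam)
    r2 <- cov_vec - (lam * b[1] + e_t * b[2])
    sum(w_S * r1^2) + sum(n * r2^2)
  }
  start <- c(unname(solution$loadings_cov), unname(solution$u_cov))
  fit <- stats::nlminb(start, obj,
                       control = list(iter.max = 500, rel.tol = 1e-14))
  lam <- fit$par[seq_len(k)]
  b <- paths_given(lam)
  cv <- path_solver(cbind(lam, e_t), n)$cov
  list(b_g = b[1], se_g = sqrt(cv[1, 1]),
       b_resid = b[2], se_resid = sqrt(cv[2, 2]))
}

#' Summary statistics for the common factor itself
#'
#' A "g GWAS": per variant, the single SNP-to-g path fitted by weighted
#' least squares against all k covariance equations (no residual path).
#' Useful for checking that corrected traits are uncorrelated with the
#' factor.
#'
#' @inheritParams correct_trait
#' @return A `corrected_sumstats`-shaped tibble for the factor.
#' @export
factor_gwas <- function(panel, solution) {
  k <- length(panel$traits)
  C <- snp_trait_covariances(panel)
  complete <- colSums(!is.finite(C)) == 0
  X <- cbind(g = unname(solution$loadings_cov))
  sol <- path_solver(X, panel$n)
  b <- drop(sol$A %*% ifelse(is.finite(C), C, 0))
  b[!complete] <- NA_real_
  se <- rep(sqrt(sol$cov[1, 1]), ncol(C))
  scale <- sqrt(2 * panel$variants$freq * (1 - panel$variants$freq))
  out <- dplyr::mutate(panel$variants,
                       beta = b / scale, se = se / scale, z = b / se,
                       b_std = b, se_std = se)
  out <- out[complete, , drop = FALSE]
  n_eff <- estimate_effective_n(out)
  out <- dplyr::mutate(out, n_eff = n_eff)
  class(out) <- c("corrected_sumstats", class(out))
  attr(out, "trait") <- "g"
  attr(out, "n_eff") <- n_eff
  attr(out, "skipped") <- sum(!complete)
  attr(out, "mode") <- "fixed"
  out
}

#' Effective sample size of derived summary statistics
#'
#' `N_eff = mean over variants of (Z_j / beta_j)^2 / (2 p_j (1 - p_j))`,
#' restricted to variants with minor-allele frequency strictly between
#' `window[1]` and `window[2]` (default 0.1-0.4, the common practice for
#' latent-factor GWAS outputs). When no variant falls in the window the
#' median over all variants is used instead, with a message.
#'
#' @param x A tibble with per-allele `beta`, `se`, `z` and `freq` columns.
#' @param window Frequency window, default `c(0.1, 0.4)`.
#' @return A single effective sample size.
#' @export
estimate_effective_n <- function(x, window = c(0.1, 0.4)) {
  maf <- pmin(x$freq, 1 - x$freq)
  per_variant <- (x$z / x$beta)^2 / (2 * x$freq * (1 - x$freq))
  in_win <- is.finite(per_variant) & !is.na(maf) & maf > window[1] & maf < window[2]
  if (!any(in_win)) {
    inform("estimate_effective_n: no variants in the frequency window; using the median over all variants")
    return(stats::median(per_variant[is.finite(per_variant)]))
  }
  mean(per_variant[in_win])
}

#' Run the g-correction for every trait in the panel
#'
#' @inheritParams correct_trait
#' @param dir Optional output directory; one corrected-sumstats file per
#'   trait plus a JSON run manifest.
#' @return A named list of `corrected_sumstats`, one per trait.
#' @export
correct_all_traits <- function(panel, solution, mode = c("fixed", "refit"),
                               dir = NULL) {
  mode <- match.arg(mode)
  out <- purrr::map(setNames(panel$traits, panel$traits), function(t) {
    correct_trait(panel, solution, t, mode = mode,
                  path = if (is.null(dir)) NULL else file.path(dir, paste0(t, ".gcorrected.tsv")))
  })
  if (!is.null(dir)) {
    jsonlite::write_json(
      list(mode = mode,
           n_eff = purrr::map_dbl(out, ~ attr(.x, "n_eff")),
           skipped = purrr::map_int(out, ~ as.integer(attr(.x, "skipped")))),
      file.path(dir, "correction_manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Assemble corrected traits (plus optional extra traits) into a panel
#'
#' Builds a `sumstats_panel` from a list of corrected summary statistics so
#' the post-correction genetic landscape can be estimated with the same LDSC
#' machinery as the original panel. Z-scores and effective sample sizes are
#' taken from each corrected set; the variant set is the intersection.
#'
#' @param corrected Named list of `corrected_sumstats`.
#' @param ld An [ld_score_table()] (or the original panel, whose LD scores
#'   are reused).
#' @return A `sumstats_panel`.
#' @export
panel_from_corrected <- function(corrected, ld) {
  stopifnot(length(corrected) >= 2)
  if (inherits(ld, "sumstats_panel")) {
    ld <- ld_score_table(tibble(variant_id = ld$variants$variant_id, l2 = ld$ld), M = ld$M)
  }
  shared <- Reduce(intersect, purrr::map(corrected, "variant_id"))
  shared <- shared[shared %in% ld$variant_id]
  first <- corrected[[1]][match(shared, corrected[[1]]$variant_id), ]
  Z <- vapply(corrected, function(cs) cs$z[match(shared, cs$variant_id)],
              numeric(length(shared)))
  colnames(Z) <- names(corrected)
  structure(list(
    traits = names(corrected),
    variants = dplyr::select(first, "variant_id", "chrom", "pos", "a1", "a2", "freq"),
    Z = Z,
    n = purrr::map_dbl(corrected, ~ attr(.x, "n_eff")),
    ld = pmax(ld$l2[match(shared, ld$variant_id)], 1),
    M = attr(ld, "M"),
    log = list("assembled from corrected summary statistics")
  ), class = "sumstats_panel")
}
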