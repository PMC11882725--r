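# LD score regression: per-trait heritability, cross-trait genetic
# covariance, and joint assembly of S (genetic covariance matrix) and V
# (block-jackknife sampling covariance of vech(S)).

# Weighted straight-line fit of y on l with delete-one-block estimates.
# Sufficient statistics are accumulated per block, so the jackknife is a
# subtraction, not a refit. NA entries in y are masked (blocks stay aligned).
ldsc_line <- function(y, l, block_id, weights) {
  ok <- is.finite(y)
  w <- ifelse(ok, weights, 0)
  y0 <- ifelse(ok, y, 0)
  sw   <- as.vector(rowsum(w, block_id))
  swl  <- as.vector(rowsum(w * l, block_id))
  swll <- as.vector(rowsum(w * l * l, block_id))
  swy  <- as.vector(rowsum(w * y0, block_id))
  swly <- as.vector(rowsum(w * l * y0, block_id))

  solve_line <- function(sw, swl, swll, swy, swly) {
    det <- sw * swll - swl^2
    cbind(intercept = (swy * swll - swl * swly) / det,
          slope = (sw * swly - swl * swy) / det)
  }
  tot <- c(sum(sw), sum(swl), sum(swll), sum(swy), sum(swly))
  full <- solve_line(tot[1], tot[2], tot[3], tot[4], tot[5])
  del <- solve_line(tot[1] - sw, tot[2] - swl, tot[3] - swll,
                    tot[4] - swy, tot[5] - swly)
  list(intercept = unname(full[1, "intercept"]), slope = unname(full[1, "slope"]),
       intercept_del = unname(del[, "intercept"]), slope_del = unname(del[, "slope"]),
       n_used = sum(ok))
}

# Two-step LDSC weights: 1 / (l * (1 + s1_a l) * (1 + s1_b l)) where s1_t is
# the clamped first-pass unweighted chi-square slope of trait t (= n h^2 / M
# in expectation). For a = b this is the canonical univariate weighting
# 1 / (l (1 + n h2 l / M)^2).
ldsc_weights <- function(l, s1_a, s1_b = s1_a) {
  1 / (l * (1 + max(s1_a, 0) * l) * (1 + max(s1_b, 0) * l))
}

firstpass_slope <- function(y, l) {
  ok <- is.finite(y)
  stats::cov(y[ok], l[ok]) / stats::var(l[ok])
}

default_n_blocks <- function(m, n_blocks = NULL) {
  if (!is.null(n_blocks)) return(n_blocks)
  max(2L, min(200L, m %/% 50L))
}

# One LDSC regression for a trait pair (a == b gives the chi-square
# regression). Returns estimates on the genetic-covariance scale
# (slope * M / sqrt(n_a n_b)) plus delete-one-block values.
ldsc_pair <- function(panel, a, b, block_id, s1) {
  y <- panel$Z[, a] * panel$Z[, b]
  l <- panel$ld
  w <- ldsc_weights(l, s1[a], s1[b])
  fit <- ldsc_line(y, l, block_id, w)
  scale <- panel$M / sqrt(panel$n[[a]] * panel$n[[b]])
  nb <- max(block_id)
  est <- fit$slope * scale
  est_del <- fit$slope_del * scale
  list(slope = fit$slope, intercept = fit$intercept,
       est = est, est_del = est_del,
       se = jackknife_se(est_del),
       intercept_se = jackknife_se(fit$intercept_del),
       n_blocks = nb, n_used = fit$n_used)
}

new_ldsc_fit <- function(x, type, traits) {
  structure(c(x, list(type = type, traits = traits)), class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  lab <- if (x$type == "h2") sprintf("h2(%s)", x$traits[1]) else sprintf("cov_g(%s, %s)", x$traits[1], x$traits[2])
  cat(sprintf("<ldsc_fit> %s = %.4f (SE %.4f), intercept = %.3f (SE %.3f), %d variants, %d jackknife blocks\n",
              lab, x$est, x$se, x$intercept, x$intercept_se, x$n_used, x$n_blocks))
  invisible(x)
}

#' SNP heritability by LD score regression
#'
#' Regresses per-variant chi-square statistics on LD scores with the
#' canonical two-step weights `1 / (l (1 + n h2 l / M)^2)` (a first-pass
#' unweighted slope supplies the heteroscedasticity term; LD scores are
#' floored at 1), free intercept, and a delete-one-block jackknife over
#' contiguous variant blocks for standard errors. The heritability estimate
#' is `slope * M / n`. Negative estimates are reported and flagged, not
#' truncated.
#'
#' @param panel A `sumstats_panel`.
#' @param trait Trait label.
#' @param n_blocks Number of jackknife blocks; default `min(200,
#'   floor(m / 50))`.
#' @return An `ldsc_fit` with fields `est` (h2), `se`, `slope`, `intercept`,
#'   `intercept_se`, `est_del` (delete-one-block estimates), `n_blocks`,
#'   `n_used`.
#' @export
ldsc_h2 <- function(panel, trait, n_blocks = NULL) {
  stopifnot(trait %in% panel$traits)
  m <- nrow(panel$Z)
  nb <- default_n_blocks(m, n_blocks)
  block_id <- jackknife_blocks(m, nb)
  s1 <- setNames(firstpass_slope(panel$Z[, trait]^2, panel$ld), trait)
  fit <- ldsc_pair(panel, trait, trait, block_id, s1)
  if (fit$est < 0) warn(sprintf("negative h2 estimate for %s (%.4f); reported as-is", trait, fit$est))
  new_ldsc_fit(fit, "h2", trait)
}

#' Cross-trait genetic covariance by LD score regression
#'
#' Regresses the per-variant Z-score product of two traits on LD scores;
#' the genetic covariance estimate is `slope * M / sqrt(n_a n_b)` and the
#' intercept absorbs sample overlap. With `trait_b == trait_a` this reduces
#' exactly to [ldsc_h2()].
#'
#' @inheritParams ldsc_h2
#' @param trait_a,trait_b Trait labels.
#' @return An `ldsc_fit` (see [ldsc_h2()]).
#' @export
ldsc_cross <- function(panel, trait_a, trait_b, n_blocks = NULL) {
  stopifnot(trait_a %in% panel$traits, trait_b %in% panel$traits)
  m <- nrow(panel$Z)
  nb <- default_n_blocks(m, n_blocks)
  block_id <- jackknife_blocks(m, nb)
  s1 <- vapply(c(trait_a, trait_b), function(t) firstpass_slope(panel$Z[, t]^2, panel$ld), 0)
  fit <- ldsc_pair(panel, trait_a, trait_b, block_id, s1)
  new_ldsc_fit(fit, "cross", c(trait_a, trait_b))
}

#' Genetic covariance matrix S with joint jackknife sampling matrix V
#'
#' Runs the LDSC regression for all `k(k+1)/2` trait pairs and assembles the
#' k x k genetic covariance matrix S (diagonal = SNP heritabilities). The
#' sampling covariance V of `vech(S)` is estimated jointly: every entry uses
#' the same contiguous block partition, and V is the covariance of the
#' jackknife pseudovalues across all entries, so cross-entry sampling
#' dependence is captured. Half-vectorization is column-major
#' lower-triangular: (1,1), (2,1), ..., (k,1), (2,2), ...
#'
#' When the assembled S has an eigenvalue below `-1e-8` it is smoothed by
#' eigenvalue flooring at zero (the largest element change is logged); the
#' raw matrix is kept alongside.
#'
#' @inheritParams ldsc_h2
#' @return A `genetic_covariance`: `S` (smoothed), `S_raw`, `V`, `traits`,
#'   `intercepts`, `se` (per-entry jackknife SEs as a k x k matrix),
#'   `est_del` (delete-one-block estimates, `n_blocks` x `k(k+1)/2`),
#'   `smoothing`, `n_blocks`, `n`, `M`.
#' @export
ldsc_covariance <- function(panel, n_blocks = NULL) {
  k <- length(panel$traits)
  m <- nrow(panel$Z)
  nb <- default_n_blocks(m, n_blocks)
  block_id <- jackknife_blocks(m, nb)
  s1 <- vapply(panel$traits, function(t) firstpass_slope(panel$Z[, t]^2, panel$ld), 0)

  pairs <- vech_pairs(k)
  p_star <- nrow(pairs)
  S <- matrix(0, k, k, dimnames = list(panel$traits, panel$traits))
  intercepts <- S
  se <- S
  est_del <- matrix(NA_real_, nb, p_star)
  ests <- numeric(p_star)

  for (e in seq_len(p_star)) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    fit <- tryCatch(ldsc_pair(panel, i, j, block_id, s1),
                    error = function(err) {
                      abort(sprintf("LDSC regression failed for pair (%s, %s): %s",
                                    panel$traits[i], panel$traits[j], conditionMessage(err)))
                    })
    ests[e] <- fit$est
    est_del[, e] <- fit$est_del
    S[i, j] <- S[j, i] <- fit$est
    intercepts[i, j] <- intercepts[j, i] <- fit$intercept
    se[i, j] <- se[j, i] <- fit$se
  }

  # pseudovalues; V = cov(P) / n_blocks
  P <- nb * matrix(ests, nb, p_star, byrow = TRUE) - (nb - 1) * est_del
  V <- stats::cov(P) / nb

  sm <- nearest_psd(S)
  structure(list(
    S = sm$mat, S_raw = S, V = V,
    traits = panel$traits,
    intercepts = intercepts, se = se,
    est_del = est_del,
    smoothing = list(applied = sm$smoothed, max_change = sm$max_change),
    n_blocks = nb, n = panel$n, M = panel$M, m_variants = m
  ), class = "genetic_covariance")
}

#' @export
print.genetic_covariance <- function(x, ...) {
  cat(sprintf("<genetic_covariance> %d traits, %d jackknife blocks over %d variants\n",
              length(x$traits), x$n_blocks, x$m_variants))
  cat("h2 (diag of S):", paste(format(diag(x$S), digits = 3), collapse = ", "), "\n")
  if (x$smoothing$applied) {
    cat(sprintf("PSD smoothing applied (max element change %.2e)\n", x$smoothing$max_change))
  }
  invisible(x)
}

#' @describeIn ldsc_covariance Tidy the S matrix into one row per trait pair
#'   with estimate and jackknife SE.
#' @param x A `genetic_covariance`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.genetic_covariance <- function(x, ...) {
  pairs <- vech_pairs(length(x$traits))
  tibble(
    trait_a = x$traits[pairs[, 1]],
    trait_b = x$traits[pairs[, 2]],
    covariance = x$S[pairs],
    se = x$se[pairs],
    intercept = x$intercepts[pairs]
  )
}

#' Genetic correlation matrix from a genetic covariance object
#'
#' `r_ab = S_ab / sqrt(S_aa S_bb)` with a unit diagonal; standard errors come
#' from jackknifing the ratio (the same delete-one-block estimates that built
#' V). Traits with a non-positive heritability estimate get `NA` correlations
#' and are flagged, never fabricated.
#'
#' @param gcov A `genetic_covariance` from [ldsc_covariance()].
#' @return An `rg_matrix` object: `rg`, `se` (k x k matrices), `undefined`
#'   (flagged trait labels), `traits`.
#' @export
rg_matrix <- function(gcov) {
  k <- length(gcov$traits)
  S <- gcov$S
  h2 <- diag(S)
  bad <- gcov$traits[h2 <= 0]
  rg <- matrix(NA_real_, k, k, dimnames = dimnames(S))
  se <- rg
  pairs <- vech_pairs(k)
  # map (i, j) -> vech index for delete-one lookups
  vidx <- matrix(0L, k, k)
  vidx[pairs] <- seq_len(nrow(pairs))
  vidx[pairs[, c(2, 1)]] <- seq_len(nrow(pairs))

  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    if (i == j) { rg[i, i] <- 1; se[i, i] <- 0; next }
    if (h2[i] <= 0 || h2[j] <= 0) next
    rg[i, j] <- rg[j, i] <- S[i, j] / sqrt(h2[i] * h2[j])
    d_ij <- gcov$est_del[, vidx[i, j]]
    d_ii <- gcov$est_del[, vidx[i, i]]
    d_jj <- gcov$est_del[, vidx[j, j]]
    ok <- d_ii > 0 & d_jj > 0
    r_del <- d_ij[ok] / sqrt(d_ii[ok] * d_jj[ok])
    se[i, j] <- se[j, i] <- if (sum(ok) >= 2) jackknife_se(r_del) else NA_real_
  }
  structure(list(rg = rg, se = se, undefined = bad, traits = gcov$traits),
            class = "rg_matrix")
}

#' @export
print.rg_matrix <- function(x, ...) {
  cat(sprintf("<rg_matrix> %d traits\n", length(x$traits)))
  print(round(x$rg, 3))
  if (length(x$undefined) > 0) {
    cat("undefined for traits with non-positive h2:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn rg_matrix Tidy into one row per unordered trait pair.
#' @param x An `rg_matrix`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rg_matrix <- function(x, ...) {
  k <- length(x$traits)
  pairs <- vech_pairs(k)
  off <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  tibble(
    trait_a = x$traits[off[, 1]],
    trait_b = x$traits[off[, 2]],
    rg = x$rg[off],
    se = x$se[off]
  )
}
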