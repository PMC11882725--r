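# One-common-factor structural model on the genetic covariance matrix:
# Sigma(theta) = lambda lambda' + diag(u), latent variance fixed to 1,
# fitted by diagonally weighted least squares (W = diag(V)^-1) with a
# sandwich parameter covariance, or optionally by maximum likelihood.

# Jacobian of vech(Sigma) w.r.t. theta = (lambda_1..k, u_1..k).
factor_jacobian <- function(lambda, k) {
  pairs <- vech_pairs(k)
  p_star <- nrow(pairs)
  J <- matrix(0, p_star, 2 * k)
  for (e in seq_len(p_star)) {
    a <- pairs[e, 1]; b <- pairs[e, 2]
    J[e, a] <- J[e, a] + lambda[b]
    J[e, b] <- J[e, b] + lambda[a]
    if (a == b) J[e, k + a] <- 1
  }
  J
}

model_sigma_vech <- function(theta, k) {
  lambda <- theta[seq_len(k)]
  u <- theta[k + seq_len(k)]
  vech(tcrossprod(lambda) + diag(u, k))
}

# Browne-style residual-based test statistic:
# T = r' (Vi - Vi D (D' Vi D)^-1 D' Vi) r with Vi = pinv(V).
residual_chisq <- function(r, V, Delta) {
  Vi <- sym_pinv(V)
  A <- Vi %*% Delta
  U <- Vi - A %*% sym_pinv(crossprod(Delta, A)) %*% t(A)
  max(0, drop(t(r) %*% U %*% r))
}

#' Fit the one-common-factor model to a genetic covariance matrix
#'
#' Minimizes `(vech(S) - vech(Sigma(theta)))' W (vech(S) - vech(Sigma))`
#' with `W = diag(V)^-1` (DWLS; `estimator = "ML"` uses the normal-theory
#' discrepancy instead) over loadings and residual variances, the latent
#' variance fixed to 1. The parameter covariance is the sandwich
#' `(D'WD)^-1 D'W V W D (D'WD)^-1` with `D` the Jacobian at the optimum, so
#' standard errors reflect the full sampling matrix V even though only its
#' diagonal enters the weights. The standardized solution (loadings and
#' residual variances on the genetic correlation scale, which satisfy
#' `lambda^2 + u = 1` by construction) and its delta-method SEs are
#' reported; the factor is oriented so the mean loading is positive.
#'
#' Fit statistics: a residual-based model chi-square evaluated against the
#' full V, with `df = k(k+1)/2 - 2k`; CFI against the independence model
#' (free variances, no factor); SRMR on the standardized residuals.
#'
#' @param gcov A `genetic_covariance` from [ldsc_covariance()], or a list
#'   with elements `S` (k x k), `V` (sampling covariance of `vech(S)`;
#'   identity if omitted), and optionally `traits`.
#' @param estimator `"DWLS"` (default) or `"ML"`.
#' @param heywood `"flag"` (default) reports negative residual variances
#'   as-is; `"bound"` refits with residual variances bounded at zero.
#' @param max_restarts Jittered restarts tried on non-convergence.
#' @return A `factor_solution`.
#' @export
fit_common_factor <- function(gcov, estimator = c("DWLS", "ML"),
                              heywood = c("flag", "bound"),
                              max_restarts = 3) {
  estimator <- match.arg(estimator)
  heywood <- match.arg(heywood)
  S <- gcov$S
  k <- nrow(S)
  if (k < 3) abort("one-factor model needs k >= 3 traits for identification")
  traits <- gcov$traits %||% colnames(S) %||% paste0("trait", seq_len(k))
  p_star <- k * (k + 1) / 2
  V <- gcov$V %||% diag(p_star)
  s <- vech(S)
  w <- 1 / pmax(diag(V), 1e-12)

  objective <- if (estimator == "DWLS") {
    function(theta) {
      r <- s - model_sigma_vech(theta, k)
      sum(w * r^2)
    }
  } else {
    logdetS <- determinant(S, logarithm = TRUE)$modulus
    function(theta) {
      Sig <- tcrossprod(theta[seq_len(k)]) + diag(theta[k + seq_len(k)], k)
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      2 * sum(log(diag(ch))) + sum(diag(chol2inv(ch) %*% S)) - as.numeric(logdetS) - k
    }
  }
  gradient <- if (estimator == "DWLS") {
    function(theta) {
      r <- s - model_sigma_vech(theta, k)
      J <- factor_jacobian(theta[seq_len(k)], k)
      as.vector(-2 * crossprod(J, w * r))
    }
  } else NULL

  # start: loadings = sqrt(mean off-diagonal of standardized S), on the
  # covariance scale; residuals soak up the rest of each variance
  d0 <- pmax(diag(S), 1e-6)
  R0 <- S / sqrt(tcrossprod(d0))
  mean_off <- mean(R0[lower.tri(R0)])
  l_std0 <- sqrt(min(max(mean_off, 0.01), 0.95))
  start <- c(l_std0 * sqrt(d0), pmax(d0 * (1 - l_std0^2), 1e-6))

  run_optim <- function(par, bounded = FALSE) {
    if (bounded) {
      stats::optim(par, objective, gradient, method = "L-BFGS-B",
                   lower = c(rep(-Inf, k), rep(0, k)),
                   control = list(maxit = 2000, factr = 10))
    } else {
      stats::optim(par, objective, gradient, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-14))
    }
  }

  jitters <- c(1, 0.7, 1.3, -1)
  fit <- NULL
  restarts <- 0L
  for (j in seq_len(1 + max_restarts)) {
    cand <- tryCatch(run_optim(start * rep(c(jitters[j], 1), each = k)),
                     error = function(e) NULL)
    if (!is.null(cand) && cand$convergence == 0) { fit <- cand; break }
    restarts <- restarts + 1L
  }
  if (is.null(fit)) {
    abort(sprintf("one-factor model did not converge after %d restarts (estimator %s)",
                  max_restarts, estimator))
  }

  theta <- fit$par
  lambda <- theta[seq_len(k)]
  u <- theta[k + seq_len(k)]

  hw <- u < 0
  if (any(hw) && heywood == "bound") {
    fit <- run_optim(c(lambda, pmax(u, 0)), bounded = TRUE)
    theta <- fit$par
    lambda <- theta[seq_len(k)]
    u <- theta[k + seq_len(k)]
  }

  # orientation: mean standardized loading positive
  sigma <- lambda^2 + u
  if (mean(lambda / sqrt(sigma)) < 0) lambda <- -lambda

  # sandwich covariance (DWLS weights at the optimum)
  J <- factor_jacobian(lambda, k)
  JtW <- t(J) * rep(w, each = 2 * k)
  bread <- sym_pinv(JtW %*% J)
  vcov_theta <- bread %*% (JtW %*% V %*% t(JtW)) %*% bread

  # standardized solution + delta-method SEs
  lam_std <- lambda / sqrt(sigma)
  u_std <- u / sigma
  G <- matrix(0, 2 * k, 2 * k)  # d(std params)/d(theta), block 2x2 per trait
  for (t in seq_len(k)) {
    s32 <- sigma[t]^(-1.5)
    G[t, t] <- u[t] * s32                      # d lam_std / d lambda
    G[t, k + t] <- -0.5 * lambda[t] * s32      # d lam_std / d u
    G[k + t, t] <- -2 * lambda[t] * u[t] / sigma[t]^2
    G[k + t, k + t] <- lambda[t]^2 / sigma[t]^2
  }
  vcov_std <- G %*% vcov_theta %*% t(G)
  se_std <- sqrt(pmax(diag(vcov_std), 0))

  # fit statistics
  r_hat <- s - model_sigma_vech(c(lambda, u), k)
  chisq <- residual_chisq(r_hat, V, J)
  df <- p_star - 2 * k
  # independence model: free variances only, fitted exactly by the diagonal
  r_indep <- s - vech(diag(diag(S), k))
  J_indep <- factor_jacobian(rep(0, k), k)[, k + seq_len(k), drop = FALSE]
  chisq_indep <- residual_chisq(r_indep, V, J_indep)
  df_indep <- p_star - k
  num <- max(chisq - df, 0)
  den <- max(chisq_indep - df_indep, num)
  cfi <- if (den <= 0) 1 else 1 - num / den

  R_obs <- S / sqrt(tcrossprod(pmax(diag(S), 1e-12)))
  Sig_hat <- tcrossprod(lambda) + diag(u, k)
  R_mod <- Sig_hat / sqrt(tcrossprod(pmax(diag(Sig_hat), 1e-12)))
  srmr <- sqrt(mean(vech(R_obs - R_mod)^2))

  structure(list(
    traits = traits,
    loadings = setNames(lam_std, traits),
    loadings_se = setNames(se_std[seq_len(k)], traits),
    resid = setNames(u_std, traits),
    resid_se = setNames(se_std[k + seq_len(k)], traits),
    variance_share = setNames(lam_std^2, traits),
    loadings_cov = setNames(lambda, traits),
    u_cov = setNames(u, traits),
    sigma = setNames(sigma, traits),
    vcov = vcov_theta,
    vcov_std = vcov_std,
    S_obs = S, w_S = w,
    heywood = setNames(hw, traits),
    fit = list(chisq = chisq, df = df,
               p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
               chisq_indep = chisq_indep, df_indep = df_indep,
               cfi = cfi, srmr = srmr),
    estimator = estimator,
    convergence = list(converged = TRUE, objective = fit$value,
                       counts = fit$counts, restarts = restarts)
  ), class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  k <- length(x$traits)
  cat(sprintf("<factor_solution> one-factor model, %d traits (%s)\n", k, x$estimator))
  print(tidy(x), n = k)
  cat(sprintf("chisq(%d) = %.3f, CFI = %.3f, SRMR = %.3f; mean loading = %.3f, mean g share = %.1f%%\n",
              x$fit$df, x$fit$chisq, x$fit$cfi, x$fit$srmr,
              mean(x$loadings), 100 * mean(x$variance_share)))
  if (any(x$heywood)) cat("Heywood case flagged for:", paste(x$traits[x$heywood], collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_common_factor One row per trait: standardized loading,
#'   residual variance, their SEs, and the factor variance share.
#' @param x A `factor_solution`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.factor_solution <- function(x, ...) {
  tibble(
    trait = x$traits,
    loading = unname(x$loadings),
    loading_se = unname(x$loadings_se),
    resid_var = unname(x$resid),
    resid_se = unname(x$resid_se),
    g_share = unname(x$variance_share),
    heywood = unname(x$heywood)
  )
}

#' @describeIn fit_common_factor One-row model summary with fit indices.
#' @exportS3Method generics::glance
glance.factor_solution <- function(x, ...) {
  tibble(
    chisq = x$fit$chisq, df = x$fit$df, p_value = x$fit$p_value,
    cfi = x$fit$cfi, srmr = x$fit$srmr,
    mean_loading = mean(x$loadings),
    mean_g_share = mean(x$variance_share),
    estimator = x$estimator,
    converged = x$convergence$converged
  )
}

#' Decompose genetic variance into factor and specific shares
#'
#' Per trait, the share of genetic variance carried by the common factor is
#' the squared standardized loading and the specific share is the
#' standardized residual variance; the two sum to 1 on the standardized
#' solution. Panel means of both are attached as attributes.
#'
#' @param solution A `factor_solution`.
#' @return A tibble with columns `trait`, `g_share`, `specific_share`, and
#'   attributes `mean_g_share`, `mean_specific_share`.
#' @export
variance_decomposition <- function(solution) {
  out <- tibble(
    trait = solution$traits,
    g_share = unname(solution$loadings^2),
    specific_share = unname(solution$resid)
  )
  attr(out, "mean_g_share") <- mean(out$g_share)
  attr(out, "mean_specific_share") <- mean(out$specific_share)
  out
}
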