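# Independent oracles and small fixture builders used across the suite.

# Brute-force weighted straight-line fit via the normal equations, written
# against base matrix algebra only (independent of the engine's block-sum
# path).
oracle_wls <- function(y, l, w) {
  X <- cbind(1, l)
  ok <- is.finite(y)
  XtW <- t(X[ok, , drop = FALSE] * w[ok])
  beta <- solve(XtW %*% X[ok, , drop = FALSE], XtW %*% y[ok])
  c(intercept = beta[1], slope = beta[2])
}

# The engine's documented two-step weights, recomputed independently.
oracle_weights <- function(y_a, y_b, l) {
  s1 <- function(y) {
    ok <- is.finite(y)
    max(stats::cov(y[ok], l[ok]) / stats::var(l[ok]), 0)
  }
  1 / (l * (1 + s1(y_a^2) * l) * (1 + s1(y_b^2) * l))
}

# Delete-one-block jackknife by literally refitting the weighted regression
# for every deleted block; returns the joint sampling covariance of the
# scaled estimates across all supplied trait pairs.
oracle_joint_jackknife <- function(panel, n_blocks) {
  m <- nrow(panel$Z)
  block_id <- sort(rep_len(seq_len(n_blocks), m))
  k <- length(panel$traits)
  pairs <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "col"], pairs[, "row"]), , drop = FALSE]
  ests <- numeric(nrow(pairs))
  est_del <- matrix(0, n_blocks, nrow(pairs))
  for (e in seq_len(nrow(pairs))) {
    a <- pairs[e, 1]; b <- pairs[e, 2]
    y <- panel$Z[, a] * panel$Z[, b]
    w <- oracle_weights(panel$Z[, a], panel$Z[, b], panel$ld)
    scale <- panel$M / sqrt(panel$n[[a]] * panel$n[[b]])
    ests[e] <- oracle_wls(y, panel$ld, w)["slope"] * scale
    for (bl in seq_len(n_blocks)) {
      keep <- block_id != bl
      est_del[bl, e] <- oracle_wls(y[keep], panel$ld[keep], w[keep])["slope"] * scale
    }
  }
  P <- n_blocks * matrix(ests, n_blocks, nrow(pairs), byrow = TRUE) -
    (n_blocks - 1) * est_del
  list(ests = ests, est_del = est_del, V = stats::cov(P) / n_blocks)
}

# A small quick panel for unit tests.
small_panel <- function(k = 3, m = 3000, seed = 1, loadings = seq(0.5, 0.8, length.out = k),
                        h2 = 0.25, n = 20000, ...) {
  truth <- truth_set(k = k, loadings = loadings, h2 = h2, n = n, m = m,
                     block_size = 5, rho = c(0.1, 0.8),
                     traits = paste0("t", seq_len(k)), ...)
  simulate_panel(truth, seed = seed)
}

# A hand-built panel with exactly prescribed Z-scores and LD scores.
manual_panel <- function(Z, l, n, M = length(l)) {
  k <- ncol(Z)
  traits <- if (is.null(colnames(Z))) paste0("t", seq_len(k)) else colnames(Z)
  colnames(Z) <- traits
  structure(list(
    traits = traits,
    variants = tibble::tibble(
      variant_id = paste0("v", seq_len(nrow(Z))),
      chrom = "1", pos = as.numeric(seq_len(nrow(Z))),
      a1 = "A", a2 = "G", freq = rep(0.3, nrow(Z))
    ),
    Z = Z, n = stats::setNames(rep_len(n, k), traits),
    ld = pmax(l, 1), M = M, log = list()
  ), class = "sumstats_panel")
}

# A minimal factor_solution for constructed landscape tests.
fake_solution <- function(loadings, traits = names(loadings)) {
  k <- length(loadings)
  structure(list(
    traits = traits,
    loadings = stats::setNames(loadings, traits),
    loadings_cov = stats::setNames(loadings, traits),
    u_cov = stats::setNames(1 - loadings^2, traits),
    resid = stats::setNames(1 - loadings^2, traits),
    vcov = matrix(0, 2 * k, 2 * k)
  ), class = "factor_solution")
}

# A genetic_covariance wrapper around a fixed S (zero sampling noise), for
# tests of downstream algebra.
fake_gcov <- function(S, traits = colnames(S)) {
  k <- nrow(S)
  dimnames(S) <- list(traits, traits)
  p_star <- k * (k + 1) / 2
  v <- S[lower.tri(S, diag = TRUE)]
  structure(list(
    S = S, S_raw = S, V = diag(1e-8, p_star),
    traits = traits,
    intercepts = matrix(1, k, k), se = matrix(0, k, k),
    est_del = matrix(rep(v, each = 2), 2, p_star),
    smoothing = list(applied = FALSE, max_change = 0),
    n_blocks = 2, n = stats::setNames(rep(1e4, k), traits), M = 1e4,
    m_variants = 1e4
  ), class = "genetic_covariance")
}

write_sumstats_file <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}
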