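# Internal linear-algebra and indexing helpers shared across modules.

# Half-vectorization order used everywhere: column-major lower triangle,
# i.e. (1,1),(2,1),...,(k,1),(2,2),(3,2),... Matches the layout of S and V.
vech_pairs <- function(k) {
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

unvech <- function(v, k) {
  M <- matrix(0, k, k)
  M[lower.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M))
}

# Moore-Penrose pseudoinverse via symmetric eigendecomposition.
sym_pinv <- function(A, tol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

# Eigenvalue flooring at zero; returns the input untouched when already PSD
# (min eigenvalue >= -tol).
nearest_psd <- function(A, tol = 1e-8) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    return(list(mat = A, smoothed = FALSE, max_change = 0))
  }
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  list(mat = out, smoothed = TRUE, max_change = max(abs(out - A)))
}

# Contiguous near-equal block assignment for the delete-one-block jackknife.
jackknife_blocks <- function(m, n_blocks) {
  if (n_blocks < 2) abort("jackknife needs at least 2 blocks")
  if (m < n_blocks) abort(sprintf("fewer variants (%d) than jackknife blocks (%d)", m, n_blocks))
  sort(rep_len(seq_len(n_blocks), m))
}

# Jackknife SE from delete-one estimates.
jackknife_se <- function(theta_del) {
  nb <- length(theta_del)
  sqrt((nb - 1) / nb * sum((theta_del - mean(theta_del))^2))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed != round(seed)) {
    abort("`seed` must be a single integer")
  }
  as.integer(seed)
}
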