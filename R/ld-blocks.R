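#' Exchangeable LD-block structure
#'
#' Partitions `m` variants into contiguous blocks of size `block_size` with
#' an exchangeable (compound-symmetric) correlation matrix inside each block:
#' unit diagonal, off-diagonal `rho`, zero correlation between blocks. Under
#' this structure every variant in a block with correlation `rho_b` has the
#' closed-form LD score `l_j = 1 + (block_size - 1) * rho_b^2`, which keeps
#' both the LD-score regressor and the marginal-effect convolution exact.
#'
#' `rho` may be a single value (every block identical), a pair interpreted
#' as a range spread evenly across blocks, or one value per block. A single
#' `rho` makes all LD scores equal, which is fine for closed-form checks but
#' leaves the LD score regression without a usable regressor (slope and
#' intercept become collinear); panels meant for LDSC estimation should use
#' a range, as [truth_set()] does by default.
#'
#' @param m Total number of variants; must be divisible by `block_size`.
#' @param block_size Variants per block (1 = no LD).
#' @param rho Within-block correlation(s), each in `[0, 1)`: length 1, a
#'   length-2 range, or one per block.
#' @return An `ld_blocks` object: block assignment, per-block correlations,
#'   and per-variant LD scores.
#' @export
#' @examples
#' ld <- make_ld_blocks(100, block_size = 5, rho = 0.5)
#' unique(ld$l2)  # 1 + 4 * 0.25 = 2
make_ld_blocks <- function(m, block_size, rho) {
  if (any(rho < 0) || any(rho >= 1)) abort("`rho` must be in [0, 1)")
  if (block_size < 1 || m %% block_size != 0) {
    abort(sprintf("m = %d is not divisible into blocks of size %d", m, block_size))
  }
  n_block <- m %/% block_size
  rho_block <- if (length(rho) == 1) {
    rep(rho, n_block)
  } else if (length(rho) == 2) {
    seq(rho[1], rho[2], length.out = n_block)
  } else {
    rep_len(rho, n_block)
  }
  block <- rep(seq_len(n_block), each = block_size)
  structure(list(
    m = m, block_size = block_size, rho = rho_block,
    n_block = n_block,
    block = block,
    rho_variant = rho_block[block],
    l2 = 1 + (block_size - 1) * rho_block[block]^2
  ), class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  cat(sprintf("<ld_blocks> %d variants in %d blocks of %d (rho %s, mean l_j = %.3f)\n",
              x$m, x$n_block, x$block_size,
              if (length(unique(x$rho)) == 1) sprintf("= %g", x$rho[1])
              else sprintf("in [%g, %g]", min(x$rho), max(x$rho)),
              mean(x$l2)))
  invisible(x)
}

#' @rdname make_ld_blocks
#' @param ld An `ld_blocks` object.
#' @param variant_id Variant identifiers to attach (default `rs1..rsm`).
#' @return For `ld_blocks_table()`, an [ld_score_table()] over the block
#'   structure with `M = m`.
#' @export
ld_blocks_table <- function(ld, variant_id = paste0("rs", seq_len(ld$m))) {
  ld_score_table(tibble(variant_id = variant_id, l2 = ld$l2), M = ld$m)
}

# Multiply the block-diagonal LD matrix R into per-variant vector(s):
# (R x)_j = (1 - rho_b) x_j + rho_b * sum(x over j's block).
ld_convolve <- function(ld, x) {
  x <- as.matrix(x)
  if (ld$block_size == 1 || all(ld$rho == 0)) return(x)
  bsums <- rowsum(x, ld$block, reorder = TRUE)
  out <- (1 - ld$rho_variant) * x + ld$rho_variant * bsums[ld$block, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Draw vectors with within-block covariance R (exchangeable), independent
# across columns: sqrt(1 - rho_b) * iid + sqrt(rho_b) * shared block term.
ld_noise <- function(ld, ncol = 1) {
  e <- matrix(stats::rnorm(ld$m * ncol), ld$m, ncol)
  if (ld$block_size == 1 || all(ld$rho == 0)) return(e)
  s <- matrix(stats::rnorm(ld$n_block * ncol), ld$n_block, ncol)
  sqrt(1 - ld$rho_variant) * e + sqrt(ld$rho_variant) * s[ld$block, , drop = FALSE]
}
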