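# Pre- versus post-correction genetic correlation landscape: delta matrices,
# per-test profiles, sign flips, and the loading-difference analysis.

#' Compare genetic correlation landscapes before and after g-correction
#'
#' Computes the delta matrix (post minus pre), mean off-diagonal
#' correlations (unweighted over the k(k-1)/2 unique pairs; pairs undefined
#' on either side are excluded with a count), per-test profile vectors (each
#' test against the other k-1), and sign-flip counts. The raw sign-flip
#' count treats any pre/post sign change; the filtered count requires both
#' estimates to exceed one jackknife SE in magnitude so that noise crossings
#' near zero are not counted.
#'
#' @param rg_pre,rg_post `rg_matrix` objects (or plain correlation matrices
#'   with matching dimnames) for the uncorrected and corrected panels.
#' @return A `landscape_comparison`: matrices `rg_pre`, `rg_post`, `delta`,
#'   `se_pre`, `se_post`; scalars `mean_pre`, `mean_post`, `mean_delta`,
#'   `sign_flips_raw`, `sign_flips`, `n_undefined`; tibbles `pairs` (one
#'   row per unordered pair) and `profiles` (one row per ordered
#'   test/other pair, pre and post).
#' @export
compare_landscapes <- function(rg_pre, rg_post) {
  pre <- as_rg(rg_pre)
  post <- as_rg(rg_post)
  if (!identical(pre$traits, post$traits)) {
    abort("pre and post matrices have different trait labels")
  }
  traits <- pre$traits
  k <- length(traits)
  delta <- post$rg - pre$rg

  pairs_idx <- vech_pairs(k)
  off <- pairs_idx[pairs_idx[, 1] != pairs_idx[, 2], , drop = FALSE]
  pairs <- tibble(
    trait_a = traits[off[, 1]], trait_b = traits[off[, 2]],
    rg_pre = pre$rg[off], se_pre = pre$se[off],
    rg_post = post$rg[off], se_post = post$se[off],
    delta = delta[off]
  )
  ok <- is.finite(pairs$rg_pre) & is.finite(pairs$rg_post)
  flip_raw <- ok & sign(pairs$rg_pre) != sign(pairs$rg_post) &
    pairs$rg_pre != 0 & pairs$rg_post != 0
  flip_filtered <- flip_raw &
    is.finite(pairs$se_pre) & is.finite(pairs$se_post) &
    abs(pairs$rg_pre) > pairs$se_pre & abs(pairs$rg_post) > pairs$se_post

  profiles <- tidyr::pivot_longer(pairs, c("rg_pre", "rg_post"),
                                  names_to = "stage", values_to = "rg")
  profiles <- dplyr::mutate(profiles, stage = sub("^rg_", "", .data$stage))
  # each unordered pair contributes to both tests' profiles
  profiles <- dplyr::bind_rows(
    dplyr::transmute(profiles, test = .data$trait_a, other = .data$trait_b,
                     stage = .data$stage, rg = .data$rg),
    dplyr::transmute(profiles, test = .data$trait_b, other = .data$trait_a,
                     stage = .data$stage, rg = .data$rg)
  )

  structure(list(
    traits = traits,
    rg_pre = pre$rg, rg_post = post$rg, delta = delta,
    se_pre = pre$se, se_post = post$se,
    mean_pre = mean(pairs$rg_pre[ok]),
    mean_post = mean(pairs$rg_post[ok]),
    mean_delta = mean(pairs$delta[ok]),
    sign_flips_raw = sum(flip_raw),
    sign_flips = sum(flip_filtered),
    n_undefined = sum(!ok),
    pairs = pairs,
    profiles = dplyr::arrange(profiles, .data$test, .data$other, .data$stage)
  ), class = "landscape_comparison")
}

as_rg <- function(x) {
  if (inherits(x, "rg_matrix")) return(x)
  if (is.matrix(x)) {
    traits <- colnames(x) %||% paste0("trait", seq_len(ncol(x)))
    return(list(rg = x, se = matrix(NA_real_, nrow(x), ncol(x)), traits = traits))
  }
  abort("expected an rg_matrix or a plain correlation matrix")
}

#' @export
print.landscape_comparison <- function(x, ...) {
  cat(sprintf("<landscape_comparison> %d traits, %d pairs\n",
              length(x$traits), nrow(x$pairs)))
  cat(sprintf("mean off-diagonal rg: %.3f (pre) -> %.3f (post); mean delta %.3f\n",
              x$mean_pre, x$mean_post, x$mean_delta))
  cat(sprintf("sign flips: %d raw, %d beyond 1 SE both sides", x$sign_flips_raw, x$sign_flips))
  if (x$n_undefined > 0) cat(sprintf("; %d pairs undefined", x$n_undefined))
  cat("\n")
  invisible(x)
}

#' @describeIn compare_landscapes One row per unordered trait pair.
#' @param x A `landscape_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.landscape_comparison <- function(x, ...) x$pairs

#' @describeIn compare_landscapes One-row summary.
#' @exportS3Method generics::glance
glance.landscape_comparison <- function(x, ...) {
  tibble(mean_rg_pre = x$mean_pre, mean_rg_post = x$mean_post,
         mean_delta = x$mean_delta, sign_flips_raw = x$sign_flips_raw,
         sign_flips = x$sign_flips, n_undefined = x$n_undefined)
}

#' Do loading differences explain correlation changes?
#'
#' For every unordered trait pair, correlates the absolute difference in
#' standardized factor loadings `|lambda_a - lambda_b|` with the pair's
#' change in genetic correlation (post minus pre). A correlation near zero
#' says the reshaped landscape is not a by-product of how strongly each test
#' loads on the factor. When all loadings are (numerically) equal the
#' correlation is undefined and the result is flagged degenerate rather
#' than returned as a number.
#'
#' @param solution A `factor_solution`.
#' @param comparison A `landscape_comparison` over the same traits.
#' @return A one-row tibble: `estimate`, `n_pairs`, `degenerate`.
#' @export
loading_delta_test <- function(solution, comparison) {
  if (!identical(sort(solution$traits), sort(comparison$traits))) {
    abort("solution and comparison cover different traits")
  }
  k <- length(solution$traits)
  if (k < 3) abort("needs at least 3 traits (3 pairs)")
  lam <- solution$loadings[comparison$traits]
  pairs <- comparison$pairs
  dl <- abs(lam[pairs$trait_a] - lam[pairs$trait_b])
  ok <- is.finite(pairs$delta)
  if (stats::sd(dl[ok]) < 1e-12 || stats::sd(pairs$delta[ok]) < 1e-12) {
    return(tibble(estimate = NA_real_, n_pairs = sum(ok), degenerate = TRUE))
  }
  tibble(estimate = stats::cor(dl[ok], pairs$delta[ok]),
         n_pairs = sum(ok), degenerate = FALSE)
}

#' Genetic correlations of an external trait with the panel, pre and post
#'
#' Harmonizes an external trait's summary statistics with the panel's
#' variants, then estimates its genetic correlation with every test before
#' correction (against the original panel) and after (against the corrected
#' summary statistics), flagging tests whose pre and post intervals
#' (estimate +/- 1.96 SE) exclude each other.
#'
#' @param panel The uncorrected `sumstats_panel`.
#' @param corrected Named list of `corrected_sumstats` (from
#'   [correct_all_traits()]).
#' @param external A record table for the external trait (Z on the panel's
#'   allele orientation, e.g. from [simulate_external_trait()] or
#'   [read_sumstats()] after harmonization).
#' @param n_blocks Jackknife blocks (see [ldsc_h2()]).
#' @param min_overlap Minimum overlapping variants per comparison; fewer
#'   gives an `NA` entry with a flag.
#' @return A tibble: `test`, `rg_pre`, `se_pre`, `rg_post`, `se_post`,
#'   `significant_change`, `flagged`.
#' @export
external_profile <- function(panel, corrected, external, n_blocks = NULL,
                             min_overlap = 200) {
  stopifnot(identical(sort(panel$traits), sort(names(corrected))))
  ld_tbl <- ld_score_table(tibble(variant_id = panel$variants$variant_id,
                                  l2 = panel$ld), M = panel$M)
  ext_n <- stats::median(external$n, na.rm = TRUE)

  one_rg <- function(z_test, n_test, z_ext, ld, M) {
    ok <- is.finite(z_test) & is.finite(z_ext)
    if (sum(ok) < min_overlap) return(c(NA_real_, NA_real_))
    mini <- structure(list(
      traits = c("test", "ext"),
      variants = tibble(variant_id = paste0("v", seq_len(sum(ok)))),
      Z = cbind(test = z_test[ok], ext = z_ext[ok]),
      n = c(test = n_test, ext = ext_n),
      ld = ld[ok], M = M, log = list()
    ), class = "sumstats_panel")
    gc <- ldsc_covariance(mini, n_blocks = n_blocks)
    rg <- rg_matrix(gc)
    c(rg$rg["test", "ext"], rg$se["test", "ext"])
  }

  idx_ext <- match(panel$variants$variant_id, external$variant_id)
  z_ext_panel <- external$z[idx_ext]

  rows <- purrr::map(panel$traits, function(t) {
    pre <- one_rg(panel$Z[, t], panel$n[[t]], z_ext_panel, panel$ld, panel$M)
    cs <- corrected[[t]]
    idx <- match(cs$variant_id, panel$variants$variant_id)
    post <- one_rg(cs$z, attr(cs, "n_eff"), external$z[match(cs$variant_id, external$variant_id)],
                   panel$ld[idx], panel$M)
    tibble(test = t, rg_pre = pre[1], se_pre = pre[2],
           rg_post = post[1], se_post = post[2])
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
                significant_change = is.finite(.data$rg_pre) & is.finite(.data$rg_post) &
                  (abs(.data$rg_pre - .data$rg_post) >
                     1.96 * (.data$se_pre + .data$se_post)),
                flagged = !is.finite(.data$rg_pre) | !is.finite(.data$rg_post))
}
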