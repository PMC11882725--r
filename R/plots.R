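# ggplot2 displays for the fitted objects: loading table, pre/post
# correlation heat maps, and per-test profile dot plots.

#' Plot standardized factor loadings with confidence intervals
#'
#' @param solution A `factor_solution`.
#' @param level Confidence level for the error bars. Default 0.95.
#' @return A ggplot.
#' @export
plot_loadings <- function(solution, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  d <- tidy(solution)
  d$trait <- factor(d$trait, levels = d$trait[order(d$loading)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$loading, y = .data$trait)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$loading - zq * .data$loading_se,
                                         xmax = .data$loading + zq * .data$loading_se),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "standardized loading on genomic g", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_landscapes Heat maps of the pre- and post-correction
#'   genetic correlation matrices side by side.
#' @param object A `landscape_comparison`.
#' @exportS3Method ggplot2::autoplot
autoplot.landscape_comparison <- function(object, ...) {
  k <- length(object$traits)
  to_long <- function(M, stage) {
    tibble(
      trait_a = rep(object$traits, times = k),
      trait_b = rep(object$traits, each = k),
      rg = as.vector(M), stage = stage
    )
  }
  d <- dplyr::bind_rows(to_long(object$rg_pre, "uncorrected"),
                        to_long(object$rg_post, "g-corrected"))
  d$stage <- factor(d$stage, levels = c("uncorrected", "g-corrected"))
  d$trait_a <- factor(d$trait_a, levels = object$traits)
  d$trait_b <- factor(d$trait_b, levels = rev(object$traits))
  ggplot2::ggplot(d, ggplot2::aes(.data$trait_a, .data$trait_b, fill = .data$rg)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~stage) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1), name = "rg") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-test genetic correlation profiles, uncorrected vs corrected
#'
#' One panel per test showing its genetic correlation with each of the other
#' tests before (orange) and after (blue) g-correction.
#'
#' @param comparison A `landscape_comparison`.
#' @return A ggplot.
#' @export
plot_profiles <- function(comparison) {
  d <- comparison$profiles
  d$stage <- factor(ifelse(d$stage == "pre", "uncorrected", "g-corrected"),
                    levels = c("uncorrected", "g-corrected"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rg, y = .data$other, colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~test) +
    ggplot2::scale_colour_manual(values = c(uncorrected = "#e08214", `g-corrected` = "#4575b4"),
                                 name = NULL) +
    ggplot2::labs(x = "genetic correlation", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
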