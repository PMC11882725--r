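# End-to-end orchestration: file-based stages (simulate -> munge -> ldsc ->
# fit-g -> correct -> landscape) driven by a single configuration list, so a
# full run is reproducible from (config, seed) alone. Outputs are delimited
# text plus JSON; re-running with the same config and seed reproduces them
# byte-for-byte.

#' Default pipeline configuration
#'
#' A plain named list, round-trippable through YAML with
#' [read_config()]/[write_config()]. `truth` holds the simulator parameters
#' (see [truth_set()]); `qc` the munging thresholds (see [qc_filter()]).
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Integer seed recorded in every manifest.
#' @return A named list.
#' @export
default_config <- function(out_dir = file.path(tempdir(), "genomicg_run"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    truth = list(k = 12, m = 20000, block_size = 10, rho = 0.5),
    qc = list(maf_min = 0.01, info_min = 0.9, chi2_max = 80, drop_ambiguous = TRUE),
    min_overlap = 5000,
    n_blocks = NULL,
    estimator = "DWLS",
    snp_mode = "fixed"
  )
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @rdname default_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(config) {
  allowed <- names(default_config())
  extra <- setdiff(names(config), allowed)
  if (length(extra) > 0) {
    abort(sprintf("invalid config key(s): %s", paste(extra, collapse = ", ")))
  }
  required <- c("out_dir", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort(sprintf("config is missing: %s", paste(missing, collapse = ", ")))
  }
  invisible(config)
}

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

need_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(sprintf("missing artifact %s: run the `%s` stage first", path, produced_by))
  }
  path
}

write_manifest <- function(dir, config, extra = list()) {
  jsonlite::write_json(
    c(list(seed = config$seed, config_hash = rlang::hash(config)), extra),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Stages: `simulate` draws a truth-known panel and writes per-trait
#' sumstats, LD scores, and the truth; `munge` reads, QC-filters and
#' harmonizes the sumstats into a panel; `ldsc` estimates S, V, and the
#' genetic correlation matrix; `fit-g` fits the one-factor model; `correct`
#' writes g-corrected sumstats for every trait; `landscape` estimates the
#' post-correction correlation matrix and the pre/post comparison; `all`
#' chains them. Later stages find earlier artifacts under `config$out_dir`
#' and fail with a dependency message if they are absent.
#'
#' @param name One of `"simulate"`, `"munge"`, `"ldsc"`, `"fit-g"`,
#'   `"correct"`, `"landscape"`, `"all"`.
#' @param config A configuration list (see [default_config()]).
#' @return The stage's main in-memory result, invisibly (the panel, the
#'   `genetic_covariance`, the `factor_solution`, the corrected list, or the
#'   `landscape_comparison`).
#' @export
run_stage <- function(name, config = default_config()) {
  name <- match.arg(name, c("simulate", "munge", "ldsc", "fit-g", "correct",
                            "landscape", "all"))
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (name == "all") {
    for (stage in c("simulate", "munge", "ldsc", "fit-g", "correct", "landscape")) {
      res <- run_stage(stage, config)
    }
    return(invisible(res))
  }

  t0 <- Sys.time()
  res <- switch(name,
    "simulate" = stage_simulate(config),
    "munge" = stage_munge(config),
    "ldsc" = stage_ldsc(config),
    "fit-g" = stage_fit_g(config),
    "correct" = stage_correct(config),
    "landscape" = stage_landscape(config)
  )
  inform(sprintf("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs")))
  invisible(res)
}

stage_simulate <- function(config) {
  dir <- stage_dir(config, "sim")
  truth <- do.call(truth_set, config$truth %||% list())
  panel <- simulate_panel(truth, seed = config$seed, dir = dir)
  write_manifest(dir, config, list(stage = "simulate", traits = truth$traits))
  panel
}

stage_munge <- function(config) {
  sim <- stage_dir(config, "sim")
  files <- sort(list.files(sim, pattern = "\\.sumstats\\.tsv$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no sumstats under %s: run the `simulate` stage first (or point out_dir at existing inputs)", sim))
  ld <- read_ld_scores(need_artifact(file.path(sim, "ldscores.tsv"), "simulate"))
  qc <- config$qc %||% list()
  tables <- purrr::map(files, function(f) {
    rec <- read_sumstats(f)
    do.call(qc_filter, c(list(rec), qc))
  })
  names(tables) <- sub("\\.sumstats\\.tsv$", "", basename(files))
  panel <- harmonize(tables, ld, min_overlap = config$min_overlap %||% 5000)
  dir <- stage_dir(config, "panel")
  write_panel_files(panel, dir)
  write_manifest(dir, config, list(
    stage = "munge", traits = panel$traits, variants = nrow(panel$variants),
    qc = purrr::map(tables, ~ as.list(attr(.x, "qc_report")))))
  panel
}

read_stage_panel <- function(config) {
  dir <- stage_dir(config, "panel")
  files <- sort(list.files(dir, pattern = "\\.sumstats\\.tsv$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no harmonized panel under %s: run the `munge` stage first", dir))
  ld <- read_ld_scores(file.path(dir, "ldscores.tsv"))
  tables <- purrr::map(files, read_sumstats)
  names(tables) <- sub("\\.sumstats\\.tsv$", "", basename(files))
  harmonize(tables, ld, min_overlap = config$min_overlap %||% 5000)
}

stage_ldsc <- function(config) {
  panel <- read_stage_panel(config)
  gcov <- ldsc_covariance(panel, n_blocks = config$n_blocks)
  rg <- rg_matrix(gcov)
  dir <- stage_dir(config, "ldsc")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(gcov$S, file.path(dir, "S.tsv"))
  write_matrix_tsv(gcov$V, file.path(dir, "V.tsv"), rownames_col = FALSE)
  write_matrix_tsv(rg$rg, file.path(dir, "rg.tsv"))
  write_matrix_tsv(rg$se, file.path(dir, "rg_se.tsv"))
  jsonlite::write_json(
    list(traits = gcov$traits, n_blocks = gcov$n_blocks,
         m_variants = gcov$m_variants, n = as.list(gcov$n), M = gcov$M,
         h2 = as.list(setNames(diag(gcov$S), gcov$traits)),
         smoothing = gcov$smoothing),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(dir, config, list(stage = "ldsc"))
  gcov
}

stage_fit_g <- function(config) {
  dir_in <- stage_dir(config, "ldsc")
  S <- read_matrix_tsv(need_artifact(file.path(dir_in, "S.tsv"), "ldsc"))
  V <- read_matrix_tsv(file.path(dir_in, "V.tsv"), rownames_col = FALSE)
  fit <- fit_common_factor(list(S = S, V = V, traits = colnames(S)),
                           estimator = config$estimator %||% "DWLS")
  dir <- stage_dir(config, "fit_g")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(traits = fit$traits,
         loadings = fit$loadings, loadings_se = fit$loadings_se,
         resid = fit$resid, resid_se = fit$resid_se,
         variance_share = fit$variance_share,
         loadings_cov = fit$loadings_cov, u_cov = fit$u_cov,
         vcov = fit$vcov, S_obs = fit$S_obs, w_S = fit$w_S,
         fit = fit$fit, estimator = fit$estimator),
    file.path(dir, "solution.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(tidy(fit), file.path(dir, "loadings.tsv"), progress = FALSE)
  write_manifest(dir, config, list(stage = "fit-g"))
  fit
}

read_stage_solution <- function(config) {
  path <- need_artifact(file.path(stage_dir(config, "fit_g"), "solution.json"), "fit-g")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(x$traits)
  structure(list(
    traits = x$traits,
    loadings = setNames(x$loadings, x$traits),
    loadings_se = setNames(x$loadings_se, x$traits),
    resid = setNames(x$resid, x$traits),
    resid_se = setNames(x$resid_se, x$traits),
    variance_share = setNames(x$variance_share, x$traits),
    loadings_cov = setNames(x$loadings_cov, x$traits),
    u_cov = setNames(x$u_cov, x$traits),
    vcov = matrix(unlist(x$vcov), 2 * k, 2 * k),
    S_obs = matrix(unlist(x$S_obs), k, k, dimnames = list(x$traits, x$traits)),
    w_S = x$w_S,
    fit = x$fit, estimator = x$estimator,
    heywood = setNames(x$resid < 0, x$traits),
    convergence = list(converged = TRUE)
  ), class = "factor_solution")
}

stage_correct <- function(config) {
  panel <- read_stage_panel(config)
  solution <- read_stage_solution(config)
  dir <- stage_dir(config, "corrected")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corrected <- correct_all_traits(panel, solution,
                                  mode = config$snp_mode %||% "fixed", dir = dir)
  write_manifest(dir, config, list(stage = "correct"))
  corrected
}

stage_landscape <- function(config) {
  panel <- read_stage_panel(config)
  solution <- read_stage_solution(config)
  dir_corr <- stage_dir(config, "corrected")
  files <- sort(list.files(dir_corr, pattern = "\\.gcorrected\\.tsv$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no corrected sumstats under %s: run the `correct` stage first", dir_corr))
  corrected <- purrr::map(files, function(f) {
    cs <- read_sumstats(f, corrected_column_map())
    attr(cs, "n_eff") <- stats::median(cs$n, na.rm = TRUE)
    cs
  })
  names(corrected) <- sub("\\.gcorrected\\.tsv$", "", basename(files))

  rg_pre <- rg_matrix(ldsc_covariance(panel, n_blocks = config$n_blocks))
  post_panel <- panel_from_corrected(corrected, panel)
  rg_post <- rg_matrix(ldsc_covariance(post_panel, n_blocks = config$n_blocks))
  cmp <- compare_landscapes(rg_pre, rg_post)
  ldt <- loading_delta_test(solution, cmp)

  dir <- stage_dir(config, "landscape")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cmp$rg_pre, file.path(dir, "rg_pre.tsv"))
  write_matrix_tsv(cmp$rg_post, file.path(dir, "rg_post.tsv"))
  write_matrix_tsv(cmp$delta, file.path(dir, "rg_delta.tsv"))
  readr::write_tsv(cmp$pairs, file.path(dir, "pairs.tsv"), progress = FALSE)
  jsonlite::write_json(
    c(as.list(glance(cmp)), list(loading_delta_correlation = ldt$estimate)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(dir, config, list(stage = "landscape"))
  cmp
}

write_matrix_tsv <- function(M, path, rownames_col = TRUE) {
  d <- as.data.frame(M)
  if (is.null(colnames(M))) names(d) <- paste0("c", seq_len(ncol(M)))
  if (rownames_col && !is.null(rownames(M))) d <- cbind(trait = rownames(M), d)
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path, rownames_col = TRUE) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (rownames_col && names(d)[1] == "trait") {
    rn <- d$trait
    M <- as.matrix(d[, -1])
    rownames(M) <- rn
  } else {
    M <- as.matrix(d)
    dimnames(M) <- NULL
  }
  M
}
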