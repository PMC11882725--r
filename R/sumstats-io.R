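#' Read GWAS summary statistics from a delimited text file
#'
#' Parses a whitespace- or tab-delimited summary-statistics file into a tidy
#' table of per-variant records. Column names in the file are mapped to
#' canonical fields through `column_map`; the default map understands the
#' common `SNP A1 A2 Z N` dialect and its `BETA`/`SE` variant. When the
#' association statistic is supplied as an effect size plus standard error,
#' the Z-score is computed as `beta / se`.
#'
#' Malformed rows (non-ACGT alleles, identical alleles, non-finite statistic,
#' non-positive sample size) are rejected, counted per reason, and reported
#' via a message; the counts are attached as the `"rejections"` attribute.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical field names
#'   (`variant`, `chrom`, `pos`, `a1`, `a2`, `z`, `beta`, `se`, `n`, `freq`,
#'   `info`) to column names in the file. Only the columns present in the
#'   file are used; either `z` or both `beta` and `se` must resolve.
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `z`, `n`, `freq`, `info` (missing optional fields are `NA`), with the
#'   per-reason rejection counts in `attr(, "rejections")`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("SNP CHR BP A1 A2 Z N", "rs1 1 100 A G 2.0 10000"), f)
#' read_sumstats(f)
read_sumstats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) abort(sprintf("sumstats file not found: %s", path))
  raw <- readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  cm <- column_map[column_map %in% names(raw)]

  need <- c("variant", "a1", "a2")
  missing_req <- setdiff(need, names(cm))
  if (length(missing_req) > 0) {
    abort(sprintf("required column(s) not found: %s (mapped names: %s)",
                  paste(missing_req, collapse = ", "),
                  paste(column_map[missing_req], collapse = ", ")))
  }
  has_z <- "z" %in% names(cm)
  has_beta <- all(c("beta", "se") %in% names(cm))
  if (!has_z && !has_beta) {
    abort("no association statistic: need a `z` column or both `beta` and `se`")
  }
  if (!"n" %in% names(cm)) abort(sprintf("required column not found: n (mapped name: %s)", column_map[["n"]]))

  num <- function(field) {
    if (field %in% names(cm)) suppressWarnings(as.numeric(raw[[cm[[field]]]])) else rep(NA_real_, nrow(raw))
  }
  chr_col <- function(field) {
    if (field %in% names(cm)) as.character(raw[[cm[[field]]]]) else rep(NA_character_, nrow(raw))
  }

  z <- if (has_z) num("z") else num("beta") / num("se")
  out <- tibble(
    variant_id = chr_col("variant"),
    chrom = chr_col("chrom"),
    pos = num("pos"),
    a1 = toupper(chr_col("a1")),
    a2 = toupper(chr_col("a2")),
    z = z,
    n = num("n"),
    freq = num("freq"),
    info = num("info")
  )

  bad_allele <- !(out$a1 %in% c("A", "C", "G", "T")) | !(out$a2 %in% c("A", "C", "G", "T"))
  same_allele <- !bad_allele & out$a1 == out$a2
  bad_z <- !is.finite(out$z)
  bad_n <- !is.finite(out$n) | out$n <= 0
  rejections <- c(
    non_acgt_allele = sum(bad_allele),
    identical_alleles = sum(same_allele),
    nonfinite_statistic = sum(bad_z & !bad_allele & !same_allele),
    invalid_n = sum(bad_n & !bad_z & !bad_allele & !same_allele)
  )
  keep <- !(bad_allele | same_allele | bad_z | bad_n)
  if (any(!keep)) {
    inform(sprintf("read_sumstats: rejected %d of %d rows (%s)",
                   sum(!keep), nrow(out),
                   paste(sprintf("%s=%d", names(rejections), rejections), collapse = ", ")))
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

#' @rdname read_sumstats
#' @export
default_column_map <- function() {
  c(variant = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
    z = "Z", beta = "BETA", se = "SE", n = "N", freq = "FREQ", info = "INFO")
}

#' Quality-filter summary-statistic records
#'
#' Applies the standard pre-LDSC filters: minor-allele-frequency bounds,
#' imputation-quality floor, a chi-square ceiling that removes variants with
#' implausibly large associations, and removal of strand-ambiguous (A/T, C/G)
#' variants. Records with a missing `freq` or `info` pass the corresponding
#' filter. Per-filter removal counts are attached as the `"qc_report"`
#' attribute; counts always sum to rows-in minus rows-out.
#'
#' @param records A record table from [read_sumstats()].
#' @param maf_min Minimum effect-allele frequency; variants outside
#'   `[maf_min, 1 - maf_min]` are removed. Default 0.01.
#' @param info_min Minimum imputation quality. Default 0.9.
#' @param chi2_max Maximum allowed `z^2`. Default 80.
#' @param drop_ambiguous Remove strand-ambiguous variants. Default `TRUE`.
#' @return The filtered tibble with a named-count `"qc_report"` attribute.
#' @export
qc_filter <- function(records, maf_min = 0.01, info_min = 0.9, chi2_max = 80,
                      drop_ambiguous = TRUE) {
  ambiguous <- drop_ambiguous & (
    (records$a1 == "A" & records$a2 == "T") | (records$a1 == "T" & records$a2 == "A") |
    (records$a1 == "C" & records$a2 == "G") | (records$a1 == "G" & records$a2 == "C"))
  low_maf <- !is.na(records$freq) & (records$freq < maf_min | records$freq > 1 - maf_min)
  low_info <- !is.na(records$info) & records$info < info_min
  big_chi2 <- records$z^2 > chi2_max

  report <- c(
    strand_ambiguous = sum(ambiguous),
    maf = sum(low_maf & !ambiguous),
    info = sum(low_info & !ambiguous & !low_maf),
    chi2 = sum(big_chi2 & !ambiguous & !low_maf & !low_info)
  )
  out <- records[!(ambiguous | low_maf | low_info | big_chi2), , drop = FALSE]
  if (nrow(out) == 0) abort("no variants survive QC")
  attr(out, "qc_report") <- report
  attr(out, "rejections") <- attr(records, "rejections")
  out
}

#' Construct an LD-score table
#'
#' @param scores A tibble with columns `variant_id` and `l2` (the LD score).
#' @param M Reference-panel SNP count used as the heritability denominator.
#' @return A tibble of class `ld_score_table` with `M` stored as an attribute.
#'   LD scores are floored at 1 (a variant is always in perfect LD with
#'   itself).
#' @export
ld_score_table <- function(scores, M) {
  stopifnot(all(c("variant_id", "l2") %in% names(scores)))
  if (M < nrow(scores)) abort("M must be at least the number of scored variants")
  out <- tibble(variant_id = as.character(scores$variant_id), l2 = pmax(scores$l2, 1))
  attr(out, "M") <- M
  class(out) <- c("ld_score_table", class(out))
  out
}

#' Read / write LD scores in the two-column `SNP L2` dialect
#'
#' The variant count `M` travels in a sidecar file `<path>.M` holding a
#' single number, mirroring the `.l2.M` convention.
#'
#' @param path File path.
#' @return For the reader, an [ld_score_table()].
#' @export
read_ld_scores <- function(path) {
  tbl <- readr::read_table(path, col_types = readr::cols(SNP = readr::col_character(),
                                                          L2 = readr::col_double()),
                           progress = FALSE)
  m_path <- paste0(path, ".M")
  if (!file.exists(m_path)) abort(sprintf("sidecar SNP count not found: %s", m_path))
  M <- as.numeric(readLines(m_path, warn = FALSE)[1])
  ld_score_table(tibble(variant_id = tbl$SNP, l2 = tbl$L2), M = M)
}

#' @rdname read_ld_scores
#' @param ld An [ld_score_table()].
#' @export
write_ld_scores <- function(ld, path) {
  readr::write_tsv(tibble(SNP = ld$variant_id, L2 = ld$l2), path, progress = FALSE)
  writeLines(format(attr(ld, "M"), scientific = FALSE), paste0(path, ".M"))
  invisible(path)
}

#' Harmonize per-trait summary statistics into a multi-trait panel
#'
#' Restricts all traits to a shared variant set (intersection by default),
#' chooses one reference allele orientation per variant (the first trait's),
#' and flips the sign of any trait whose effect/other alleles are swapped
#' relative to the reference so that every Z-score refers to the same effect
#' allele. Variants whose allele pairs cannot be reconciled are dropped and
#' counted. The panel is restricted to variants present in the LD-score
#' table. Matching is by variant ID only, following LDSC convention;
#' positions are carried through but never used.
#'
#' @param tables Named list (length >= 2) of QC-passed record tables, one per
#'   trait, in the `read_sumstats()` layout.
#' @param ld An [ld_score_table()].
#' @param min_overlap Minimum number of shared variants required; fewer is
#'   fatal. Default 5000.
#' @param n_fallback Optional named vector of per-trait sample sizes used
#'   when a trait has no usable `n` column; the substitution is logged.
#' @return A `sumstats_panel`: variant table, Z-score matrix (variants x
#'   traits), per-trait sample sizes, LD scores, and a harmonization log.
#' @export
harmonize <- function(tables, ld, min_overlap = 5000, n_fallback = NULL) {
  if (length(tables) < 2) abort("harmonize needs at least 2 traits")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a named list of per-trait record tables")
  }
  traits <- names(tables)
  k <- length(traits)

  shared <- Reduce(intersect, lapply(tables, function(t) t$variant_id))
  shared <- shared[shared %in% ld$variant_id]
  # keep the first trait's ordering
  ref <- tables[[1]][match(shared, tables[[1]]$variant_id), , drop = FALSE]

  m <- length(shared)
  Z <- matrix(NA_real_, m, k, dimnames = list(NULL, traits))
  n_per_trait <- setNames(numeric(k), traits)
  dropped_irreconcilable <- 0L
  keep <- rep(TRUE, m)
  log <- list()

  for (t in seq_len(k)) {
    tab <- tables[[t]][match(shared, tables[[t]]$variant_id), , drop = FALSE]
    same <- tab$a1 == ref$a1 & tab$a2 == ref$a2
    swap <- tab$a1 == ref$a2 & tab$a2 == ref$a1
    bad <- !(same | swap)
    keep <- keep & !bad
    dropped_irreconcilable <- dropped_irreconcilable + sum(bad)
    z <- tab$z
    z[swap] <- -z[swap]
    Z[, t] <- z
    n_col <- tab$n
    if (all(!is.finite(n_col)) || all(is.na(n_col))) {
      if (is.null(n_fallback) || is.na(n_fallback[traits[t]])) {
        abort(sprintf("trait %s has no sample sizes and no `n_fallback` entry", traits[t]))
      }
      n_per_trait[t] <- n_fallback[[traits[t]]]
      log[[length(log) + 1]] <- sprintf("trait %s: substituted per-trait n = %g from config", traits[t], n_per_trait[t])
    } else {
      n_per_trait[t] <- stats::median(n_col, na.rm = TRUE)
    }
  }

  variants <- tibble(
    variant_id = ref$variant_id,
    chrom = ref$chrom, pos = ref$pos,
    a1 = ref$a1, a2 = ref$a2, freq = ref$freq
  )[keep, , drop = FALSE]
  Z <- Z[keep, , drop = FALSE]

  if (nrow(variants) < min_overlap) {
    abort(sprintf("only %d overlapping variants (< min_overlap = %d)", nrow(variants), min_overlap))
  }

  l2 <- ld$l2[match(variants$variant_id, ld$variant_id)]

  structure(list(
    traits = traits,
    variants = variants,
    Z = Z,
    n = n_per_trait,
    ld = pmax(l2, 1),
    M = attr(ld, "M"),
    log = c(log, sprintf("dropped %d variant-trait pairs with irreconcilable alleles", dropped_irreconcilable))
  ), class = "sumstats_panel")
}

#' @export
print.sumstats_panel <- function(x, ...) {
  cat(sprintf("<sumstats_panel> %d traits x %d variants (M = %g)\n",
              length(x$traits), nrow(x$variants), x$M))
  cat("traits:", paste(x$traits, collapse = ", "), "\n")
  cat("per-trait n:", paste(format(x$n, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one trait's records from a panel
#'
#' Inverse of [harmonize()] for a single trait: a tidy record table in the
#' [read_sumstats()] layout, with Z-scores on the panel's reference allele
#' orientation.
#'
#' @param panel A `sumstats_panel`.
#' @param trait Trait label.
#' @return A tibble of records.
#' @export
panel_records <- function(panel, trait) {
  stopifnot(trait %in% panel$traits)
  dplyr::mutate(panel$variants,
                z = panel$Z[, trait],
                n = panel$n[[trait]],
                info = NA_real_,
                .after = "a2")
}

#' Write corrected (or plain) summary statistics to disk
#'
#' Emits the tab-delimited `SNP CHR BP A1 A2 BETA SE Z N_eff` layout, which
#' round-trips through [read_sumstats()]. An empty result set produces a
#' header-only file with a warning.
#'
#' @param x A `corrected_sumstats` object from [correct_trait()], or any
#'   tibble with columns `variant_id`, `chrom`, `pos`, `a1`, `a2`, `beta`,
#'   `se`, `z` and either an `n_eff` column or attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corrected_sumstats <- function(x, path) {
  n_eff <- x$n_eff %||% attr(x, "n_eff")
  tbl <- tibble(
    SNP = x$variant_id, CHR = x$chrom, BP = x$pos,
    A1 = x$a1, A2 = x$a2,
    BETA = x$beta, SE = x$se, Z = x$z,
    N_eff = if (length(n_eff) %in% c(1L, nrow(x))) n_eff else NA_real_
  )
  if (nrow(tbl) == 0) warn(sprintf("writing header-only sumstats file: %s", path))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_corrected_sumstats
#' @export
corrected_column_map <- function() {
  c(variant = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
    beta = "BETA", se = "SE", z = "Z", n = "N_eff")
}
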