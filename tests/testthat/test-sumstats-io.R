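test_that("read_sumstats parses the common dialects and rejects malformed rows", {
  f <- withr::local_tempfile()
  writeLines(c("SNP CHR BP A1 A2 Z N",
               "rs1 1 100 A G 2.0 10000",
               "rs2 1 200 C T -1.5 10000",
               "rs3 1 300 I D 1.0 10000"), f)
  rec <- suppressMessages(read_sumstats(f))
  expect_equal(nrow(rec), 2)
  expect_equal(rec$z[rec$variant_id == "rs1"], 2.0)
  expect_equal(rec$n[1], 10000)
  expect_equal(unname(attr(rec, "rejections")[["non_acgt_allele"]]), 1)

  # beta + se resolves to z = beta / se
  f2 <- withr::local_tempfile()
  writeLines(c("SNP A1 A2 BETA SE N",
               "rs1 A G 0.02 0.01 5000"), f2)
  rec2 <- read_sumstats(f2)
  expect_equal(rec2$z, 2.0)

  # missing required column is fatal and names the column
  f3 <- withr::local_tempfile()
  writeLines(c("SNP A1 A2 Z", "rs1 A G 1.0"), f3)
  expect_error(read_sumstats(f3), "n")
  f4 <- withr::local_tempfile()
  writeLines(c("SNP A1 Z N", "rs1 A 1.0 100"), f4)
  expect_error(read_sumstats(f4), "a2")
})

test_that("qc_filter applies each rule and its counts reconcile", {
  rec <- tibble::tibble(
    variant_id = paste0("rs", 1:6), chrom = "1", pos = 1:6 * 100,
    a1 = c("A", "A", "C", "A", "A", "G"),
    a2 = c("T", "G", "G", "G", "G", "A"),
    z = c(1, 1, 1, 1, 10, 1),
    n = 1e4, freq = c(0.3, 0.005, 0.3, 0.3, 0.3, NA), info = c(1, 1, 1, 0.5, 1, NA)
  )
  out <- qc_filter(rec, maf_min = 0.01, info_min = 0.9, chi2_max = 80)
  rep <- attr(out, "qc_report")
  expect_equal(unname(rep[["strand_ambiguous"]]), 2)  # A/T and C/G
  expect_equal(unname(rep[["maf"]]), 1)               # freq 0.005
  expect_equal(unname(rep[["info"]]), 1)              # info 0.5
  expect_equal(unname(rep[["chi2"]]), 1)              # z = 10 -> 100 > 80
  expect_equal(sum(rep), nrow(rec) - nrow(out))
  expect_equal(out$variant_id, "rs6")                 # missing freq/info passes

  expect_error(qc_filter(dplyr::mutate(rec, z = 100)), "no variants survive")
})

test_that("harmonize orients alleles to one reference and flips swapped traits", {
  base <- tibble::tibble(
    variant_id = paste0("rs", 1:6), chrom = "1", pos = 1:6 * 100,
    a1 = "A", a2 = "G", z = c(2, -1, 0.5, 1, -2, 3), n = 1e4,
    freq = 0.3, info = NA_real_
  )
  swapped <- dplyr::mutate(base, a1 = "G", a2 = "A", z = z + 1)
  irrec <- base
  irrec$a1[3] <- "C"; irrec$a2[3] <- "T"
  ld <- ld_score_table(tibble::tibble(variant_id = base$variant_id, l2 = 2), M = 10)

  panel <- harmonize(list(x = base, y = swapped, w = irrec), ld, min_overlap = 2)
  # swapped trait: z negated onto the reference orientation
  expect_equal(panel$Z[, "y"], -(base$z[base$variant_id %in% panel$variants$variant_id] + 1))
  # irreconcilable variant dropped
  expect_false("rs3" %in% panel$variants$variant_id)
  expect_equal(nrow(panel$variants), 5)

  # variant present in one trait only is dropped (intersection)
  short <- base[-1, ]
  p2 <- harmonize(list(x = base, y = short), ld, min_overlap = 2)
  expect_false("rs1" %in% p2$variants$variant_id)

  expect_error(harmonize(list(x = base, y = base), ld, min_overlap = 100),
               "min_overlap")
})

test_that("harmonize is idempotent and invariant to an allele flip of one trait", {
  p0 <- small_panel(k = 3, m = 500, seed = 4)
  tables <- purrr::map(stats::setNames(p0$traits, p0$traits),
                       function(t) panel_records(p0, t))
  ld <- ld_score_table(tibble::tibble(variant_id = p0$variants$variant_id,
                                      l2 = p0$ld), M = p0$M)
  h1 <- harmonize(tables, ld, min_overlap = 100)
  h2 <- harmonize(purrr::map(stats::setNames(h1$traits, h1$traits),
                             function(t) panel_records(h1, t)),
                  ld, min_overlap = 100)
  expect_equal(h2$Z, h1$Z)
  expect_equal(h2$variants, h1$variants)

  flipped <- tables
  flipped[[2]] <- dplyr::mutate(flipped[[2]], z = -z, freq = 1 - freq,
                                a1 = tables[[2]]$a2, a2 = tables[[2]]$a1)
  h3 <- harmonize(flipped, ld, min_overlap = 100)
  expect_equal(h3$Z, h1$Z)
})

test_that("corrected sumstats round-trip through disk within 1e-6", {
  cs <- tibble::tibble(
    variant_id = paste0("rs", 1:5), chrom = "2", pos = 1:5 * 10,
    a1 = "A", a2 = "C", freq = 0.25,
    beta = c(0.01, -0.02, 0, 0.005, 0.03), se = 0.005
  )
  cs$z <- cs$beta / cs$se
  cs$n_eff <- 4000
  f <- withr::local_tempfile()
  write_corrected_sumstats(cs, f)
  back <- read_sumstats(f, corrected_column_map())
  expect_equal(back$z, cs$z, tolerance = 1e-6)
  expect_equal(back$z[1], 2.0)
  expect_equal(back$n[1], 4000)

  # empty result set: header-only file plus a warning
  f2 <- withr::local_tempfile()
  expect_warning(write_corrected_sumstats(cs[0, ], f2), "header-only")
  expect_equal(length(readLines(f2)), 1)
})

test_that("LD score tables floor at 1 and enforce M", {
  tbl <- tibble::tibble(variant_id = c("a", "b"), l2 = c(0.2, 5))
  ld <- ld_score_table(tbl, M = 100)
  expect_equal(ld$l2, c(1, 5))
  expect_error(ld_score_table(tbl, M = 1), "M must be")

  f <- withr::local_tempfile()
  write_ld_scores(ld, f)
  ld2 <- read_ld_scores(f)
  expect_equal(ld2$l2, ld$l2)
  expect_equal(attr(ld2, "M"), 100)
})
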