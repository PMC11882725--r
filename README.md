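# genomicg

Extracting a genomic general factor ("genomic *g*") from multi-trait GWAS
summary statistics, residualizing each trait's per-SNP effects for the
factor (GWAS-by-subtraction), and quantifying how the genetic correlation
landscape changes after the correction.

## Who this is for

Statistical geneticists working with panels of GWAS summary statistics —
typically cognitive test batteries — who want to separate the genetics each
trait shares with a general factor from the genetics specific to the trait,
without individual-level data. The package implements the full pipeline:

1. **Munging** — read, quality-filter, and allele-harmonize per-trait
   summary statistics and LD scores (`read_sumstats()`, `qc_filter()`,
   `harmonize()`).
2. **LD score regression** — SNP heritabilities and cross-trait genetic
   covariances; the genetic covariance matrix *S* with its joint
   block-jackknife sampling matrix *V* (`ldsc_h2()`, `ldsc_cross()`,
   `ldsc_covariance()`, `rg_matrix()`).
3. **Common factor model** — a one-factor model Σ(θ) = λλᵀ + diag(u) fitted
   to *S* by diagonally weighted least squares (W = diag(V)⁻¹) with
   sandwich standard errors, standardized loadings, and fit indices
   (`fit_common_factor()`, `variance_decomposition()`).
4. **g-correction** — per variant, paths from the SNP to *g* and to one
   trait's residual, solved with the measurement model fixed at its
   panel-level estimates; the residual path is the g-corrected association
   (`correct_trait()`, `correct_all_traits()`, `factor_gwas()`).
5. **Landscape comparison** — pre/post correlation matrices, delta
   statistics, sign flips, per-test profiles, the loading-difference test,
   and external-trait profiles (`compare_landscapes()`,
   `loading_delta_test()`, `external_profile()`).

A truth-known simulator (`truth_set()`, `simulate_panel()`,
`simulate_external_trait()`) generates multi-trait summary statistics under
a one-factor architecture with LD-block structure, so the whole pipeline is
validated by parameter recovery with no external downloads. See
`vignettes/methods.Rmd` for the model, estimators, and design choices.

## Worked example

```r
library(genomicg)

truth <- truth_set()                      # 12 traits, loadings 0.26-0.92
panel <- simulate_panel(truth, seed = 7)  # 20,000 variants, LD blocks

gcov <- ldsc_covariance(panel)            # S and V by LDSC + joint jackknife
fit  <- fit_common_factor(gcov)           # genomic g
fit
#> <factor_solution> one-factor model, 12 traits (DWLS)
#> # A tibble: 12 x 7
#>    trait  loading loading_se resid_var resid_se g_share heywood
#>    <chr>    <dbl>      <dbl>     <dbl>    <dbl>   <dbl> <lgl>
#>  1 test01   0.335     0.109      0.888    0.0731   0.112 FALSE
#>  2 test02   0.397     0.0706     0.842    0.0561   0.158 FALSE
#>  ...
#> 12 test12   0.953     0.0342     0.0921   0.0651   0.908 FALSE
#> chisq(54) = 88.883, CFI = 0.896, SRMR = 0.066; mean loading = 0.673, mean g share = 48.7%

corrected <- correct_all_traits(panel, fit)   # 12 g-corrected sumstats sets
post <- ldsc_covariance(panel_from_corrected(corrected, panel))
cmp <- compare_landscapes(rg_matrix(gcov), rg_matrix(post))
cmp
#> <landscape_comparison> 12 traits, 66 pairs
#> mean off-diagonal rg: 0.450 (pre) -> -0.077 (post); mean delta -0.527
#> sign flips: 48 raw, 19 beyond 1 SE both sides
```

The loadings recover the generative truth (0.26–0.92) within sampling
error; the mean off-diagonal genetic correlation collapses from strongly
positive to near zero once *g* is removed — the positive manifold is gone,
and what remains is each test's specific genetic signal.
`plot_loadings(fit)`, `autoplot(cmp)` and `plot_profiles(cmp)` draw the
loading table, the pre/post heat maps, and the per-test profiles;
`tidy()`/`glance()` return the results as tibbles.

An end-to-end file-based pipeline with YAML configuration is available via
`run_stage("all", config)` (stages: simulate, munge, ldsc, fit-g, correct,
landscape), with a thin command-line wrapper in `inst/cli/pipeline.R`.

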