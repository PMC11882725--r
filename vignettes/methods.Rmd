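---
title: "Removing a genomic general factor from multi-trait GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing a genomic general factor from multi-trait GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomicg)
```

# The problem

Cognitive tests are genetically correlated with one another across the
board — the "positive manifold". A single latent factor, genomic *g*,
captures this shared genetic covariance. The question this package
addresses: what does the genetic landscape of a battery of tests look like
once the contribution of *g* is removed from each test's GWAS summary
statistics, trait by trait? The pipeline estimates the genetic covariance
structure of a panel of summary statistics, extracts the common factor,
residualizes every trait's per-SNP effects for that factor
(GWAS-by-subtraction), and compares the genetic correlation matrices before
and after.

Because real cognitive-battery summary statistics require controlled-access
downloads, the package ships a truth-known simulator; every stage is
validated by parameter recovery against the generative truth.

# The model

## Measurement model

For $k$ traits the genetic correlation structure is modelled as

$$\Sigma(\theta) = \lambda \lambda^\top + \mathrm{diag}(u), \qquad
  \mathrm{Var}(g) = 1,$$

with standardized loadings $\lambda_t$ and residual genetic variances
$u_t$. The model is fitted to the LDSC-estimated genetic covariance matrix
$S$ (below) by diagonally weighted least squares,

$$\hat\theta = \arg\min_\theta
  \big(\mathrm{vech}(S) - \mathrm{vech}(\Sigma(\theta))\big)^\top W
  \big(\mathrm{vech}(S) - \mathrm{vech}(\Sigma(\theta))\big),
  \qquad W = \mathrm{diag}(V)^{-1},$$

where $V$ is the block-jackknife sampling covariance of
$\mathrm{vech}(S)$. Only the diagonal of $V$ enters the weights; the full
$V$ is used in the sandwich parameter covariance
$(\Delta^\top W \Delta)^{-1} \Delta^\top W V W \Delta
 (\Delta^\top W \Delta)^{-1}$
(with $\Delta$ the Jacobian at the optimum) and in the residual-based model
chi-square. This split is the standard arrangement for structural models on
summary-statistic covariance matrices. Identification is by unit latent
variance rather than by a marker loading, so no single test is privileged;
the factor is oriented so the mean loading is positive, matching the
convention that higher scores mean better performance.

The model is fitted on the covariance scale and standardized afterwards
($\lambda^{std}_t = \hat\lambda_t / \sqrt{\hat\lambda_t^2 + \hat u_t}$),
which guarantees $\lambda^2 + u = 1$ on the reported solution exactly;
standard errors follow by the delta method. Negative $\hat u_t$ (Heywood
cases) are reported and flagged by default; `heywood = "bound"` refits with
$u \ge 0$.

## LD score regression

SNP heritabilities and genetic covariances come from LD score regression:
for traits $a, b$ and variant $j$,

$$E[z_{aj} z_{bj}] = \delta_{ab} + \frac{\sqrt{n_a n_b}\,
  \mathrm{cov}_g(a,b)}{M} \ell_j + \text{(confounding / overlap)},$$

so the slope of $z_a z_b$ on the LD score $\ell_j$ scaled by
$M/\sqrt{n_a n_b}$ estimates the genetic covariance, and the intercept
absorbs sample overlap. Weights are the canonical two-step form
$1/(\ell_j (1 + s_a \ell_j)(1 + s_b \ell_j))$, where $s_t$ is the clamped
first-pass unweighted chi-square slope of trait $t$ (for $a = b$ this is
exactly $1/(\ell (1 + n h^2 \ell / M)^2)$); LD scores are floored at 1.
Standard errors use a delete-one-block jackknife over contiguous variant
blocks, 200 blocks by default, reduced to $\lfloor m/50 \rfloor$ for small
panels. $V$ is estimated *jointly*: every entry of $S$ uses the same block
partition and $V$ is the covariance of the jackknife pseudovalues across
all $k(k+1)/2$ entries, so cross-entry sampling dependence is captured.
The same block sums drive both the full fit and the deletions, so assembly
introduces no drift relative to standalone regressions, and a brute-force
per-block refit oracle reproduces $V$ to near machine precision (tested).

If the assembled $S$ has an eigenvalue below $-10^{-8}$ it is smoothed by
eigenvalue flooring at zero before the factor fit, with the largest element
change logged; negative heritability estimates are otherwise reported, not
truncated, except that genetic correlations involving a non-positive
diagonal are returned as undefined and flagged.

## Per-SNP residualization (GWAS-by-subtraction)

For target trait $a$, each variant gets two paths — to the factor and to
the target's residual. With the measurement model held at its panel-level
estimates, the $k$ covariance equations

$$\widehat{\mathrm{cov}}(\mathrm{SNP}_j, t) = z_{tj}/\sqrt{n_t}
  = \lambda^{cov}_t b_g + \mathbb{1}[t = a]\, b_{resid} + \varepsilon_t$$

are solved per variant by weighted least squares with weights $n_t$ (the
inverse sampling variances; cross-trait sampling covariance is zero under
the non-overlap assumption). Standard errors add, by the delta method, the
propagated uncertainty of the estimated loadings. This fixed-measurement
solve is the default because a full per-SNP re-fit multiplies an optimizer
over every variant; the full re-fit is retained as an audit mode
(`mode = "refit"`) and agrees with the fast solve to well under $10^{-3}$
when the measurement model is precisely determined (tested). The corrected
effect is reported per allele ($\beta = b/\sqrt{2p(1-p)}$) with
$Z = b/\mathrm{se}$, and the effective sample size is
$N_{eff} = \mathrm{mean}\big[(Z_j/\beta_j)^2 / (2 p_j (1-p_j))\big]$ over
variants with minor-allele frequency in (0.1, 0.4) — the common practice
for latent-factor GWAS outputs; the window is configurable and falls back
to the median over all variants when empty.

### A structural property worth knowing

The residual path's solve must be orthogonal to the *estimated* loading
vector while giving the target unit weight. That contrast spreads weight
$\approx -\lambda_a \lambda_t w_t / \sum_{t' \neq a} \lambda_{t'}^2 w_{t'}$
over the companion traits, so every corrected trait carries a small
admixture of the *other* traits' residual genetic effects. Two corrected
traits therefore share components with negative sign, which biases their
genetic correlation by roughly $-2/k + (k-2)/k^2$ (about $-0.1$ at
$k = 12$) even when the true residuals are independent. This is inherent to
per-SNP subtraction with an estimated factor — not an artifact of this
implementation — and it shrinks as $1/k$. It is consistent with the small
negative average correlation observed among g-corrected tests in empirical
work with twelve indicators. The package reports raw post-correction
correlations without attempting to debias them, since that is what the
procedure under study produces; the simulation suite quantifies the effect.

## Landscape comparison

`compare_landscapes()` reports pre/post correlation matrices, the delta
matrix, unweighted means over the $k(k-1)/2$ unique pairs (precision
weighting of pairs is deliberately not applied; pairs undefined on either
side are excluded with a count), per-test profiles, and sign flips. A
"sign flip" is counted in the headline figure only when both the pre and
post estimates exceed one jackknife SE in magnitude, so noise crossings
near zero are not counted; the raw count is reported alongside.

`loading_delta_test()` correlates, over unordered pairs, the absolute
loading difference $|\lambda_a - \lambda_b|$ with the pair's correlation
change. Pairs are unordered, so only the absolute difference is well
defined. When all loadings are numerically equal the correlation does not
exist and the result is flagged degenerate rather than returned as a
number.

One caveat, quantified by the validation suite: because the loadings and
the correlation matrices are estimated from the same panel, their sampling
errors are coupled — a noisy-high $\hat r_{ab}$ pulls $\hat\lambda_a$ and
$\hat\lambda_b$ together *and* makes the pair's delta more negative, which
biases the statistic upward when the per-entry precision is low. The
statistic is therefore only a clean null diagnostic when the underlying
correlations are estimated precisely (large effective sample sizes); the
suite's null experiment runs at $n = 100{,}000$, the upper end of the
emulated cohort sizes, for exactly this reason.

# The simulator

`truth_set()` + `simulate_panel()` generate the study conditions: factor
effects $\alpha_j \sim N(0, 1/m)$, specific effects
$\delta_{tj} \sim N(0, 1/m)$ (optionally correlated across traits through
`resid_cor`), standardized causal effects
$\beta_{tj} = \sqrt{h^2_t}(\lambda_t \alpha_j + \sqrt{u_t}\,\delta_{tj})$,
marginal effects by within-block LD convolution $R\beta$, and observed
$z_{tj} = \sqrt{n_t}(R\beta_t)_j + \varepsilon_{tj}$ with
$\varepsilon \sim N(0, R)$ within blocks and independent across traits
(non-overlapping samples, so cross-trait LDSC intercepts are null).

Defaults describe a 12-test battery: loadings 0.26–0.92 (mean 0.66; mean
squared loading 0.465, i.e. the factor carries just under half the genetic
variance), SNP heritabilities 0.10–0.25 (mean 0.16), sample sizes 15,000 to
35,000, and $m = 20{,}000$ variants in exchangeable blocks of 10.

LD is exchangeable within blocks so that LD scores have the closed form
$\ell_j = 1 + (b-1)\rho_b^2$ and the marginal-effect convolution is exact.
One design point matters: if every block shares a single $\rho$, all LD
scores are equal and the LDSC regression loses its regressor (slope and
intercept are collinear). The default therefore spreads $\rho_b$ evenly
over 0.2–0.8 across blocks, giving the regression an informative spread of
LD scores while keeping every closed form intact. Allele frequencies are
drawn Uniform(0.05, 0.5) and enter only the effective-sample-size
computation; effects live on the standardized-genotype scale.

What the simulator does *not* emulate: realistic human LD maps (block
structure is exchangeable and non-overlapping), per-SNP sample-size
variation, binary traits on the liability scale, ancestry structure, or
sample overlap between cohorts (an intercept, not modelled by default).
Passing recovery tests here therefore demonstrates correctness of the
estimators under the stated generative model, not robustness to every
feature of real data.

`simulate_external_trait()` reuses the panel's causal draws so an external
trait's genetic correlation with the factor (`g_corr`) and with named
specific components (`specific_corr`) is exact by construction; the
remainder goes to an independent component, and
$g_{corr}^2 + \sum c_t^2 \le 1$ is enforced.

# Numerical choices

* DWLS optimizer: BFGS with analytic gradient, relative tolerance
  $10^{-14}$, started from loadings $=\sqrt{\bar r}$ (the mean off-diagonal
  standardized covariance) on the covariance scale; up to three
  deterministically jittered restarts on non-convergence, then failure with
  the optimizer trace.
* $V$ (and $\Delta^\top W \Delta$) are inverted by symmetric
  pseudo-inverse with relative eigenvalue tolerance $10^{-10}$, so a
  jackknife-rank-deficient $V$ degrades gracefully.
* Model chi-square is the residual-based quadratic form evaluated against
  the full $V$ with the projection onto the model tangent space removed;
  df $= k(k+1)/2 - 2k$. CFI is computed against the independence model
  (free variances only), SRMR on standardized residuals including the
  diagonal.
* PSD smoothing triggers only below $-10^{-8}$; the jackknife delete-one
  estimates feeding correlation SEs use the raw (unsmoothed) entries.
* Jackknife blocks are contiguous and near-equal; with the default sizes
  each jackknife block spans whole LD blocks, so deletions respect the
  dependence structure.
* All simulation is seeded explicitly; a panel is bit-reproducible from
  (truth, seed), and the file-based pipeline is byte-reproducible from
  (config, seed).

# Problem sizes used in the test suite

Unit tests run on panels of 500–10,000 variants. The validation suite uses
the defaults above: 50 replicates per heritability level for bias and SE
calibration; 20 replicates for loading recovery and 100 for CI coverage;
20 replicates each for the subtraction, sign-flip-mechanism, and
loading-difference experiments; a 5,000-variant panel for the brute-force
oracle comparisons. These sizes give Monte-Carlo error comfortably inside
the asserted tolerances while keeping a full run on one CPU in minutes.

# Known limitations

* Variant matching is by ID only (LDSC convention); no liftover or
  positional reconciliation, and no INDEL support.
* Per-trait sample size is a scalar (the median of the per-SNP column);
  per-SNP $n$ is parsed but not propagated into the regressions.
* The structural $O(1/k)$ negative bias among corrected traits described
  above is reported, not removed.
* Partitioned heritability, liability-scale conversion, covariate-adjusted
  LD scores, and multi-ancestry panels are out of scope.
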