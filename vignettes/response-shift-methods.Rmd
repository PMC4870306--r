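---
title: "Detecting response shift in ordinal items: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting response shift in ordinal items: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When patients answer the same quality-of-life questionnaire before and after a
major health event, the comparison of their scores over time presumes that the
questions still *mean* the same thing to them. Often they do not: patients
recalibrate their internal response scale, reprioritize which aspects of life
define their well-being, or reconceptualize the construct itself. These
*response shifts* confound observed change. `ordshift` implements a two-stage
structural-equation approach that detects response shifts in discrete ordinal
items (2-6 response categories, two measurement occasions) and separates them
from *true change* in the underlying construct.

## Stage 1: underlying continuous variables

Each ordinal item $x$ with $m$ categories is modelled as a discretized normal
variable $y^*$: category $i$ is observed when
$\delta_{i-1} < y^* < \delta_i$, with $\delta_0 = -\infty$,
$\delta_m = +\infty$ and $m - 1$ ordered thresholds. If $y^*$ is standard
normal, $\delta_i$ is the normal quantile of the cumulative response
proportion (`thresholds_from_props()`). Associations between two items are
polychoric (tetrachoric for binary items) correlations: the correlation of the
two underlying normals that best reproduces the observed contingency table by
maximum likelihood (`polychoric()`).

Stage 1 proceeds in four steps (`run_stage1()`):

1. **Underlying bivariate normality.** For every pair of variables with 3+
   categories, the discretized-bivariate-normal model is tested against the
   saturated multinomial: $LR$ on $m_1 m_2 - m_1 - m_2$ df, with a Bonferroni
   level $\alpha^* = \alpha / (2n^2 - n)$ across the battery, and the RMSEA
   (cutoff 0.1 by default) as the tenability criterion. Pairs of dichotomous
   items carry no information about this hypothesis, so dichotomous variables
   are tested in triplets against a discretized trivariate normal (1 df,
   `tvn_test()`).
2. **Threshold invariance.** For each item the equal-thresholds longitudinal
   model is compared to the model with occasion-specific thresholds
   ($m - 3$ df; applicable only for 4+ categories). Rejection indicates
   recalibration relative to the underlying variable's scale.
3. **Follow-up.** With 5+ categories, single thresholds can be freed one at a
   time (1 df each) to locate where on the response scale the recalibration
   happened. Recalibrated items keep occasion-specific thresholds and are
   excluded from Stage-2 invariance constraints and from change
   interpretation.
4. **True change per item.** Under equal thresholds the underlying variable's
   means and SDs may differ by occasion; the standardized change is
   $d = (\hat\mu_2 - \hat\mu_1) / \hat\sigma_{\text{diff}}$ with
   $\hat\sigma_{\text{diff}} = \sqrt{\hat\sigma_1^2 + \hat\sigma_2^2 -
   2\hat\rho\hat\sigma_1\hat\sigma_2}$; 0.2 / 0.5 / 0.8 are read as small /
   medium / large.

### Estimation flow

The default per-item estimator (`method = "two_step"`) mirrors the classical
PRELIS-style longitudinal workflow: thresholds are the standard-normal
quantiles of the *baseline* margin (so the baseline underlying variable is the
reference, mean 0 and SD 1); the follow-up mean and SD are then estimated by
ML on the follow-up margin given those thresholds; and the pre-post
correlation by ML on the joint table given all margin parameters.
Cross-variable correlations are likewise estimated with each variable's scale
held fixed. A joint-ML alternative (`method = "ml"`) maximizes the full
multinomial likelihood; the two agree asymptotically. The two-step flow is the
default because it is the one under which published worked values of this
procedure reproduce exactly; the joint-ML flow is used inside the
threshold-invariance tests, where both compared models must be ML fits for the
likelihood-ratio difference to be valid.

### Identification of the underlying scale

Two equivalent identifications are supported (`reparameterize()` maps between
them, and all effect sizes are invariant):

* **standard** — means sum to zero and squared SDs sum to the number of
  occasions across occasions ($\mu_1 + \mu_2 = 0$,
  $\sigma_1^2 + \sigma_2^2 = 2$);
* **alternative** — the first two thresholds are fixed at 0 and 1
  (dichotomous items: threshold 0, SDs 1).

Stage-1 reports print thresholds in the standard identification and means/SDs
in the alternative one, following the conventional layout. The moments passed
to Stage 2 are assembled in the **alternative** identification for a
structural reason: under the standard identification the stacked moment vector
satisfies exact per-item constraints, so the asymptotic covariance of the
moments is singular and weighted least squares is undefined.

### The weight matrix

`estimate_acov()` treats the entire two-step flow as a stack of estimating
equations (threshold quantile conditions; margin-likelihood scores for the
follow-up mean/SD; pairwise-likelihood scores for each correlation, with
cross-derivative blocks capturing the dependence of second-step equations on
first-step parameters) and computes the sandwich covariance
$A^{-1} B A^{-1\prime}/N$ of all parameters from per-subject scores, then maps
it to the stacked moment vector by the delta method. This accounts for the
fact that all pairwise tables share the same subjects.

## Stage 2: the longitudinal common factor model

The underlying variables of one subscale are modelled as
$$\mu = \tau + \Lambda\kappa, \qquad
  \Sigma = \Lambda\Phi\Lambda' + \Theta,$$
with one common factor per occasion, every indicator loading on its
occasion's factor, and same-item residuals correlated across occasions.
Fitting minimizes the weighted least-squares discrepancy
$F = (s - \sigma(\theta))'\,W^{-1} (s - \sigma(\theta))$ over the free
parameters, where $s$ stacks the means and lower-triangle covariances and $W$
is the estimated asymptotic covariance of $s$; the minimized $F$ is the
chi-square statistic. When $W$ is unavailable or ill-conditioned (condition
number above $10^{10}$), the fit falls back to diagonally weighted least
squares with a mean-adjusted (Satorra-Bentler type) statistic; with no weight
information at all an unweighted fit is available but reports no test
statistic. Minimization is damped Gauss-Newton on the analytic Jacobian of
$\sigma(\theta)$ (the problem is nearly linear); standard errors use the
sandwich formula. Fit is summarized by the chi-square, RMSEA and ECVI with
90% confidence intervals from the noncentral chi-square
(`fit_indices()`, `noncentrality_ci()`), using $N - 1$ as the sample-size
multiplier throughout; nested models are compared by the chi-square
difference and the $q$-free ECVI difference
$(T_\text{diff} - 2\,df_\text{diff})/(N-1)$ (`chisq_diff_test()`).

The detection procedure (`detect_response_shift()`):

1. **Measurement model** — factor means fixed at 0 and variances at 1 at
   *both* occasions, no across-occasion constraints. Extra residual
   covariances can be configured per scale; a configured pair frees the full
   within- and cross-occasion covariance block of the two items (this is the
   convention under which the published models' degrees of freedom reproduce).
2. **No-response-shift model** — intercepts and loadings equal across
   occasions; only the occasion-1 factor mean and variance are fixed, so the
   occasion-2 factor mean and variance become estimable. Comparing this model
   to the measurement model is the global test for response shift.
3. **Iterative search** (`search_shifts()`) — only if the global test rejects
   (the search is *gated*; this is what keeps the false-detection rate of the
   whole procedure at the nominal level), each constrained intercept and
   loading is freed one at a time, the model refitted, and the release with
   the largest 1-df improvement kept, until the best release is no longer
   significant at `alpha_stop` (default 0.05; the gate makes further
   correction unnecessary for calibration, but a Bonferroni option exists).
   Ties break deterministically: intercepts before loadings, then item order.
   Freed intercepts are uniform recalibration, freed loading values
   reprioritization; a loading significant at one occasion only flags
   reconceptualization; residual variances (nonuniform recalibration) are
   excluded from the candidate set by default and can be enabled with
   `include_theta = TRUE`. Modification indices are not used for selection —
   selection is by actual refits.
4. **True change and decomposition** — from the final model,
   $d = (\hat\kappa_2 - \hat\kappa_1) / \sqrt{\hat\varphi_{11} +
   \hat\varphi_{22} - 2\hat\varphi_{21}}$ per factor (`true_change()`), and
   per item the exact identity
   $\mu_2 - \mu_1 = (\tau_2 - \tau_1) + (\Lambda_2 - \Lambda_1)\kappa_2 +
   \Lambda_1\kappa_2$ (recalibration + reprioritization/reconceptualization +
   true change), each component standardized by that item's model-implied SD
   of change (`decompose_change()`).

### Special cases

* **Single-item scales** get Stage-1 analyses only (a one-indicator factor
  model is not identified).
* **Two-item scales** need one extra restriction: zero same-item
  cross-occasion residual covariances or equal loadings within occasion
  (`two_item_identification()`; `"auto"` fits both and keeps the
  better-fitting one). If the global test indicates response shift, which of
  the two intercepts to free is statistically arbitrary — the model with
  item 1's intercept freed fits exactly as well as the model with item 2's —
  so the package requires an explicit, substantively motivated
  `free_intercept` choice in the configuration and otherwise reports the
  global evidence without freeing anything.
* **Dichotomous scales** are on the tetrachoric scale, with unit variances at
  both occasions by construction; those variance moments carry no
  information, so they are excluded from the WLS discrepancy and the residual
  variances are derived. The constrained model cannot express across-occasion
  variance differences through residuals, so the no-response-shift model gains
  free occasion-2 scale factors (the first item's fixed at 1 when all items
  are dichotomous), entering as $\mu = D(\tau + \Lambda\kappa)$,
  $\Sigma = D(\Lambda\Phi\Lambda' + \Theta)D$. Loadings of dichotomous items
  leave the candidate set — only intercept (recalibration) shifts are
  detectable — and the presence of response shift is judged from the overall
  fit of the no-response-shift model rather than a difference test.

## The synthetic-data generator

`sim_config()` / `simulate_ordinal()` generate subject-level data in the
generative direction of the same model: factor scores
$\xi \sim N(\kappa, \Phi)$, residuals from the per-item 2x2 residual blocks,
$y^* = \tau + \Lambda\xi + \varepsilon$, discretized by per-item per-occasion
thresholds. Draws are subject-major from a single seeded generator, so a seed
fixes the dataset byte-for-byte. `inject_shift()` offsets the occasion-2 copy
of one parameter: intercepts (uniform recalibration), loadings
(reprioritization), residual variances (nonuniform recalibration), thresholds
(Stage-1 recalibration) or the factor mean (true change).

The default configuration mirrors a mental-health-like subscale: 5 items, 6
categories, 2 occasions, N = 437. Where the generating values are not dictated
by that shape we chose conventional moderate values once: loadings 0.7, unit
factor variances with pre-post factor correlation 0.6, residual variances
$1 - \lambda^2$ (unit-variance indicators), same-item residual correlation
0.3 across occasions, and equally spaced thresholds from -1.5 to 1.5. The
generator emulates the measurement structure of real data — ordinal
discretization, longitudinal dependence, common-factor structure — but not
survey realism: no missing data mechanisms, no skew-heavy category use, no
violations of underlying normality, a single factor per occasion. Passing
recovery and calibration tests therefore demonstrates correctness of the
estimators and the detection logic under the model, not robustness to
violations of it.

## Numerical choices

* Bivariate normal rectangle probabilities use deterministic Gauss-Legendre
  quadrature (48 nodes) on the smooth angular form of the
  Drezner-Wesolowsky identity, vectorized over cells; for $|\rho| > 0.925$
  the computation is delegated to a deterministic Gauss-quadrature routine
  specialized for two and three dimensions (mvtnorm's TVPACK). Accuracy is
  checked against an independent CDF oracle at $10^{-9}$.
* Correlations are estimated on the Fisher-$z$ scale, SDs on the log scale,
  thresholds as a first value plus log-increments; estimates of $|\rho|$ are
  capped at 0.999 with a boundary warning.
* No continuity correction by default; `smooth = 0.5` adds the conventional
  correction. Empty cells contribute zero to the saturated log-likelihood.
* Categories empty at both occasions are collapsed into the adjacent lower
  category, with a warning and a recorded mapping.
* The WLS minimizer is damped Gauss-Newton with analytic Jacobians, relative
  tolerance $10^{-12}$; a deterministic start (loadings 0.7, intercepts at
  the sample means, residual variances at half the sample variances) makes
  refits reproducible. Negative residual-variance solutions (Heywood cases)
  produce a warning by default and can be bounded at zero with
  `bound_theta = TRUE` (bounded fits use a projected quasi-Newton method).
* Stage-1 batteries are Bonferroni-corrected; Step-2/3 threshold tests are
  reported unadjusted, with an optional adjustment flag in the search.

## Problem sizes used in the packaged checks

The test suite exercises the pipeline at the sizes where its statistical
claims are sharp but cheap: recovery checks use N of 500-6000 with 2-5 items;
the detection calibration study uses the default 5-item 6-category shape at
N = 2000 with 100 replicates per arm (one injected 0.4 SD intercept shift vs
none), and the bootstrap validation of the moment covariance uses 150
resamples of an N = 700 two-item dataset. These sizes were chosen so each
property is tested at conventional power, and they are stated here so results
can be reproduced exactly.

## Known limitations

* Two measurement occasions are validated end-to-end; the data structures
  allow more, but no multi-occasion behavior is tested.
* No polyserial correlations (mixed ordinal-continuous), no item-response-
  theory (full-information) estimation route, no copula or non-normal latent
  distributions, and no imputation — subjects with missing responses in the
  analyzed scale are dropped listwise (with a logged count).
* Reconceptualization across different subscales or involving external
  covariates is out of scope; the reconceptualization check is the
  within-scale loading-significance pattern.
* WLS needs substantial samples to behave; the automatic DWLS fallback
  mirrors standard practice for small N or large models, but no small-sample
  corrections beyond the mean adjustment are provided.
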