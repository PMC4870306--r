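# ordshift

Response-shift detection and true-change estimation for **ordinal**
questionnaire items measured at two occasions, by two-stage structural
equation modelling.

When the same health-related quality-of-life instrument (e.g., the SF-36) is
administered before and after a major health event, patients may change their
internal standards (*recalibration*), the importance they attach to an item
(*reprioritization*), or the meaning of the construct itself
(*reconceptualization*). These response shifts confound the comparison of
scores over time. `ordshift` separates them from *true change* at the level of
individual Likert-type items (2–6 response categories), for researchers in
patient-reported outcomes, psychometrics and epidemiology.

## The model

**Stage 1.** Each ordinal item *x* is a discretized normal variable *y\**:
category *i* is observed when δ<sub>i−1</sub> < *y\** < δ<sub>i</sub>.
Thresholds, per-occasion means/SDs of *y\** under equal thresholds, and
polychoric (tetrachoric) correlations are estimated from the contingency
tables by maximum likelihood; underlying bivariate normality and threshold
invariance across occasions are tested by likelihood ratio (df = m₁m₂−m₁−m₂
and m−3). Standardized change per item is
d = (μ̂₂−μ̂₁)/√(σ̂₁²+σ̂₂²−2ρ̂σ̂₁σ̂₂).

**Stage 2.** The Stage-1 means and covariances feed a longitudinal common
factor model, μ = τ + Λκ, Σ = ΛΦΛ′ + Θ, fitted by weighted least squares with
the estimated asymptotic covariance of the moments as weight (DWLS with a
mean-adjusted statistic as fallback). Comparing the measurement model (factor
means 0, variances 1 at both occasions) to the no-response-shift model
(invariant τ and Λ) tests globally for response shift; constrained parameters
are then freed one at a time, keeping the largest 1-df improvement, until no
release is significant. Freed τ = uniform recalibration, freed Λ values =
reprioritization, loadings significant at one occasion only =
reconceptualization. Change per item decomposes exactly as
μ₂ − μ₁ = (τ₂−τ₁) + (Λ₂−Λ₁)κ₂ + Λ₁κ₂, and true change in the construct is
d = κ̂₂/√(φ̂₁₁+φ̂₂₂−2φ̂₂₁). Fit is judged by χ², RMSEA and ECVI with 90%
noncentrality-based intervals; nested models by the χ² and ECVI differences.

See the methods vignette (`vignettes/response-shift-methods.Rmd`) for
estimators, identification (standard vs alternative parameterization),
two-item and dichotomous-scale special cases, and numerical choices.

## Worked example

Fit the equal-thresholds longitudinal model to the packaged frequency margins
of the "nervousness" item (6 categories, N = 437, measured before and ~4 weeks
after the start of antineoplastic treatment):

```r
library(ordshift)

fit <- fit_item_longitudinal(margins = list(sf36_margins("24", 1),
                                            sf36_margins("24", 2)))
reparameterize(fit$scale, "alternative")
#> <underlying_scale> (alternative parameterization)
#>   thresholds: 0.000 1.000 1.919 3.868 5.051
#>   means:      3.222 3.826
#>   sds:        1.741 1.788

row <- subset(sf36_stage1_estimates(), item == "24")
stage1_effect_size(reparameterize(fit$scale, "alternative"), row$rho)
#> # A tibble: 1 x 4
#>   change sd_diff     d magnitude
#>    <dbl>   <dbl> <dbl> <chr>
#> 1  0.604    1.60 0.378 small
```

The underlying "nervousness" variable improved by d ≈ 0.38 — the published
analysis of these margins reports means 3.23/3.83 and d = 0.37.

End to end on synthetic data with one injected intercept shift
(uniform recalibration of item 3, +0.4 SD at follow-up, N = 2000):

```r
cfg <- inject_shift(sim_config(n_subjects = 2000, seed = 17),
                    "intercept", item = 3, delta = 0.4)
res <- detect_response_shift(simulate_ordinal(cfg), sim_scale_config(cfg))
res$findings
#> # A tibble: 1 x 8
#>   order group      type                  item   chisq_diff df_diff        p direction
#>   <int> <chr>      <chr>                 <chr>       <dbl>   <int>    <dbl>     <dbl>
#> 1     1 tau_item_3 uniform_recalibration item_3       189.       1 5.13e-43     0.575

res$true_change
#> # A tibble: 1 x 6
#>    change sd_diff       d     se     p stars
#>     <dbl>   <dbl>   <dbl>  <dbl> <dbl> <chr>
#> 1 -0.0281   0.875 -0.0321 0.0253 0.266 ""
```

The injected shift is found first (and only), classified as uniform
recalibration with the right sign, and after accounting for it the estimated
true change in the common factor is null — as generated. The decomposition
(`res$decomposition`) shows item 3's apparent improvement (d ≈ 0.39) is
recalibration (d ≈ 0.41), not true change.

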