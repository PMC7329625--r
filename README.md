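# refractQR

Quantile regression analysis of genetic and environmental risk factors for
refractive error in childhood cohorts.

## What it does and for whom

Epidemiologists studying myopia usually quantify a risk factor (high
polygenic risk, parental myopia, high reading time, low outdoor time) with
ordinary least squares, which assumes one effect size for everybody.
refractQR implements the alternative: conditional quantile regression
(CQR) across the 19-quantile grid τ = 0.05, 0.10, …, 0.95 of the
refractive error distribution, which lets the effect differ between
children in the myopic tail and children near emmetropia. Around that
estimator it provides the full analysis chain such a study needs:

* **Phenotype coding** — spherical equivalent (sphere + cyl/2), two-eye
  averaging, polygenic risk scores from dosage panels with
  centre-then-binarise high-risk coding, and data-file-driven
  questionnaire codings (1 = higher myopia risk).
* **Estimation** — `cqr()` minimises the pinball loss
  ρ_τ(u) = u(τ − 1{u<0}) exactly via a Frisch–Newton interior point
  method on the dual linear program (implemented in C++), with
  `fit_ols()` as the conventional companion and case-resampling
  percentile bootstrap intervals.
* **Inference** — permutation contrasts of β(τ) − β(0.50), random-effects
  (DerSimonian–Laird) meta-regression of effect size on age, and loess
  smoothing of effect profiles.
* **Missing data** — chained-equation multiple imputation (logistic /
  predictive-mean-matching) with Rubin-rule pooling.
* **Validation** — a synthetic cohort generator with the location–scale
  model Y = μ0 + Σβ_j X_j + σ0·exp(Σγ_j X_j)·ε, whose true quantile
  effect for a single binary factor is the closed form
  β + σ0(e^γ − 1)F_ε⁻¹(τ), so every stage can be checked against ground
  truth.

## Worked example

```r
library(refractQR)

cfg <- sim_config(20000, age_groups = 7,
                  factors = list(factor_spec("f", 0.5, beta = -0.125,
                                             gamma = log(2))),
                  mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 301)
tab <- simulate_cohort(cfg)

true_quantile_effect(cfg, "f", c(0.05, 0.5))
#> [1] -1.769854 -0.125000

g <- cqr_grid(refractive_error ~ f, tab, taus = c(0.05, 0.5))
coef(g)
#>        0.05         0.5
#> -1.73862148 -0.09562778

fit_ols(refractive_error ~ f, tab)$beta
#> [1] -0.08454455
```

The factor shifts the location by −0.125 D and doubles the residual scale
(γ = log 2), so its true effect is −0.125 D at the median but −1.77 D at
the 5th percentile — the tail-amplified pattern CQR is designed to
detect; the fitted coefficients recover both, while OLS tracks the mean
effect (−0.125) and entirely misses the tail amplification. With the
left-skewed error distribution the generator uses by default, the OLS
estimate falls between the τ = 0.05 and τ = 0.50 effects (checked in the
validation suite). A contrast of the two quantiles is tested by
permutation:

```r
permutation_quantile_contrast(refractive_error ~ f, tab,
                              tau = 0.05, n_perm = 199, seed = 5)
#> Permutation contrast for `f`: beta(0.05) - beta(0.50)
#>   delta = -1.6430 D  (beta(0.05) = -1.7386, beta(0.50) = -0.0956)
#>   p = 0.005  (199 permutations)
```

`run_analysis(analysis_config(...))` chains coding, estimation, contrasts,
age trends, profiles, demographics and the optional imputation branch into
TSV reports; `inst/scripts/refractqr` wraps it for the shell.

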