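# pmlbin

Pairwise likelihood estimation and limited-information goodness-of-fit
testing for **binary factor analysis models under complex survey
sampling**.

## The problem

Factor models for binary items (test items, symptom indicators, survey
attitudes) are usually estimated from large-scale surveys whose samples
are anything but simple random: units are selected with unequal
probabilities (sometimes informatively, i.e. depending on the latent
trait being measured), and students sit inside classes inside schools
inside strata. `pmlbin` provides, for the underlying-variable probit
formulation of the binary factor model:

- **weighted pairwise maximum likelihood (PML) estimation**, which needs
  only bivariate normal probabilities regardless of the number of items
  or factors, with survey weights making it consistent under informative
  selection;
- **Godambe (sandwich) standard errors** `H⁻¹JH⁻¹/n`, with the
  variability matrix `J` estimated under independence or by the
  between-PSU estimator for stratified multistage designs;
- **six limited-information fit statistics** — quadratic forms
  `X² = n ê₂' Ξ ê₂` in the residuals `ê₂ = p₂ − π₂(θ̂)` of the
  `S = p(p+1)/2` univariate and bivariate margins — that avoid the
  sparse `2^p` pattern table: Wald (Moore–Penrose inverse of `Ω₂`),
  VCF Wald (orthogonal complement of the moment Jacobian; exact
  `χ²_{S−m}` without inverting `Ω₂`), diagonal Wald, Pearson
  (`Ξ = diag(π₂)⁻¹`), residual sum of squares, and multinomial-weighted,
  the last four referred to moment-matched scaled chi-squares;
- **design-based covariance estimation** of the sample moments under
  stratified multistage sampling; and
- **simulators** for the three validation designs: informative selection
  with `π_h = 1/(1 + exp(y₁*))`, and a ~1M-student school population
  sampled by two-stage PPS cluster and stratified cluster designs.

## Model

Each binary item is a dichotomized latent standard normal variable:
`y_i = 1 ⇔ y_i* > τ_i`, with `y* = Λη + ε`, `η ~ N_q(0, Ψ)`,
`Θ_ε = I − diag(ΛΨΛ')`, so that `Σ_y* = ΛΨΛ' + Θ_ε` is a correlation
matrix whose off-diagonal entries are the tetrachoric correlations. The
free parameters are `θ = (λ, ρ, τ)`. The weighted pairwise
log-likelihood is

```
ℓ_P(θ) = Σ_{i<j} Σ_{c_i,c_j} p_{c_i c_j}^{(ij)} log π_{c_i c_j}^{(ij)}(θ)
```

with `p` the weighted 2×2 cell proportions of each item pair.

## Worked example

```r
library(pmlbin)
set.seed(1)

spec   <- preset_model("1F5V")          # 1 factor, 5 items
theta0 <- preset_theta("1F5V")          # loadings .8 .7 .47 .38 .34,
                                        # thresholds -1.43 -.55 -.13 -.72 -1.13

## informative sample: selection depends on the first latent variable
pop  <- generate_factor_data(spec, theta0, N = 50000)
samp <- informative_sample(pop, n = 500)

fit <- fit_pml(samp, spec, weighted = TRUE)
fit
#> Pairwise ML fit (weighted): p = 5, q = 1, m = 10
#>   loglik = -9.855517, max|score| = 3.02e-08, converged: TRUE
#> lambda1.1 lambda2.1 lambda3.1 lambda4.1 lambda5.1      tau1      tau2      tau3
#>    0.8680    0.6879    0.5089    0.2820    0.3179   -1.4352   -0.5651   -0.1126
#>      tau4      tau5
#>   -0.7975   -1.0470

sw <- pml_sandwich(fit, "iid")
round(sw$se, 3)
#>  [1] 0.084 0.075 0.076 0.086 0.084 0.066 0.061 0.064 0.067 0.070

gof_tests(fit)$results
#>          name  statistic       df      scale    pvalue
#> 1        Wald 2.29876895 5.000000 1.00000000 0.8064477
#> 2     WaldVCF 2.30221659 5.000000 1.00000000 0.8059413
#> 3    WaldDiag 4.30549908 4.224331 3.55085814 0.8953952
#> 4     Pearson 0.10515627 4.422441 0.04431413 0.7268576
#> 5         RSS 0.05774467 4.751456 0.02252459 0.7374142
#> 6 Multinomial 0.10482368 4.417910 0.04425499 0.7269985
```

The weighted estimates sit within two standard errors of the generating
values, and none of the six statistics rejects the (correct) one-factor
model. Fitting the same sample with `weighted = FALSE` shows the
hallmark failure under informative selection: the threshold-1 estimate
comes out at −1.117 against a true value of −1.43 — the characteristic
bias of about +0.31.

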