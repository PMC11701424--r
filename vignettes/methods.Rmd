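---
title: "Methods: pairwise likelihood and limited-information fit testing for binary factor models under complex sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`pmlbin` works with the underlying-variable formulation of the binary
factor model. Each observed item $y_i \in \{0,1\}$, $i = 1, \dots, p$,
is a dichotomization of a latent standard normal variable:
$y_i = 1 \iff y_i^* > \tau_i$, where

$$y^* = \Lambda\eta + \varepsilon, \qquad \eta \sim N_q(0, \Psi), \qquad
\varepsilon \sim N_p(0,\, \Theta_\varepsilon),\qquad
\Theta_\varepsilon = I - \mathrm{diag}(\Lambda\Psi\Lambda'),$$

so $\Sigma_{y^*} = \Lambda\Psi\Lambda' + \Theta_\varepsilon$ is a
correlation matrix whose off-diagonal entries are the tetrachoric
correlations $\rho_{ij} = [\Lambda\Psi\Lambda']_{ij}$. The free
parameters are $\theta = (\lambda, \rho, \tau)$ of dimension $m$: free
loadings in column-major order over the loading pattern, free
lower-triangular factor correlations, and the $p$ thresholds.
Assumptions inherited from this formulation: items are conditionally
independent given $\eta$, the latent link is Gaussian, one threshold per
item (binary, not ordinal, responses), and complete data.

Admissibility requires $\mathrm{diag}(\Lambda\Psi\Lambda') \le 1 -
10^{-8}$ (positive unique variances), $|\rho| < 1$, and positive
definite $\Psi$. Inadmissible iterates during optimization are handled
by the box transform and step halving described below.

## Weighted pairwise estimation

The weighted pairwise log-likelihood sums, over all $\binom{p}{2}$ item
pairs and their four response cells, the weighted cell proportions times
log model cell probabilities. Since each cell probability is a
bivariate normal rectangle, evaluation needs only $\Phi_2$, never a
$p$-dimensional integral. Survey weights enter through the cell
proportions and are normalized to sum to $n$ before estimation, which
makes simple random sampling the unit-weight special case and fixes the
scale of all variance formulas ($n_{\mathrm{eff}} = n$).

The estimator solves $\nabla\ell_P(\theta) = 0$. Its asymptotic
covariance is the Godambe sandwich $H^{-1} J H^{-1} / n$:

- $H$, the sensitivity matrix, is the negative Hessian of the pooled
  weighted pairwise log-likelihood, computed analytically from closed
  forms of the first and second derivatives of $\Phi_2$ (a
  finite-difference route is kept as a cross-check; the two agree to
  $10^{-6}$ in the test suite).
- $J$, the variability matrix, is estimated two ways. Under
  independence, $J = n^{-1}\sum_h (w_h u_h)(w_h u_h)'$ with $u_h$ the
  per-unit pairwise score. Under stratified multistage sampling, the
  between-cluster estimator
  $J = n^{-1}\sum_a \frac{n_a}{n_a-1}\sum_b (z_{ab}-\bar z_a)(z_{ab}-\bar
  z_a)'$ with $z_{ab}$ the weighted score total of PSU $b$ in stratum
  $a$.

The per-unit score contributions are taken as $w_h u_h$ with weights
normalized to sum to $n$. The published formulas leave the
weight-vs-normalization convention implicit; this choice makes the
singleton-PSU case collapse exactly to $\tfrac{n}{n-1}$ times the
independence estimator, and is validated empirically: nominal 95%
intervals from the weighted fit cover at $\approx .95$ under informative
selection in the test suite.

**Optimization.** BFGS with analytic gradients on a transformed scale —
$\mathrm{atanh}$ on factor correlations and (for single-loading-per-item
patterns, which guarantee admissibility) on loadings — followed by
Newton polishing with step halving, stopping when
$\max|\nabla\ell_P| < 10^{-6}$. Starting values: thresholds matched to
the observed weighted margins, loadings $0.5$, factor correlations $0$.
Non-convergence is flagged but estimates are still returned.

## Limited-information fit statistics

With $S = p(p+1)/2$ univariate and bivariate moments, the residual
vector is $\hat e_2 = p_2 - \pi_2(\hat\theta)$. Its asymptotic
covariance is

$$\Omega_2 = (I - \Delta_2 H^{-1} B)\, \Sigma_2\, (I - \Delta_2 H^{-1}
B)',$$

where $\Delta_2 = \partial\pi_2/\partial\theta'$, $\Sigma_2$ is the
covariance of $\sqrt n (p_2 - \pi_2)$, and $B(\theta)$ is the $m \times
S$ matrix with $\nabla\ell_P = B(\theta)(p_2 - \pi_2)$. The $B$ matrix
is assembled from the fixed linear maps between pairwise cells and
moments ($p_{11} = \dot\pi_{ij}$, $p_{10} = \dot\pi_i - \dot\pi_{ij}$,
etc.; constants cancel): row $k$ accumulates $(\partial\pi_{\rm
cell}/\partial\theta_k)/\pi_{\rm cell}$ times each cell's design vector.
Because the source text's appendix with this construction is not
available, the assembly is validated *by the identity itself*, which
holds to machine precision for arbitrary data in the test suite — a
stronger check than matching printed algebra.

Six statistics $X^2 = n\,\hat e_2' \hat\Xi\, \hat e_2$ are provided:

| name | $\Xi$ | reference distribution |
|---|---|---|
| Wald | $\Omega_2^{+}$ (rank $S-m$) | $\chi^2_{S-m}$ |
| VCF Wald | $\Delta_2^\perp((\Delta_2^\perp)'\Sigma_2\Delta_2^\perp)^{-1}(\Delta_2^\perp)'$ | $\chi^2_{S-m}$ exactly |
| diagonal Wald | $\mathrm{diag}(\Omega_2)^{-1}$ | moment-matched |
| Pearson | $\mathrm{diag}(\pi_2)^{-1}$ | moment-matched |
| RSS | $I$ | moment-matched |
| multinomial | $[\mathrm{diag}(\pi_2)-\pi_2\pi_2']^{-1}$ | moment-matched |

Numerical decisions, in order of consequence:

- **Wald rank rule.** The pseudo-inverse retains exactly the largest
  $S-m$ eigenvalues rather than thresholding, matching the reference
  degrees of freedom; when the ratio of the smallest retained to the
  largest discarded eigenvalue is below 10, a note is recorded in the
  result, since the p-value then genuinely depends on the rank call.
- **Moment matching.** The mixtures $\sum_s \delta_s U_s$ (with
  $\delta_s$ the eigenvalues of $L'\Xi L$, $L$ the Cholesky factor of
  $\Omega_2$, jittered by $10^{-10}$ if needed) are approximated by
  $c\,\chi^2_\nu$ matching two moments: $c = \sum\delta^2/\sum\delta$,
  $\nu = (\sum\delta)^2/\sum\delta^2$. The referenced moment-matching
  appendix is likewise unavailable; two-moment (Satterthwaite)
  matching is the standard practice in this literature, Monte-Carlo
  calibration in the test suite confirms tail accuracy (~.01 at the
  .95 quantile), and the eigenvalues are exposed in the result so a
  three-moment variant is a small extension.
- Negative eigenvalues of $\Omega_2$ (numerical) are clipped at zero.

$\Sigma_2$ comes in two flavors: model-based multinomial
(`sigma2_srs_model`, for iid sampling) and the design-based
between-cluster estimator (`sigma2_multistage`), which centers PSU
totals of the moment indicators at the null/estimated moments. Its
SRS reduction to $\tfrac{n}{n-1}\,T_2(\mathrm{diag}(p)-pp')T_2'$ is
exact and tested; note the centering vector cancels algebraically in
the unit-PSU case.

## Computing model-implied probabilities

Bivariate rectangle probabilities use a port of Genz's hybrid
Gauss-Legendre/singular-expansion algorithm for $\Phi_2$ (absolute
error below $10^{-12}$; validated against 2-D adaptive quadrature).
Cells are assembled from one orthant probability and univariate margins
so each pair's four cells sum to one exactly.

Everything above second order — full response-pattern probabilities,
and the third- and fourth-order joint moments needed for the
off-diagonal entries of the multinomial $\Sigma_2$ — exploits
conditional independence given $\eta$: the joint positive-response
probability of a set $A$ is $\int \prod_{i \in A}\Phi\!\big((\lambda_i'
\eta - \tau_i)/\sigma_i\big)\, dN_q(0,\Psi)$, evaluated by
Gauss-Hermite product quadrature (101 nodes for $q=1$, 35 for $q=2$, 21
for $q=3$). This sidesteps both $2^p$ enumeration and 4-dimensional
rectangle integration; agreement with the explicit
$T_2(\mathrm{diag}(\pi)-\pi\pi')T_2'$ construction at $p=5$ is at
machine precision, and with the $\Phi_2$ route for pairs at $10^{-14}$.
Pattern probabilities are refused for $p > 15$.

**Conventions.** Pairs are ordered lexicographically $(1,2), (1,3),
\dots, (p-1,p)$; response patterns are indexed by the bits of $r-1$
with item $p$ varying fastest. These orderings are shared by $T_2$,
$B$, $\Sigma_2$, and the samplers; they are package conventions, since
no ordering is canonical.

## The synthetic worlds

The generators' defaults are the stated conditions of the validation
studies; they are fixed, not tuning knobs.

**Flat population with informative selection.** Units drawn from the
model; selection propensity $1/(1+\exp(y_1^*))$ rescaled to inclusion
probabilities summing to $n$; a fixed-size systematic
unequal-probability draw; weights are reciprocal inclusion
probabilities. The population-to-sample ratio defaults to 100
($n/N = 1\%$), small enough that no finite-population correction is
needed. Selection depends on the latent variable, so unweighted
estimation of $\tau_1$ is biased by about $+0.31$ at the default true
values, while weighted estimation is approximately unbiased — the
package's tests and acceptance script recompute both.

**School population.** 2000 schools in three ability-stratified types
(A: 400 schools, average class size 15; B: 1000/25; C: 600/20), school
sizes $\mathrm{round}(N(500, 125))$, about one million students.
Students are ranked by their first factor score and allocated to type A
until its seats fill, then B, then C; within a school, students are
assigned uniformly at random to $\max(1, \mathrm{round}(\text{size} /
\text{avg class}))$ classes. Two designs sample it: two-stage PPS
cluster sampling ($\lfloor n/21.5\rfloor$ schools by systematic PPS on
size, one class per school, all its students) and stratified cluster
sampling ($\lfloor n/60\rfloor$ schools per stratum by SRS, one class
per school). Weights invert the stated selection probabilities; for the
PPS design the published probability omits the constant number-of-PSUs
factor, which is harmless because the pairwise likelihood normalizes
weights. The resulting between-school intraclass correlations fall in
roughly $[.04, .25]$ for the default one-factor model — inside the
stated $[.05, .6]$ envelope for the strongly loading items, slightly
below it for the weakest item ($\lambda_5 = .34$), which a per-item
tolerance in the tests acknowledges. Class-size dispersion (SD ≈ 5-6)
emerges from size variation plus multinomial assignment rather than
being imposed.

What the generators do *not* emulate: nonresponse, calibration
weighting, covariate-driven ICC structure, within-class dependence
beyond the factor model. A green test therefore establishes correctness
of the estimator and test statistics *under the model and the stated
designs*, not robustness to violations of the latent-Gaussian link.

**Misspecification (power) generator.** An extra latent $z \sim N(0,1)$
independent of $\eta$ loads on all items except items 2, 6, 14 (where
present; all items for multi-factor models), with loadings equal to the
item's factor loading. Keeping residual variances at their null-model
values and rescaling the affected $y_i^*$ by $(1+\lambda_{z,i}^2)^{-1/2}$
preserves unit variances — the alternative of shrinking residual
variances to absorb $\lambda_z^2$ is infeasible for the strongest item
($0.8^2 + 0.8^2 > 1$). A consequence worth recording: with
proportional $z$-loadings and a *single* excluded item, the implied
correlation matrix is still exactly rank one (the excluded item's
effective loading folds into the modified metric), so the five-item
one-factor power scenario is asymptotically undetectable; genuine
misfit requires at least two excluded items, and the package's power
check accordingly uses the eight-item model, where rejection rates rise
steeply with $n$ (≈ .25 at $n=500$ to ≈ .93 at $n=2500$ for Pearson at
$\alpha = .05$ in a 40-replication spot check).

## Replication summaries

`replicate_study()` re-runs sampling + estimation + testing. For the
informative design it reports bias, empirical SD, dispersion about the
true value (RMSE), mean estimated SE, their ratio, and 95% CI coverage
per parameter for both weighted and unweighted fits. The reported
`sd_se_ratio` uses the RMSE numerator: for unbiased estimators this
coincides with the plain SD ratio, and for biased ones it is the
quantity that the published diagnostic actually tracks (the plain ratio
stays near 1 even when intervals cover 1% of the time). For the SRS and
complex designs it reports rejection rates of the six statistics at
chosen levels.

## Known limitations

- Binary items only; no ordinal thresholds, no non-Gaussian links.
- No full-information ML, no three-stage WLS; the full-pattern Pearson
  statistic is a small-$p$ diagnostic without a valid reference
  distribution at pairwise estimates.
- No finite-population corrections and no replication-weight
  (jackknife/bootstrap) variance estimation.
- The stratified design's PSU-count formula uses the floor as published;
  at some sample sizes the published PSU table matches rounding instead,
  and only the unambiguous cells are asserted.
- Identification is the user's responsibility for nonstandard loading
  patterns; the presets (one factor all-free; independent clusters with
  correlated factors) are identified.
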