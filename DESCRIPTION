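Package: pmlbin
Title: Pairwise Likelihood Estimation and Limited-Information Fit Tests for
    Binary Factor Models under Complex Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weighted pairwise maximum likelihood estimation of factor
    analysis models for binary items under the underlying-variable (probit)
    formulation, with Godambe (sandwich) standard errors for independent,
    informative, and stratified multistage cluster sampling designs.
    Provides limited-information goodness-of-fit statistics built from
    univariate and bivariate margin residuals (Wald with pseudo-inverse,
    orthogonal-complement Wald, diagonal Wald, Pearson, residual sum of
    squares, and multinomial-weighted quadratic forms) with moment-matched
    chi-square reference distributions, design-based covariance estimation
    of sample moments, and simulators for informative selection and
    school-based two-stage and stratified cluster sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
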