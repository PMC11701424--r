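# Limited-information goodness-of-fit statistics.
#
# All statistics are quadratic forms X2 = n * e2' Xi e2 in the residual
# vector e2 = p2 - pi2(theta_hat) of univariate and bivariate margins.
# Under the composite null, sqrt(n) e2 is asymptotically normal with
# covariance Omega2 = (I - Delta2 H^-1 B) Sigma2 (I - Delta2 H^-1 B)',
# where B maps moment residuals to the pairwise score
# (grad l_P = B(theta) (p2 - pi2)).  Weight matrices Xi that do not make
# the quadratic form exactly chi-squared are referred to a moment-matched
# scaled chi-square via the eigenvalues of L' Xi L, L the Cholesky factor
# of Omega2.

#' Transformation matrix from pattern probabilities to moments
#'
#' The `S x R` 0/1 matrix mapping the `2^p` response-pattern probabilities
#' to the `S = p(p+1)/2` univariate and bivariate positive-response
#' moments.  Row ordering matches `pi2`; pattern columns are ordered with
#' item `p` varying fastest (see [pattern_matrix()]).
#'
#' @param p Number of items (2 to 20).
#' @return `S x R` matrix of 0s and 1s, rank `S`.
#' @export
build_T2 <- function(p) {
  stopifnot(p >= 2, p <= 20)
  C <- pattern_matrix(p)                 # R x p
  pairs <- model_spec(p, 1)$pairs
  T1 <- t(C)                             # p x R
  T2b <- t(C[, pairs[, 1], drop = FALSE] * C[, pairs[, 2], drop = FALSE])
  rbind(T1, T2b)
}

#' Weighted sample moments
#'
#' The `S`-vector `p2` of weighted first-order proportions
#' `Pr_hat(y_i = 1)` and second-order proportions `Pr_hat(y_i = 1, y_j = 1)`,
#' computed directly from the data (never materializing the `2^p` pattern
#' table).
#'
#' @param data A [survey_dataset()].
#' @return Numeric vector of length `p(p+1)/2`.
#' @export
sample_moments <- function(data) {
  y <- data$y
  w <- data$w / sum(data$w)
  pairs <- model_spec(ncol(y), 1)$pairs
  m1 <- colSums(y * w)
  m11 <- crossprod(y, y * w)
  c(m1, m11[pairs])
}

#' Margin residuals of a fitted model
#'
#' `e2 = p2 - pi2(theta_hat)`.
#'
#' @param data A [survey_dataset()].
#' @param fit A [fit_pml()] result (or a theta vector together with
#'   `spec`).
#' @param spec Required when `fit` is a bare theta vector.
#' @return Numeric residual vector of length `S`.
#' @export
gof_residuals <- function(data, fit, spec = NULL) {
  if (inherits(fit, "pml_fit")) {
    spec <- fit$spec
    theta <- fit$theta
  } else theta <- fit
  sample_moments(data) - implied_moments(spec, theta)$pi2
}

#' Score-to-residual transformation matrix B(theta)
#'
#' The `m x S` matrix satisfying `grad l_P(theta) = B(theta) (p2 -
#' pi2(theta))` for any data set.  Each pairwise cell proportion is a fixed
#' linear combination of first- and second-order moments
#' (`p11 = pidot_ij`, `p10 = pidot_i - pidot_ij`, `p01 = pidot_j -
#' pidot_ij`, `p00 = 1 - pidot_i - pidot_j + pidot_ij`; the constant
#' cancels in the residual), and row `k` of `B` accumulates
#' `(d pi_cell / d theta_k) / pi_cell` times the cell's design vector.
#'
#' @inheritParams theta_unpack
#' @return `m x S` matrix.
#' @export
build_B <- function(spec, theta) {
  up <- theta_unpack(spec, theta)
  rho <- .pair_rho(spec, theta)
  drho <- .drho_dtheta(spec, theta)
  tau_off <- spec$nlam + spec$nrho
  B <- matrix(0, spec$m, spec$S)
  for (pr in seq_len(spec$npairs)) {
    i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
    pc <- .pair_cells(up$tau[i], up$tau[j], rho[pr])
    pi_c <- pc$probs
    if (any(pi_c <= 0)) stop("zero model cell probability in build_B")
    # d log pi_cell / d theta for the 4 cells: 4 x m
    G <- matrix(0, 4, spec$m)
    G[, tau_off + i] <- pc$grad[, 1] / pi_c
    G[, tau_off + j] <- pc$grad[, 2] / pi_c
    G <- G + (pc$grad[, 3] / pi_c) %o% drho[pr, ]
    # design vectors on (e_i, e_j, e_ij): rows cells (0,0),(0,1),(1,0),(1,1)
    des <- rbind(c(-1, -1, 1), c(0, 1, -1), c(1, 0, -1), c(0, 0, 1))
    cols <- c(i, j, spec$p + pr)
    B[, cols] <- B[, cols] + t(G) %*% des
  }
  B
}

#' Asymptotic covariance of the margin residuals
#'
#' `Omega2 = (I - Delta2 H^-1 B) Sigma2 (I - Delta2 H^-1 B)'`, on the
#' scale of `sqrt(n) e2`.  With `Delta2 = 0` (no estimated parameters) it
#' reduces to `Sigma2`, the simple-null case.
#'
#' @param Delta2 `S x m` moment Jacobian (see [jacobian_pi2()]).
#' @param H Sensitivity matrix (see [sensitivity_H()]).
#' @param B `m x S` matrix from [build_B()].
#' @param Sigma2 `S x S` covariance of `sqrt(n)(p2 - pi2)` (model-based
#'   multinomial, [sigma2_srs_model()], or design-based,
#'   [sigma2_multistage()]).
#' @return Symmetric `S x S` matrix.
#' @export
omega2_matrix <- function(Delta2, H, B, Sigma2) {
  S <- nrow(Sigma2)
  A <- diag(S) - Delta2 %*% solve(H, B)
  O <- A %*% Sigma2 %*% t(A)
  (O + t(O)) / 2
}

#' Moment-matched reference distribution for a chi-square mixture
#'
#' A quadratic form with weight matrix `Xi` converges to
#' `sum_s delta_s U_s`, `U_s ~ chi^2_1`, with `delta_s` the eigenvalues of
#' `Omega2^{1/2} Xi Omega2^{1/2}`.  The mixture is approximated by a scaled
#' chi-square `c * chi^2_nu` matching the first two moments:
#' `c = sum(delta^2)/sum(delta)`, `nu = sum(delta)^2 / sum(delta^2)`.
#'
#' @param statistic Observed quadratic-form value.
#' @param delta Eigenvalues (tiny negatives are clipped to zero).
#' @return List with `scale`, `df`, `pvalue`.
#' @export
moment_match <- function(statistic, delta) {
  delta <- pmax(delta, 0)
  s1 <- sum(delta); s2 <- sum(delta^2)
  if (s1 <= 0 || s2 <= 0) return(list(scale = NA_real_, df = NA_real_,
                                      pvalue = NA_real_))
  scale <- s2 / s1
  df <- s1^2 / s2
  list(scale = scale, df = df,
       pvalue = pchisq(statistic / scale, df, lower.tail = FALSE))
}

# Eigenvalues of Omega2^{1/2} Xi Omega2^{1/2} via L' Xi L with the
# Cholesky factor of Omega2 (jittered if needed).
.mixture_eigen <- function(Omega2, Xi) {
  L <- tryCatch(t(chol(Omega2)),
                error = function(e) t(chol(Omega2 + 1e-10 * diag(nrow(Omega2)))))
  eigen(t(L) %*% Xi %*% L, symmetric = TRUE, only.values = TRUE)$values
}

.gof_result <- function(name, stat, df, scale, pvalue, delta = NULL,
                        e2 = NULL, rank_used = NA_integer_, note = NULL) {
  structure(list(name = name, statistic = stat, df = df, scale = scale,
                 pvalue = pvalue, eigenvalues = delta, e2 = e2,
                 rank_used = rank_used, note = note),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("%s: X2 = %.4f, df = %.3f%s, p = %.4g\n", x$name, x$statistic,
              x$df,
              if (!is.na(x$scale) && x$scale != 1)
                sprintf(" (scale %.3f)", x$scale) else "",
              x$pvalue))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Wald test with Moore-Penrose inverse
#'
#' `X2 = n e2' Omega2^+ e2`, the pseudo-inverse truncated to the largest
#' `S - m` eigenvalues, referred to `chi^2_{S-m}`.  A warning note is
#' recorded when the eigenvalue gap between retained and discarded
#' eigenvalues is ambiguous (ratio below 10).
#'
#' @param e2 Residual vector.
#' @param Omega2 Residual covariance.
#' @param n Sample size.
#' @param m Number of free parameters (0 for a simple null).
#' @return A `gof_result`.
#' @export
test_wald <- function(e2, Omega2, n, m) {
  S <- length(e2)
  rank <- S - m
  ed <- eigen(Omega2, symmetric = TRUE)
  note <- NULL
  if (rank < S) {
    gap <- ed$values[rank] / max(abs(ed$values[rank + 1]), 1e-300)
    if (is.finite(gap) && gap < 10)
      note <- sprintf("ambiguous eigenvalue gap (ratio %.2f) at rank S - m",
                      gap)
  }
  keep <- seq_len(rank)
  inv <- ed$vectors[, keep, drop = FALSE] %*%
    (t(ed$vectors[, keep, drop = FALSE]) / ed$values[keep])
  stat <- n * drop(t(e2) %*% inv %*% e2)
  .gof_result("Wald", stat, df = rank, scale = 1,
              pvalue = pchisq(stat, rank, lower.tail = FALSE),
              delta = ed$values, e2 = e2, rank_used = rank, note = note)
}

#' Variance-covariance-free (orthogonal-complement) Wald test
#'
#' `X2 = n e2' D (D' Sigma2 D)^{-1} D' e2` where `D` is an orthonormal
#' basis of the null space of `Delta2'`.  Exactly `chi^2_{S-m}`
#' asymptotically, invariant to the basis choice, and requires no
#' inversion of `Omega2`.
#'
#' @param e2 Residual vector.
#' @param Delta2 Moment Jacobian at the estimate (full column rank `m`).
#' @param Sigma2 Covariance of `sqrt(n)(p2 - pi2)`.
#' @param n Sample size.
#' @return A `gof_result`.
#' @export
test_wald_vcf <- function(e2, Delta2, Sigma2, n) {
  S <- length(e2)
  m <- ncol(Delta2)
  qq <- qr(Delta2)
  if (qq$rank < m) stop("Delta2 is rank deficient")
  D <- qr.Q(qq, complete = TRUE)[, (m + 1):S, drop = FALSE]
  u <- drop(t(D) %*% e2)
  W <- t(D) %*% Sigma2 %*% D
  stat <- n * drop(t(u) %*% solve(W, u))
  .gof_result("WaldVCF", stat, df = S - m, scale = 1,
              pvalue = pchisq(stat, S - m, lower.tail = FALSE), e2 = e2)
}

#' Diagonal Wald, Pearson, RSS, and multinomial quadratic-form tests
#'
#' Quadratic forms `X2 = n e2' Xi e2` with simple weight matrices:
#' `diag(Omega2)^-1` (diagonal Wald), `diag(pi2)^-1` (Pearson; expands to
#' the familiar sum of (obs - exp)^2 / exp over the S margins), the
#' identity (residual sum of squares), and
#' `(diag(pi2) - pi2 pi2')^-1` (multinomial).  Each is referred to a
#' moment-matched scaled chi-square via the eigenvalues of the weighted
#' residual covariance.
#'
#' @param e2 Residual vector.
#' @param Omega2 Residual covariance (for the reference distribution, and
#'   the diagonal Wald weights).
#' @param pi2 Model-implied moment vector (Pearson/multinomial weights).
#' @param n Sample size.
#' @return A `gof_result`.
#' @name quadratic_tests
NULL

#' @rdname quadratic_tests
#' @export
test_wald_diag <- function(e2, Omega2, n) {
  Xi <- diag(1 / diag(Omega2))
  stat <- n * sum(e2^2 / diag(Omega2))
  delta <- .mixture_eigen(Omega2, Xi)
  mm <- moment_match(stat, delta)
  .gof_result("WaldDiag", stat, mm$df, mm$scale, mm$pvalue, delta, e2)
}

#' @rdname quadratic_tests
#' @export
test_pearson <- function(e2, Omega2, pi2, n) {
  stat <- n * sum(e2^2 / pi2)
  delta <- .mixture_eigen(Omega2, diag(1 / pi2))
  mm <- moment_match(stat, delta)
  .gof_result("Pearson", stat, mm$df, mm$scale, mm$pvalue, delta, e2)
}

#' @rdname quadratic_tests
#' @export
test_rss <- function(e2, Omega2, n) {
  stat <- n * sum(e2^2)
  delta <- .mixture_eigen(Omega2, diag(length(e2)))
  mm <- moment_match(stat, delta)
  .gof_result("RSS", stat, mm$df, mm$scale, mm$pvalue, delta, e2)
}

#' @rdname quadratic_tests
#' @export
test_multinomial <- function(e2, Omega2, pi2, n) {
  Xi <- solve(diag(pi2) - tcrossprod(pi2))
  stat <- n * drop(t(e2) %*% Xi %*% e2)
  delta <- .mixture_eigen(Omega2, Xi)
  mm <- moment_match(stat, delta)
  .gof_result("Multinomial", stat, mm$df, mm$scale, mm$pvalue, delta, e2)
}

#' Simple-null limited-information statistic
#'
#' `X2 = n (p2 - pi20)' Sigma20^{-1} (p2 - pi20)` for a fully specified
#' null `pi = pi0`; asymptotically `chi^2_S`.
#'
#' @param p2 Observed moment vector.
#' @param pi20 Hypothesized moment vector.
#' @param Sigma20 Covariance of `sqrt(n)(p2 - pi20)` under the null
#'   (multinomial form for iid sampling, or a design-based estimate).
#' @param n Sample size.
#' @return A `gof_result` with `S` degrees of freedom.
#' @export
simple_null_x2 <- function(p2, pi20, Sigma20, n) {
  e <- p2 - pi20
  stat <- n * drop(t(e) %*% solve(Sigma20, e))
  S <- length(e)
  .gof_result("SimpleNullX2", stat, df = S, scale = 1,
              pvalue = pchisq(stat, S, lower.tail = FALSE), e2 = e)
}

#' Full-pattern Pearson statistic (small-p diagnostic)
#'
#' `X2 = n sum_r (p_r - pi_r)^2 / pi_r` over all `2^p` response patterns,
#' with the nominal df `2^p - p(q+1) - 1` reported informationally.  This
#' is a small-p diagnostic only: its chi-square reference assumes
#' efficient full-information estimates, which pairwise likelihood does
#' not provide.
#'
#' @param data A [survey_dataset()].
#' @inheritParams theta_unpack
#' @return A `gof_result` (p-value omitted).
#' @export
full_pattern_pearson_oracle <- function(data, spec, theta) {
  if (spec$p > 8) stop("full-pattern statistic restricted to p <= 8")
  pr <- pattern_probs(spec, theta)
  key <- as.vector(data$y %*% (2^(spec$p - seq_len(spec$p)))) + 1
  w <- data$w / sum(data$w)
  phat <- numeric(2^spec$p)
  agg <- rowsum(w, key)
  phat[as.integer(rownames(agg))] <- agg
  stat <- data$n * sum((phat - pr)^2 / pr)
  .gof_result("FullPatternPearson", stat,
              df = 2^spec$p - spec$p * (spec$q + 1) - 1,
              scale = NA_real_, pvalue = NA_real_)
}

#' All limited-information fit statistics for a fitted model
#'
#' Computes the residuals, their covariance `Omega2`, and the six
#' quadratic-form statistics (Wald, VCF Wald, diagonal Wald, Pearson, RSS,
#' multinomial).
#'
#' @param fit A [fit_pml()] object with attached data.
#' @param sigma2 `"model"` for the multinomial covariance at the fitted
#'   model (iid sampling), `"multistage"` for the design-based
#'   between-cluster estimator (requires PSU labels).
#' @return List with `results` (data frame), `details` (list of
#'   `gof_result`), `e2`, `Omega2`.
#' @export
gof_tests <- function(fit, sigma2 = c("model", "multistage")) {
  sigma2 <- match.arg(sigma2)
  if (is.null(fit$data)) stop("gof_tests requires the fitted data")
  spec <- fit$spec
  data <- fit$data
  theta <- fit$theta
  e2 <- gof_residuals(data, fit)
  pi2 <- implied_moments(spec, theta)$pi2
  Delta2 <- jacobian_pi2(spec, theta)
  H <- sensitivity_H(spec, theta, fit$table)
  B <- build_B(spec, theta)
  Sigma2 <- if (sigma2 == "model") sigma2_srs_model(spec, theta)
  else data$n * sigma2_multistage(data, pi2)
  Om <- omega2_matrix(Delta2, H, B, Sigma2)
  n <- data$n
  res <- list(
    test_wald(e2, Om, n, spec$m),
    test_wald_vcf(e2, Delta2, Sigma2, n),
    test_wald_diag(e2, Om, n),
    test_pearson(e2, Om, pi2, n),
    test_rss(e2, Om, n),
    test_multinomial(e2, Om, pi2, n)
  )
  names(res) <- vapply(res, `[[`, "", "name")
  tab <- data.frame(
    name = names(res),
    statistic = vapply(res, `[[`, 0, "statistic"),
    df = vapply(res, `[[`, 0, "df"),
    scale = vapply(res, `[[`, 0, "scale"),
    pvalue = vapply(res, `[[`, 0, "pvalue"),
    row.names = NULL
  )
  list(results = tab, details = res, e2 = e2, Omega2 = Om, Sigma2 = Sigma2)
}
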