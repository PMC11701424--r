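# Model-implied moments of the binary items.
#
# First- and second-order moments come straight from univariate and
# bivariate normal probabilities.  Higher-order joint moments and full
# response-pattern probabilities exploit conditional independence of the
# items given the factors: Pr(y = c) integrates the product of item
# Bernoulli probabilities over the factor distribution, evaluated by
# Gauss-Hermite product quadrature (exact up to quadrature error, feasible
# for q <= 3).

# Gauss-Hermite rule for integrals against the standard normal density
# (Golub-Welsch on the probabilists' Hermite recurrence).
gauss_hermite_normal <- function(k) {
  if (k == 1) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(k - 1))
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1), 2:k)] <- off
  J[cbind(2:k, seq_len(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ord])^2)
}

# Product-rule grid over the factor space: eta ~ N_q(0, Psi).
# Returns nodes (n_nodes x q, already transformed by chol(Psi)) + weights.
.factor_grid <- function(Psi, k) {
  q <- nrow(Psi)
  gh <- gauss_hermite_normal(k)
  if (q == 1) {
    return(list(eta = matrix(gh$nodes * sqrt(Psi[1, 1]), ncol = 1),
                w = gh$weights))
  }
  grids <- replicate(q, gh$nodes, simplify = FALSE)
  X <- as.matrix(expand.grid(grids))
  W <- Reduce(function(a, b) as.vector(outer(a, b)),
              replicate(q, gh$weights, simplify = FALSE))
  Lc <- t(chol(Psi))
  list(eta = X %*% t(Lc), w = W)
}

.default_gh_nodes <- function(q) switch(q, 101, 35, 21, 15)

# Item response curves Pr(y_i = 1 | eta) on a factor grid: n_nodes x p.
.item_probs_on_grid <- function(spec, theta, grid) {
  up <- theta_unpack(spec, theta)
  commun <- rowSums((up$Lambda %*% up$Psi) * up$Lambda)
  sds <- sqrt(pmax(1 - commun, 1e-12))
  mu <- grid$eta %*% t(up$Lambda)           # n_nodes x p
  pnorm(sweep(sweep(mu, 2, up$tau, "-"), 2, sds, "/"))
}

#' Model-implied probability of joint positive responses
#'
#' `Pr(y_i = 1 for all i in items)` under the model, by Gauss-Hermite
#' quadrature over the factor distribution.  Handles any subset size, which
#' makes the fourth-order moments needed by the multinomial covariance of
#' sample moments available without 2^p enumeration.
#'
#' @inheritParams theta_unpack
#' @param items Integer vector of item indices (may be empty: returns 1).
#' @param gh_nodes Number of quadrature nodes per factor dimension.
#' @return Probability.
#' @export
joint_moment <- function(spec, theta, items, gh_nodes = NULL) {
  if (length(items) == 0) return(1)
  if (is.null(gh_nodes)) gh_nodes <- .default_gh_nodes(spec$q)
  up <- theta_unpack(spec, theta)
  grid <- .factor_grid(up$Psi, gh_nodes)
  P <- .item_probs_on_grid(spec, theta, grid)
  drop(apply(P[, items, drop = FALSE], 1, prod) %*% grid$w)
}

#' Model-implied moments of the binary items
#'
#' Computes the `p` univariate positive-response probabilities, the
#' `choose(p, 2)` bivariate ones (pairs ordered `(1,2), (1,3), ...,
#' (p-1,p)`), their stacked `S = p(p+1)/2` vector, the implied tetrachoric
#' correlation matrix, and optionally the full `2^p` vector of
#' response-pattern probabilities.
#'
#' @inheritParams theta_unpack
#' @param with_patterns If `TRUE` (and `p <= 15`) also return the pattern
#'   probabilities, indexed with item `p` varying fastest (pattern `r`
#'   encodes the responses as bits).
#' @param gh_nodes Gauss-Hermite nodes per dimension for the pattern
#'   probabilities.
#' @return List with `pidot1`, `pidot2`, `pi2`, `sigma_ystar`, and
#'   optionally `pattern_probs`.
#' @export
implied_moments <- function(spec, theta, with_patterns = FALSE,
                            gh_nodes = NULL) {
  up <- theta_unpack(spec, theta)
  R <- implied_correlations(spec, theta)
  pidot1 <- pnorm(-up$tau)
  rho <- R[spec$pairs]
  pidot2 <- pbvnorm_upper(up$tau[spec$pairs[, 1]],
                          up$tau[spec$pairs[, 2]], rho)
  out <- list(pidot1 = pidot1, pidot2 = pidot2,
              pi2 = c(pidot1, pidot2), sigma_ystar = R)
  if (with_patterns) {
    if (spec$p > 15)
      stop("pattern probabilities refused for p > 15 (2^p patterns)",
           call. = FALSE)
    out$pattern_probs <- pattern_probs(spec, theta, gh_nodes)
  }
  out
}

#' Response-pattern probabilities
#'
#' All `2^p` pattern probabilities under the model, via conditional
#' independence given the factors and Gauss-Hermite quadrature.  Pattern
#' `r` (1-based) encodes responses as the bits of `r - 1` with item `p`
#' varying fastest, i.e. item `i` is 1 in pattern `r` iff bit
#' `p - i` of `r - 1` is set.
#'
#' @inheritParams implied_moments
#' @return Numeric vector of length `2^p` summing to 1.
#' @export
pattern_probs <- function(spec, theta, gh_nodes = NULL) {
  if (is.null(gh_nodes)) gh_nodes <- .default_gh_nodes(spec$q)
  up <- theta_unpack(spec, theta)
  grid <- .factor_grid(up$Psi, gh_nodes)
  P <- .item_probs_on_grid(spec, theta, grid)       # nodes x p
  C <- pattern_matrix(spec$p)                        # R x p of 0/1
  lp <- log(pmax(P, 1e-300)); lq <- log(pmax(1 - P, 1e-300))
  # R x nodes log-probabilities, then integrate
  M <- C %*% t(lp) + (1 - C) %*% t(lq)
  as.vector(exp(M) %*% grid$w)
}

#' Enumerate response patterns
#'
#' @param p Number of items.
#' @return `2^p x p` 0/1 matrix; row `r` is the pattern encoded by the bits
#'   of `r - 1`, item `p` varying fastest.
#' @export
pattern_matrix <- function(p) {
  r <- 0:(2^p - 1)
  sapply(seq_len(p), function(i) bitwAnd(r %/% 2^(p - i), 1L))
}

#' Jacobian of the stacked moment vector
#'
#' `Delta_2 = d pi_2(theta) / d theta'`, an `S x m` matrix with rows
#' ordered as `pi2` (univariate then bivariate moments) and columns as the
#' parameter vector.  Univariate rows involve only the item's threshold;
#' bivariate rows chain the bivariate-normal derivatives through
#' `rho_ij = [Lambda Psi Lambda']_ij`.
#'
#' @inheritParams theta_unpack
#' @return `S x m` Jacobian matrix.
#' @export
jacobian_pi2 <- function(spec, theta) {
  up <- theta_unpack(spec, theta)
  D <- matrix(0, spec$S, spec$m)
  tau_off <- spec$nlam + spec$nrho
  # univariate rows: d Phi(-tau_i)/d tau_i = -phi(tau_i)
  for (i in seq_len(spec$p))
    D[i, tau_off + i] <- -dnorm(up$tau[i])
  rho <- .pair_rho(spec, theta)
  drho <- .drho_dtheta(spec, theta)
  for (pr in seq_len(spec$npairs)) {
    i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
    g <- .pair_cells(up$tau[i], up$tau[j], rho[pr])$grad[4, ]  # cell (1,1)
    row <- spec$p + pr
    D[row, tau_off + i] <- g[1]
    D[row, tau_off + j] <- g[2]
    D[row, ] <- D[row, ] + g[3] * drho[pr, ]
  }
  D
}
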