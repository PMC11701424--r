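# Covariance of the weighted sample moments under SRS and stratified
# multistage sampling.

#' Between-cluster covariance estimator of the sample moments
#'
#' The design-based estimator of `n^{-1} Sigma2`, the covariance of the
#' weighted moment vector `p2`, under stratified multistage sampling:
#' `n^{-1} Sigma2_hat = sum_a n_a/(n_a - 1) sum_b (v_ab - vbar_a)(v_ab -
#' vbar_a)'` with `v_ab = sum_{h in ab} w_h (y2(h) - pi20) / sum_h w_h` and
#' `y2(h)` the S-vector of indicators `[y_i = 1]` and `[y_i = y_j = 1]`.
#' With one stratum, each unit its own PSU, and constant weights it
#' reduces exactly to `(n(n-1))^{-1} T2 (diag(p) - p p') T2'` where `p`
#' holds the sample pattern proportions.
#'
#' @param data A [survey_dataset()] with PSU labels (units lacking them are
#'   treated as their own PSUs in a single stratum).
#' @param pi20 Centering S-vector: hypothesized moments (simple null) or
#'   model-implied moments at the estimate (composite null).
#' @return `S x S` symmetric PSD matrix estimating `n^{-1} Sigma2`;
#'   multiply by `n` for the `Sigma2` scale used by the test statistics.
#' @export
sigma2_multistage <- function(data, pi20) {
  p <- data$p
  pairs <- model_spec(p, 1)$pairs
  y2 <- cbind(data$y, data$y[, pairs[, 1], drop = FALSE] *
                data$y[, pairs[, 2], drop = FALSE])
  stopifnot(length(pi20) == ncol(y2))
  w <- data$w / sum(data$w)
  stratum <- if (is.null(data$stratum)) rep(1L, data$n) else data$stratum
  psu <- if (is.null(data$psu)) seq_len(data$n) else data$psu
  V <- sweep(y2, 2, pi20) * w
  out <- matrix(0, ncol(y2), ncol(y2))
  for (a in unique(stratum)) {
    ida <- stratum == a
    Z <- rowsum(V[ida, , drop = FALSE], group = psu[ida])
    na <- nrow(Z)
    if (na < 2)
      stop(sprintf("stratum '%s' has a single PSU; cannot estimate variance",
                   a))
    Zc <- sweep(Z, 2, colMeans(Z))
    out <- out + na / (na - 1) * crossprod(Zc)
  }
  (out + t(out)) / 2
}

#' Model-based multinomial covariance of the sample moments
#'
#' `Sigma2 = T2 (diag(pi) - pi pi') T2'` evaluated at the model-implied
#' pattern probabilities, computed without materializing the `2^p` pattern
#' space: entry `(A, B)` equals `pi_{A union B} - pi_A pi_B`, a joint
#' positive-response probability of at most four items obtained by
#' Gauss-Hermite quadrature over the factors.
#'
#' @inheritParams theta_unpack
#' @param gh_nodes Quadrature nodes per factor dimension.
#' @return `S x S` covariance matrix of `sqrt(n)(p2 - pi2)` under iid
#'   sampling at the model.
#' @export
sigma2_srs_model <- function(spec, theta, gh_nodes = NULL) {
  if (is.null(gh_nodes)) gh_nodes <- .default_gh_nodes(spec$q)
  up <- theta_unpack(spec, theta)
  grid <- .factor_grid(up$Psi, gh_nodes)
  P <- .item_probs_on_grid(spec, theta, grid)        # nodes x p
  # moment sets as indicator rows: S x p
  Z <- rbind(diag(spec$p),
             (diag(spec$p)[spec$pairs[, 1], , drop = FALSE] +
                diag(spec$p)[spec$pairs[, 2], , drop = FALSE]))
  # all pairwise unions
  S <- nrow(Z)
  pi_set <- as.vector(exp(Z %*% t(log(pmax(P, 1e-300)))) %*% grid$w)
  out <- matrix(0, S, S)
  # union probabilities: iterate over set pairs, caching by union key
  cache <- new.env(hash = TRUE)
  key2 <- function(u) paste(which(u > 0), collapse = ",")
  lp <- t(log(pmax(P, 1e-300)))                      # p x nodes
  for (a in seq_len(S)) {
    for (b in a:S) {
      u <- pmin(Z[a, ] + Z[b, ], 1)
      k <- key2(u)
      piU <- cache[[k]]
      if (is.null(piU)) {
        piU <- drop(exp(u %*% lp) %*% grid$w)
        cache[[k]] <- piU
      }
      out[a, b] <- out[b, a] <- piU - pi_set[a] * pi_set[b]
    }
  }
  out
}
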