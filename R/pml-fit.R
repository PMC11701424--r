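# Weighted pairwise maximum likelihood estimation.
#
# The weighted pairwise log-likelihood is
#   l_P(theta) = sum_{i<j} sum_{ci, cj} p_{ci cj}^{(ij)} log pi_{ci cj}^{(ij)}(theta),
# with p the weighted cell proportions.  The estimator solves the
# estimating equations grad l_P = 0; its asymptotic covariance is the
# Godambe sandwich H^{-1} J H^{-1} / n, with H the sensitivity matrix
# (weighted average negative per-unit Hessian) and J the variability matrix
# estimated either under independence or by the between-cluster estimator
# for stratified multistage designs.

#' Construct a survey data set of binary items
#'
#' @param y `n x p` matrix (or data frame) of 0/1 responses.
#' @param w Optional positive survey weights (default 1).  Weights are
#'   stored as given; estimation normalizes them to sum to `n`.
#' @param stratum Optional stratum labels.
#' @param psu Optional primary-sampling-unit labels (nested in strata),
#'   required for the cluster-robust variability matrix.
#' @return Object of class `"survey_dataset"`.
#' @export
survey_dataset <- function(y, w = NULL, stratum = NULL, psu = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (anyNA(y)) stop("missing responses are not supported")
  if (!all(y %in% c(0L, 1L))) stop("responses must be 0/1")
  n <- nrow(y)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(!is.finite(w)) || any(w < 0))
    stop("weights must be non-negative, finite, and of length nrow(y)")
  if (sum(w) <= 0) stop("weights must not be all zero")
  if (!is.null(stratum)) stopifnot(length(stratum) == n)
  if (!is.null(psu)) stopifnot(length(psu) == n)
  structure(list(y = y, w = as.numeric(w), stratum = stratum, psu = psu,
                 n = n, p = ncol(y)),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("survey_dataset: n = %d units, p = %d binary items\n", x$n, x$p))
  cat(sprintf("  weights: %s; strata: %s; PSUs: %s\n",
              if (all(x$w == x$w[1])) "constant" else "unequal",
              if (is.null(x$stratum)) "none" else
                as.character(length(unique(x$stratum))),
              if (is.null(x$psu)) "none" else
                as.character(length(unique(paste(x$stratum, x$psu))))))
  invisible(x)
}

#' Weighted pairwise contingency table
#'
#' Weighted cell proportions `p_{ci cj}^{(ij)}` for every item pair, cells
#' ordered `(0,0), (0,1), (1,0), (1,1)`.  With unit weights these are the
#' raw cell frequencies divided by `n`.
#'
#' @param data A [survey_dataset()].
#' @param spec Optional [model_spec()]; defaults to the pair layout implied
#'   by `ncol(y)`.
#' @return Object of class `"pairwise_table"`: a `4 x npairs` matrix of
#'   proportions with the pair index attached.
#' @export
make_pairwise_table <- function(data, spec = NULL) {
  y <- data$y
  w <- data$w / sum(data$w)
  p <- ncol(y)
  if (is.null(spec)) spec <- model_spec(p, 1)
  yw <- y * w
  m1 <- colSums(yw)                       # weighted Pr(y_i = 1)
  m11 <- crossprod(y, yw)                 # weighted Pr(y_i = 1, y_j = 1)
  tab <- matrix(0, 4, spec$npairs)
  for (pr in seq_len(spec$npairs)) {
    i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
    p11 <- m11[i, j]
    tab[, pr] <- c(1 - m1[i] - m1[j] + p11, m1[j] - p11, m1[i] - p11, p11)
  }
  structure(list(cells = tab, pairs = spec$pairs, p = p,
                 npairs = spec$npairs),
            class = "pairwise_table")
}

# Internal: evaluate log-likelihood / score / (optionally) Hessian at theta
# given a pairwise table.  Returns list(loglik, score, hessian).
.pml_eval <- function(spec, theta, table, want_score = TRUE,
                      want_hess = FALSE) {
  up <- theta_unpack(spec, theta)
  rho <- .pair_rho(spec, theta)
  drho <- if (want_score || want_hess) .drho_dtheta(spec, theta) else NULL
  tau_off <- spec$nlam + spec$nrho
  ll <- 0
  sc <- if (want_score) numeric(spec$m) else NULL
  He <- if (want_hess) matrix(0, spec$m, spec$m) else NULL
  for (pr in seq_len(spec$npairs)) {
    i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
    pc <- .pair_cells(up$tau[i], up$tau[j], rho[pr], want_hess = want_hess)
    pi_c <- pmax(pc$probs, 1e-300)
    p_c <- table$cells[, pr]
    ll <- ll + sum(p_c * log(pi_c))
    if (want_score || want_hess) {
      ratio <- p_c / pi_c
      gv <- colSums(ratio * pc$grad)          # d l_pair / d(tau_i,tau_j,rho)
      if (want_score) {
        sc[tau_off + i] <- sc[tau_off + i] + gv[1]
        sc[tau_off + j] <- sc[tau_off + j] + gv[2]
        sc <- sc + gv[3] * drho[pr, ]
      }
      if (want_hess) {
        Hin <- matrix(0, 3, 3)
        for (cl in 1:4) {
          cell <- c("00", "01", "10", "11")[cl]
          Hin <- Hin + ratio[cl] * pc$hess[[cell]] -
            (p_c[cl] / pi_c[cl]^2) * tcrossprod(pc$grad[cl, ])
        }
        Jv <- matrix(0, 3, spec$m)
        Jv[1, tau_off + i] <- 1
        Jv[2, tau_off + j] <- 1
        Jv[3, ] <- drho[pr, ]
        He <- He + t(Jv) %*% Hin %*% Jv
        if (abs(gv[3]) > 0 && (spec$nlam > 0 || spec$nrho > 0))
          He <- He + gv[3] * .d2rho_dtheta(spec, theta, pr)
      }
    }
  }
  list(loglik = ll, score = sc, hessian = He)
}

#' Weighted pairwise log-likelihood
#'
#' @inheritParams theta_unpack
#' @param table A [make_pairwise_table()] result (weighted cell
#'   proportions).
#' @return Scalar log-likelihood (per unit of normalized weight).
#' @export
pairwise_loglik <- function(spec, theta, table) {
  .pml_eval(spec, theta, table, want_score = FALSE)$loglik
}

#' Score of the weighted pairwise log-likelihood
#'
#' Analytic gradient of [pairwise_loglik()] with respect to theta.
#'
#' @inheritParams pairwise_loglik
#' @return Numeric vector of length `m`.
#' @export
pml_score <- function(spec, theta, table) {
  .pml_eval(spec, theta, table)$score
}

# Transform between optimization space z and parameter space theta:
# atanh on loadings (single-loading-per-item patterns) and factor
# correlations keeps iterates admissible for the standard patterns.
.make_transform <- function(spec) {
  single <- all(rowSums(spec$loading_pattern) == 1)
  lam_tr <- single
  idx_tanh <- c(if (lam_tr) seq_len(spec$nlam),
                if (spec$nrho > 0) spec$nlam + seq_len(spec$nrho))
  list(
    to_z = function(theta) {
      z <- theta
      z[idx_tanh] <- atanh(pmin(pmax(theta[idx_tanh], -1 + 1e-8), 1 - 1e-8))
      z
    },
    to_theta = function(z) {
      th <- z
      th[idx_tanh] <- tanh(z[idx_tanh])
      th
    },
    jac = function(z) {   # d theta / d z (diagonal)
      jj <- rep(1, length(z))
      jj[idx_tanh] <- 1 - tanh(z[idx_tanh])^2
      jj
    }
  )
}

#' Fit a binary factor model by weighted pairwise maximum likelihood
#'
#' Maximizes the weighted pairwise log-likelihood by quasi-Newton iteration
#' with analytic gradients (factor correlations, and loadings under
#' single-loading patterns, box-transformed through `atanh`), followed by
#' Newton polishing with step halving until the score norm drops below
#' `tol`.  Starting values: thresholds matched to the observed weighted
#' margins, loadings 0.5, factor correlations 0.
#'
#' @param data A [survey_dataset()], or a [make_pairwise_table()] when the
#'   weighted cell proportions are already available (no per-unit
#'   quantities are then possible).
#' @param spec A [model_spec()].
#' @param weighted Use the survey weights?  If `FALSE`, unit weights are
#'   used (the unweighted estimator under informative sampling).
#' @param start Optional starting theta.
#' @param tol Convergence tolerance on `max(abs(score))`.
#' @param max_newton Maximum Newton polishing steps.
#' @return Object of class `"pml_fit"`: `theta` (named), `loglik`,
#'   `score_norm`, `converged`, `iterations`, plus the table, spec, and
#'   (when a data set was supplied) the data with normalized weights.
#' @export
fit_pml <- function(data, spec, weighted = TRUE, start = NULL,
                    tol = 1e-6, max_newton = 50) {
  if (inherits(data, "pairwise_table")) {
    table <- data
    data <- NULL
  } else {
    stopifnot(inherits(data, "survey_dataset"))
    if (!weighted) {
      data <- survey_dataset(data$y, w = NULL, stratum = data$stratum,
                             psu = data$psu)
    }
    table <- make_pairwise_table(data, spec)
  }
  stopifnot(table$p == spec$p)

  if (is.null(start)) {
    # threshold start: Phi(tau) = observed Pr(y = 0)
    prop1 <- numeric(spec$p)
    for (pr in seq_len(spec$npairs)) {
      i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
      prop1[i] <- sum(table$cells[c(3, 4), pr])
      prop1[j] <- sum(table$cells[c(2, 4), pr])
    }
    prop1 <- pmin(pmax(prop1, 1e-4), 1 - 1e-4)
    start <- c(rep(0.5, spec$nlam), rep(0, spec$nrho), qnorm(1 - prop1))
  }
  tr <- .make_transform(spec)
  negll <- function(z) {
    th <- tr$to_theta(z)
    if (!theta_admissible(spec, th)) return(1e10)
    -pairwise_loglik(spec, th, table)
  }
  neggr <- function(z) {
    th <- tr$to_theta(z)
    if (!theta_admissible(spec, th)) return(rep(0, spec$m))
    -pml_score(spec, th, table) * tr$jac(z)
  }
  opt <- stats::optim(tr$to_z(start), negll, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  theta <- tr$to_theta(opt$par)

  # Newton polish on theta with step halving
  iter <- 0
  repeat {
    ev <- .pml_eval(spec, theta, table, want_hess = TRUE)
    sc <- ev$score
    if (max(abs(sc)) < tol || iter >= max_newton) break
    step <- tryCatch(solve(-ev$hessian, sc), error = function(e) sc)
    lam0 <- 1
    repeat {
      cand <- theta + lam0 * step
      if (theta_admissible(spec, cand) &&
          pairwise_loglik(spec, cand, table) >= ev$loglik - 1e-12) break
      lam0 <- lam0 / 2
      if (lam0 < 1e-10) break
    }
    if (lam0 < 1e-10) break
    theta <- theta + lam0 * step
    iter <- iter + 1
  }
  ev <- .pml_eval(spec, theta, table)
  names(theta) <- theta_names(spec)
  structure(list(
    theta = theta, loglik = ev$loglik,
    score_norm = max(abs(ev$score)),
    converged = max(abs(ev$score)) < tol,
    iterations = list(bfgs = opt$counts[["function"]], newton = iter),
    spec = spec, table = table, data = data, weighted = weighted
  ), class = "pml_fit")
}

#' @export
print.pml_fit <- function(x, ...) {
  cat(sprintf("Pairwise ML fit (%s): p = %d, q = %d, m = %d\n",
              if (x$weighted) "weighted" else "unweighted",
              x$spec$p, x$spec$q, x$spec$m))
  cat(sprintf("  loglik = %.6f, max|score| = %.2e, converged: %s\n",
              x$loglik, x$score_norm, x$converged))
  print(round(x$theta, 4))
  invisible(x)
}

#' Sensitivity matrix H
#'
#' The weighted average of the negative per-unit Hessians of the pairwise
#' log-likelihood, which equals the negative Hessian of the pooled
#' weighted pairwise log-likelihood.  Computed analytically from closed
#' forms of the bivariate-normal second derivatives (finite differencing of
#' the analytic score is available as a cross-check).
#'
#' @inheritParams pairwise_loglik
#' @param method `"analytic"` or `"fd"` (central differences of the score).
#' @return Symmetric `m x m` matrix.
#' @export
sensitivity_H <- function(spec, theta, table, method = c("analytic", "fd")) {
  method <- match.arg(method)
  if (method == "analytic") {
    H <- -.pml_eval(spec, theta, table, want_hess = TRUE)$hessian
  } else {
    eps <- 1e-6
    H <- matrix(0, spec$m, spec$m)
    for (k in seq_len(spec$m)) {
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + eps; tm[k] <- tm[k] - eps
      H[, k] <- -(pml_score(spec, tp, table) - pml_score(spec, tm, table)) /
        (2 * eps)
    }
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(abs(ev)))
    warning(sprintf("sensitivity matrix near-singular (min eigenvalue %.3e)",
                    min(ev)))
  H
}

# Per-unit weighted score contributions w_h * u_h(theta) with weights
# normalized to sum to n; rows grouped by response pattern for speed.
.unit_scores <- function(spec, theta, data) {
  y <- data$y
  n <- nrow(y)
  w <- data$w / sum(data$w) * n
  up <- theta_unpack(spec, theta)
  rho <- .pair_rho(spec, theta)
  drho <- .drho_dtheta(spec, theta)
  tau_off <- spec$nlam + spec$nrho
  # d log pi_cell / d theta for all pairs/cells: array [4, npairs, m]
  key <- as.vector(y %*% (2^(seq_len(spec$p) - 1)))
  uk <- unique(key)
  pat <- y[match(uk, key), , drop = FALSE]
  Su <- matrix(0, length(uk), spec$m)
  # cell gradient rows per pair
  for (pr in seq_len(spec$npairs)) {
    i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
    pc <- .pair_cells(up$tau[i], up$tau[j], rho[pr])
    pi_c <- pmax(pc$probs, 1e-300)
    cl <- 1 + pat[, i] * 2 + pat[, j]       # cell index per pattern
    gtau_i <- pc$grad[cl, 1] / pi_c[cl]
    gtau_j <- pc$grad[cl, 2] / pi_c[cl]
    grho <- pc$grad[cl, 3] / pi_c[cl]
    Su[, tau_off + i] <- Su[, tau_off + i] + gtau_i
    Su[, tau_off + j] <- Su[, tau_off + j] + gtau_j
    Su <- Su + outer(grho, drho[pr, ])
  }
  list(scores = Su[match(key, uk), , drop = FALSE] * w, n = n, w = w)
}

#' Variability matrix J under independence
#'
#' `J = (1/n) sum_h (w_h u_h)(w_h u_h)'` with weights normalized to sum to
#' `n` and `u_h` the per-unit pairwise score.
#'
#' @inheritParams theta_unpack
#' @param data A [survey_dataset()].
#' @return Symmetric PSD `m x m` matrix.
#' @export
variability_J_iid <- function(spec, theta, data) {
  us <- .unit_scores(spec, theta, data)
  crossprod(us$scores) / us$n
}

#' Variability matrix J under stratified cluster sampling
#'
#' The between-cluster estimator
#' `J = (1/n) sum_a n_a/(n_a - 1) sum_b (z_ab - zbar_a)(z_ab - zbar_a)'`
#' where `z_ab` is the weighted score total of PSU `b` in stratum `a`.
#'
#' @inheritParams variability_J_iid
#' @return Symmetric PSD `m x m` matrix.
#' @export
variability_J_cluster <- function(spec, theta, data) {
  if (is.null(data$psu)) stop("cluster variability matrix requires PSU labels")
  stratum <- if (is.null(data$stratum)) rep(1L, data$n) else data$stratum
  us <- .unit_scores(spec, theta, data)
  J <- matrix(0, spec$m, spec$m)
  for (a in unique(stratum)) {
    ida <- stratum == a
    psus <- unique(data$psu[ida])
    na <- length(psus)
    if (na < 2)
      stop(sprintf("stratum '%s' has a single PSU; collapse strata before ",
                   a), "estimating the cluster variability matrix")
    Z <- rowsum(us$scores[ida, , drop = FALSE], group = data$psu[ida])
    Zc <- sweep(Z, 2, colMeans(Z))
    J <- J + na / (na - 1) * crossprod(Zc)
  }
  J / us$n
}

#' Godambe sandwich covariance of the pairwise estimator
#'
#' `acov = H^{-1} J H^{-1} / n_eff` with standard errors from its diagonal.
#'
#' @param H Sensitivity matrix.
#' @param J Variability matrix.
#' @param n_eff Effective sample size (the number of units; weights are
#'   normalized to sum to it).
#' @param j_flavor Label recording how J was estimated.
#' @return List with `H`, `J`, `G` (Godambe information), `acov`, `se`.
#' @export
sandwich_parts <- function(H, J, n_eff, j_flavor = c("iid", "cluster")) {
  j_flavor <- match.arg(j_flavor)
  Hi <- solve(H)
  acov <- Hi %*% J %*% Hi / n_eff
  acov <- (acov + t(acov)) / 2
  list(H = H, J = J, G = H %*% solve(J, H), acov = acov,
       se = sqrt(pmax(diag(acov), 0)), j_flavor = j_flavor)
}

#' Sandwich standard errors for a fitted model
#'
#' Convenience wrapper computing H, J (iid or between-cluster), and the
#' Godambe sandwich for a [fit_pml()] result carrying its data.
#'
#' @param fit A `"pml_fit"` object with attached data.
#' @param j_flavor `"iid"` or `"cluster"`.
#' @return See [sandwich_parts()].
#' @export
pml_sandwich <- function(fit, j_flavor = c("iid", "cluster")) {
  j_flavor <- match.arg(j_flavor)
  if (is.null(fit$data))
    stop("sandwich standard errors require per-unit data, not just a table")
  H <- sensitivity_H(fit$spec, fit$theta, fit$table)
  J <- if (j_flavor == "iid")
    variability_J_iid(fit$spec, fit$theta, fit$data)
  else variability_J_cluster(fit$spec, fit$theta, fit$data)
  sandwich_parts(H, J, fit$data$n, j_flavor)
}

#' Population-level pairwise table implied by the model
#'
#' The weighted pairwise table that an infinite sample generated at `theta`
#' would produce; fitting it recovers `theta` exactly (noiseless recovery).
#'
#' @inheritParams theta_unpack
#' @return A `"pairwise_table"`.
#' @export
implied_pairwise_table <- function(spec, theta) {
  im <- implied_moments(spec, theta)
  tab <- matrix(0, 4, spec$npairs)
  for (pr in seq_len(spec$npairs)) {
    i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
    p11 <- im$pidot2[pr]
    tab[, pr] <- c(1 - im$pidot1[i] - im$pidot1[j] + p11,
                   im$pidot1[j] - p11, im$pidot1[i] - p11, p11)
  }
  structure(list(cells = tab, pairs = spec$pairs, p = spec$p,
                 npairs = spec$npairs),
            class = "pairwise_table")
}
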