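# Model specification and parameter-vector bookkeeping for the binary
# factor model.  Items are dichotomizations of latent standard normal
# variables y* = Lambda eta + eps, eta ~ N_q(0, Psi), Theta_eps =
# I - diag(Lambda Psi Lambda'), y_i = 1 iff y*_i > tau_i.  The free
# parameter vector is theta = (lambda, rho, tau), with lambda the free
# loadings in column-major order over the pattern, rho the free
# lower-triangular factor correlations, and tau the p thresholds.

#' Specify a binary factor model
#'
#' @param p Number of binary items (at least 2).
#' @param q Number of latent factors (at least 1).
#' @param loading_pattern Optional `p x q` 0/1 matrix marking free loadings.
#'   Defaults to an all-free single column for `q = 1` and an
#'   independent-clusters pattern with `p/q` items per factor for `q > 1`
#'   (requires `p` divisible by `q`).
#' @param correlated_factors Should the off-diagonal entries of the factor
#'   correlation matrix be free parameters?  Defaults to `TRUE` when
#'   `q > 1`.
#' @return An object of class `"pml_model"` with parameter index tables.
#' @export
model_spec <- function(p, q = 1, loading_pattern = NULL,
                       correlated_factors = q > 1) {
  stopifnot(p >= 2, q >= 1)
  if (is.null(loading_pattern)) {
    if (q == 1) {
      loading_pattern <- matrix(1L, p, 1)
    } else {
      if (p %% q != 0)
        stop("supply `loading_pattern` when p is not a multiple of q")
      loading_pattern <- matrix(0L, p, q)
      per <- p %/% q
      for (f in seq_len(q))
        loading_pattern[((f - 1) * per + 1):(f * per), f] <- 1L
    }
  }
  loading_pattern <- matrix(as.integer(loading_pattern != 0), p, q)
  if (any(rowSums(loading_pattern) < 1))
    stop("every item must load on at least one factor")
  # column-major order over free loadings
  free <- which(loading_pattern == 1L)
  lam_idx <- data.frame(item = ((free - 1) %% p) + 1,
                        factor = ((free - 1) %/% p) + 1)
  nrho <- if (correlated_factors && q > 1) q * (q - 1) / 2 else 0
  rho_idx <- if (nrho > 0) {
    lt <- which(lower.tri(matrix(0, q, q)))
    data.frame(row = ((lt - 1) %% q) + 1, col = ((lt - 1) %/% q) + 1)
  } else {
    data.frame(row = integer(0), col = integer(0))
  }
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  # lexicographic (1,2), (1,3), ..., (p-1,p)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  structure(list(
    p = p, q = q,
    loading_pattern = loading_pattern,
    correlated_factors = correlated_factors && q > 1,
    lam_idx = lam_idx, rho_idx = rho_idx,
    nlam = nrow(lam_idx), nrho = nrho, ntau = p,
    m = nrow(lam_idx) + nrho + p,
    pairs = cbind(i = unname(pairs[, "row"]), j = unname(pairs[, "col"])),
    npairs = p * (p - 1) / 2,
    S = p * (p + 1) / 2
  ), class = "pml_model")
}

#' @export
print.pml_model <- function(x, ...) {
  cat(sprintf("Binary factor model: p = %d items, q = %d factor(s), m = %d free parameters\n",
              x$p, x$q, x$m))
  cat(sprintf("  free loadings: %d; factor correlations: %d; thresholds: %d\n",
              x$nlam, x$nrho, x$ntau))
  invisible(x)
}

#' Names of the free parameters, in vector order
#' @param spec A [model_spec()] object.
#' @return Character vector of length `spec$m`.
#' @export
theta_names <- function(spec) {
  c(sprintf("lambda%d.%d", spec$lam_idx$item, spec$lam_idx$factor),
    if (spec$nrho > 0) sprintf("rho%d.%d", spec$rho_idx$row, spec$rho_idx$col),
    sprintf("tau%d", seq_len(spec$p)))
}

#' Assemble Lambda, Psi, tau from a parameter vector
#' @param spec A [model_spec()] object.
#' @param theta Numeric vector of length `spec$m`.
#' @return List with `Lambda` (`p x q`), `Psi` (`q x q`), `tau` (`p`).
#' @export
theta_unpack <- function(spec, theta) {
  stopifnot(length(theta) == spec$m)
  Lambda <- matrix(0, spec$p, spec$q)
  Lambda[cbind(spec$lam_idx$item, spec$lam_idx$factor)] <-
    theta[seq_len(spec$nlam)]
  Psi <- diag(spec$q)
  if (spec$nrho > 0) {
    rr <- theta[spec$nlam + seq_len(spec$nrho)]
    Psi[cbind(spec$rho_idx$row, spec$rho_idx$col)] <- rr
    Psi[cbind(spec$rho_idx$col, spec$rho_idx$row)] <- rr
  }
  tau <- theta[spec$nlam + spec$nrho + seq_len(spec$p)]
  list(Lambda = Lambda, Psi = Psi, tau = tau)
}

#' Flatten Lambda, Psi, tau into a parameter vector
#' @inheritParams theta_unpack
#' @param Lambda,Psi,tau Model matrices conforming to `spec`.
#' @return Numeric vector of length `spec$m`.
#' @export
theta_pack <- function(spec, Lambda, Psi, tau) {
  c(Lambda[cbind(spec$lam_idx$item, spec$lam_idx$factor)],
    if (spec$nrho > 0) Psi[cbind(spec$rho_idx$row, spec$rho_idx$col)],
    tau)
}

#' Is a parameter vector admissible?
#'
#' Admissibility requires `|rho| < 1` for all factor correlations, a
#' positive-definite factor correlation matrix, and
#' `diag(Lambda Psi Lambda') <= 1 - 1e-8` so that the unique variances stay
#' positive.
#'
#' @inheritParams theta_unpack
#' @return Logical scalar.
#' @export
theta_admissible <- function(spec, theta) {
  if (any(!is.finite(theta))) return(FALSE)
  up <- theta_unpack(spec, theta)
  if (spec$nrho > 0) {
    rr <- theta[spec$nlam + seq_len(spec$nrho)]
    if (any(abs(rr) >= 1)) return(FALSE)
    ev <- eigen(up$Psi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(FALSE)
  }
  commun <- rowSums((up$Lambda %*% up$Psi) * up$Lambda)
  all(commun <= 1 - 1e-8)
}

#' Model-implied correlation matrix of the underlying variables
#'
#' Returns `Lambda Psi Lambda' + Theta_eps`, i.e. `Lambda Psi Lambda'` with
#' its diagonal replaced by 1.  Off-diagonal entry `(i, j)` is the
#' tetrachoric correlation of items `i` and `j`.
#'
#' @inheritParams theta_unpack
#' @return `p x p` correlation matrix.
#' @export
implied_correlations <- function(spec, theta) {
  if (!theta_admissible(spec, theta))
    stop("inadmissible theta: diag(Lambda Psi Lambda') must stay below 1 ",
         "and factor correlations inside (-1, 1)", call. = FALSE)
  up <- theta_unpack(spec, theta)
  R <- up$Lambda %*% up$Psi %*% t(up$Lambda)
  diag(R) <- 1
  R
}

# Tetrachoric correlations for all pairs, in pair order (1,2),(1,3),...
.pair_rho <- function(spec, theta) {
  R <- implied_correlations(spec, theta)
  R[spec$pairs]
}

# Jacobian of the pair correlations rho_ij = lambda_i' Psi lambda_j with
# respect to theta: npairs x m (zero in the tau block).
.drho_dtheta <- function(spec, theta) {
  up <- theta_unpack(spec, theta)
  L <- up$Lambda; Psi <- up$Psi
  D <- matrix(0, spec$npairs, spec$m)
  PL <- L %*% Psi                       # p x q, row i = (Psi lambda_i)'
  for (pr in seq_len(spec$npairs)) {
    i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
    # loadings
    for (k in seq_len(spec$nlam)) {
      it <- spec$lam_idx$item[k]; fa <- spec$lam_idx$factor[k]
      if (it == i) D[pr, k] <- PL[j, fa]
      else if (it == j) D[pr, k] <- PL[i, fa]
    }
    # factor correlations
    if (spec$nrho > 0) {
      for (k in seq_len(spec$nrho)) {
        u <- spec$rho_idx$row[k]; v <- spec$rho_idx$col[k]
        D[pr, spec$nlam + k] <- L[i, u] * L[j, v] + L[i, v] * L[j, u]
      }
    }
  }
  D
}

# Second derivative of rho_ij with respect to theta for one pair: m x m
# sparse structure (rho_ij is bilinear in the loadings and linear in Psi).
.d2rho_dtheta <- function(spec, theta, pr) {
  up <- theta_unpack(spec, theta)
  L <- up$Lambda; Psi <- up$Psi
  i <- spec$pairs[pr, 1]; j <- spec$pairs[pr, 2]
  H <- matrix(0, spec$m, spec$m)
  ki <- which(spec$lam_idx$item == i)
  kj <- which(spec$lam_idx$item == j)
  for (a in ki) for (b in kj) {
    fa <- spec$lam_idx$factor[a]; fb <- spec$lam_idx$factor[b]
    H[a, b] <- H[a, b] + Psi[fa, fb]
    H[b, a] <- H[b, a] + Psi[fa, fb]
  }
  if (spec$nrho > 0) {
    for (k in seq_len(spec$nrho)) {
      u <- spec$rho_idx$row[k]; v <- spec$rho_idx$col[k]
      kk <- spec$nlam + k
      for (a in ki) {
        fa <- spec$lam_idx$factor[a]
        inc <- 0
        if (fa == u) inc <- inc + L[j, v]
        if (fa == v) inc <- inc + L[j, u]
        H[a, kk] <- H[a, kk] + inc
        H[kk, a] <- H[kk, a] + inc
      }
      for (b in kj) {
        fb <- spec$lam_idx$factor[b]
        inc <- 0
        if (fb == u) inc <- inc + L[i, v]
        if (fb == v) inc <- inc + L[i, u]
        H[b, kk] <- H[b, kk] + inc
        H[kk, b] <- H[kk, b] + inc
      }
    }
  }
  H
}

#' Preset model configurations
#'
#' Five standard configurations used throughout the package's simulations:
#' one-factor models with 5, 8, or 15 items (`"1F5V"`, `"1F8V"`, `"1F15V"`)
#' and independent-cluster models with two factors / 10 items (`"2F10V"`)
#' and three factors / 15 items (`"3F15V"`), five items per factor with
#' correlated factors.
#'
#' @param label One of `"1F5V"`, `"1F8V"`, `"1F15V"`, `"2F10V"`, `"3F15V"`,
#'   or the corresponding model number 1-5.
#' @return A [model_spec()] object.
#' @export
preset_model <- function(label) {
  lab <- .preset_label(label)
  switch(lab,
    "1F5V"  = model_spec(5, 1),
    "1F8V"  = model_spec(8, 1),
    "1F15V" = model_spec(15, 1),
    "2F10V" = model_spec(10, 2),
    "3F15V" = model_spec(15, 3))
}

.preset_label <- function(label) {
  labs <- c("1F5V", "1F8V", "1F15V", "2F10V", "3F15V")
  if (is.numeric(label)) {
    stopifnot(label %in% 1:5)
    labs[label]
  } else {
    match.arg(label, labs)
  }
}

#' True generating parameter values for the preset models
#'
#' The base one-factor loadings are `(0.8, 0.7, 0.47, 0.38, 0.34)` with
#' thresholds `(-1.43, -0.55, -0.13, -0.72, -1.13)`.  Larger models recycle
#' these values item by item; the two- and three-factor presets reuse the
#' five base loadings and thresholds per factor, with factor correlations
#' `0.3` (two factors) and `(0.2, 0.3, 0.4)` (three factors).
#'
#' @param label Preset label or number, as in [preset_model()].
#' @return Named numeric vector theta in `(lambda, rho, tau)` order.
#' @export
preset_theta <- function(label) {
  lab <- .preset_label(label)
  lam5 <- c(0.8, 0.7, 0.47, 0.38, 0.34)
  tau5 <- c(-1.43, -0.55, -0.13, -0.72, -1.13)
  spec <- preset_model(lab)
  lam <- rep_len(lam5, spec$p)
  tau <- rep_len(tau5, spec$p)
  rho <- switch(lab,
    "2F10V" = 0.3,
    "3F15V" = c(0.2, 0.3, 0.4),
    numeric(0))
  th <- c(lam, rho, tau)
  names(th) <- theta_names(spec)
  th
}
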