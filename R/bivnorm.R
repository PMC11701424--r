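# Bivariate standard normal probabilities and derivatives.
#
# The upper-orthant probability Pr(X > h, Y > k) for correlated standard
# normal (X, Y) is the workhorse of every pairwise likelihood evaluation, so
# it is computed by Genz's hybrid Gauss-Legendre / singular-expansion
# algorithm (absolute error below 1e-14) rather than by quadrature over the
# density.  All four cell probabilities of a dichotomized pair are assembled
# from this one function and univariate margins so that the cells sum to one
# to machine precision.

# Gauss-Legendre nodes/weights (half rules; used with both signs).
.gl6w <- c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904)
.gl6x <- c(0.9324695142031522, 0.6612093864662647, 0.2386191860831970)
.gl12w <- c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
            0.2031674267230659, 0.2334925365383547, 0.2491470458134029)
.gl12x <- c(0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
            0.5873179542866171, 0.3678314989981802, 0.1252334085114692)
.gl20w <- c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
            0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
            0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
            0.1527533871307259)
.gl20x <- c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
            0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
            0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
            0.07652652113349733)

# Scalar Genz BVND: Pr(X > h, Y > k) with Corr(X, Y) = r.
.bvnd1 <- function(h, k, r) {
  if (abs(r) >= 1) stop("|rho| must be < 1", call. = FALSE)
  twopi <- 2 * pi
  if (abs(r) < 0.3) {
    w <- .gl6w; x <- .gl6x
  } else if (abs(r) < 0.75) {
    w <- .gl12w; x <- .gl12x
  } else {
    w <- .gl20w; x <- .gl20x
  }
  hk <- h * k
  bvn <- 0
  if (abs(r) < 0.925) {
    hs <- (h * h + k * k) / 2
    asr <- asin(r)
    for (i in seq_along(x)) {
      for (is in c(-1, 1)) {
        sn <- sin(asr * (is * x[i] + 1) / 2)
        bvn <- bvn + w[i] * exp((sn * hk - hs) / (1 - sn * sn))
      }
    }
    bvn <- bvn * asr / (2 * twopi) + pnorm(-h) * pnorm(-k)
  } else {
    if (r < 0) {
      k <- -k
      hk <- -hk
    }
    if (abs(r) < 1) {
      as <- (1 - r) * (1 + r)
      a <- sqrt(as)
      bs <- (h - k)^2
      cc <- (4 - hk) / 8
      d <- (12 - hk) / 16
      asq <- -(bs / as + hk) / 2
      if (asq > -100) {
        bvn <- a * exp(asq) *
          (1 - cc * (bs - as) * (1 - d * bs / 5) / 3 + cc * d * as * as / 5)
      }
      if (-hk < 100) {
        b <- sqrt(bs)
        bvn <- bvn - exp(-hk / 2) * sqrt(twopi) * pnorm(-b / a) * b *
          (1 - cc * bs * (1 - d * bs / 5) / 3)
      }
      a <- a / 2
      for (i in seq_along(x)) {
        for (is in c(-1, 1)) {
          xs <- (a * (is * x[i] + 1))^2
          rs <- sqrt(1 - xs)
          asq <- -(bs / xs + hk) / 2
          if (asq > -100) {
            bvn <- bvn + a * w[i] * exp(asq) *
              (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
                 (1 + cc * xs * (1 + d * xs)))
          }
        }
      }
      bvn <- -bvn / twopi
    }
    if (r > 0) {
      bvn <- bvn + pnorm(-max(h, k))
    } else {
      bvn <- -bvn
      if (k > h) bvn <- bvn + pnorm(k) - pnorm(h)
    }
  }
  min(max(bvn, 0), 1)
}

#' Upper-orthant probability of a bivariate standard normal
#'
#' Computes `Pr(X > h, Y > k)` where `(X, Y)` is bivariate standard normal
#' with correlation `rho`, by Genz's hybrid algorithm.  Vectorized over its
#' arguments (recycled to common length).
#'
#' @param h,k Numeric thresholds.
#' @param rho Correlation(s), strictly inside `(-1, 1)`.
#' @return Numeric vector of probabilities.
#' @export
pbvnorm_upper <- function(h, k, rho) {
  nn <- max(length(h), length(k), length(rho))
  h <- rep_len(h, nn); k <- rep_len(k, nn); rho <- rep_len(rho, nn)
  out <- numeric(nn)
  for (i in seq_len(nn)) out[i] <- .bvnd1(h[i], k[i], rho[i])
  out
}

#' Bivariate standard normal density
#'
#' @param a,b Evaluation points.
#' @param rho Correlation, `|rho| < 1`.
#' @return `phi2(a, b; rho)`.
#' @export
dbvnorm <- function(a, b, rho) {
  s2 <- 1 - rho * rho
  exp(-(a * a - 2 * rho * a * b + b * b) / (2 * s2)) / (2 * pi * sqrt(s2))
}

#' Univariate response probability under the threshold link
#'
#' Under the underlying-variable formulation, item `i` equals 1 exactly when
#' its standard normal latent variable exceeds the threshold `tau_i`, so
#' `Pr(y = 1) = pnorm(-tau)` and `Pr(y = 0) = pnorm(tau)`.
#'
#' @param tau Threshold.
#' @param c Observed response, 0 or 1.
#' @return Probability.
#' @export
uni_prob <- function(tau, c) {
  stopifnot(all(c %in% c(0, 1)))
  ifelse(c == 1, pnorm(-tau), pnorm(tau))
}

#' Bivariate cell probability for a pair of binary items
#'
#' Probability that items `i` and `j` take values `ci` and `cj` when their
#' underlying standard normal variables have thresholds `tau_i`, `tau_j` and
#' tetrachoric correlation `rho`.  The four cells of a pair are assembled
#' from the single upper-orthant probability and the univariate margins, so
#' they sum to 1 exactly.
#'
#' @param tau_i,tau_j Thresholds.
#' @param rho Tetrachoric correlation, `|rho| < 1`.
#' @param ci,cj Responses in `{0, 1}`.
#' @return Probability (vectorized over all arguments).
#' @export
biv_prob <- function(tau_i, tau_j, rho, ci, cj) {
  stopifnot(all(ci %in% c(0, 1)), all(cj %in% c(0, 1)))
  p11 <- pbvnorm_upper(tau_i, tau_j, rho)
  p1d <- pnorm(-tau_i)
  pd1 <- pnorm(-tau_j)
  nn <- max(length(p11), length(ci), length(cj))
  p11 <- rep_len(p11, nn); p1d <- rep_len(p1d, nn); pd1 <- rep_len(pd1, nn)
  ci <- rep_len(ci, nn); cj <- rep_len(cj, nn)
  out <- numeric(nn)
  out[ci == 1 & cj == 1] <- p11[ci == 1 & cj == 1]
  idx <- ci == 1 & cj == 0
  out[idx] <- (p1d - p11)[idx]
  idx <- ci == 0 & cj == 1
  out[idx] <- (pd1 - p11)[idx]
  idx <- ci == 0 & cj == 0
  out[idx] <- (1 - p1d - pd1 + p11)[idx]
  out
}

# All four cells of one pair plus their gradients/Hessians with respect to
# the inner variables v = (tau_i, tau_j, rho).  Returned as a list so the
# likelihood code touches Phi2 only once per pair.
#
# Cell order: (0,0), (0,1), (1,0), (1,1).
.pair_cells <- function(tau_i, tau_j, rho, want_hess = FALSE) {
  p11 <- .bvnd1(tau_i, tau_j, rho)
  p1 <- pnorm(-tau_i)
  p2 <- pnorm(-tau_j)
  probs <- c(1 - p1 - p2 + p11, p2 - p11, p1 - p11, p11)

  s <- sqrt(1 - rho * rho)
  phi_i <- dnorm(tau_i)
  phi_j <- dnorm(tau_j)
  phi2v <- dbvnorm(tau_i, tau_j, rho)
  # d p11 / d tau_i = -phi(tau_i) * Phi((rho*tau_i - tau_j)/s), etc.
  dp11 <- c(-phi_i * pnorm((rho * tau_i - tau_j) / s),
            -phi_j * pnorm((rho * tau_j - tau_i) / s),
            phi2v)
  # gradients of the four cells (rows: cells; cols: tau_i, tau_j, rho)
  grad <- rbind(
    c(phi_i + dp11[1], phi_j + dp11[2], dp11[3]),   # (0,0)
    c(-dp11[1], -phi_j - dp11[2], -dp11[3]),        # (0,1)
    c(-phi_i - dp11[1], -dp11[2], -dp11[3]),        # (1,0)
    dp11                                            # (1,1)
  )
  out <- list(probs = probs, grad = grad)
  if (want_hess) {
    # Second derivatives of p11 via Phi2 at (a, b) = (-tau_i, -tau_j).
    a <- -tau_i; b <- -tau_j
    Fa <- phi_i * pnorm((b - rho * a) / s)   # dPhi2/da at (a,b)
    Fb <- phi_j * pnorm((a - rho * b) / s)
    Faa <- -a * Fa - rho * phi2v
    Fbb <- -b * Fb - rho * phi2v
    Fab <- phi2v
    Far <- -phi2v * (a - rho * b) / (s * s)
    Fbr <- -phi2v * (b - rho * a) / (s * s)
    Q <- a * a - 2 * rho * a * b + b * b
    Frr <- phi2v * (rho / (s * s) + (a * b * s * s - rho * Q) / (s^4))
    # p11(tau_i, tau_j, rho) = Phi2(-tau_i, -tau_j; rho): chain signs.
    H11 <- matrix(c(Faa, Fab, -Far,
                    Fab, Fbb, -Fbr,
                    -Far, -Fbr, Frr), 3, 3)
    # margins: d2 Phi(-tau)/dtau2 = tau * phi(tau)
    Mi <- matrix(0, 3, 3); Mi[1, 1] <- tau_i * phi_i
    Mj <- matrix(0, 3, 3); Mj[2, 2] <- tau_j * phi_j
    out$hess <- list(
      `00` = -Mi - Mj + H11,
      `01` = Mj - H11,
      `10` = Mi - H11,
      `11` = H11
    )
  }
  out
}

#' Gradient of a bivariate cell probability
#'
#' Partial derivatives of [biv_prob()] with respect to `tau_i`, `tau_j`, and
#' `rho`, using the closed forms for the derivatives of the bivariate normal
#' CDF.  The gradients of the four cells of a pair sum to zero.
#'
#' @inheritParams biv_prob
#' @return Numeric length-3 vector `(d/dtau_i, d/dtau_j, d/drho)`.
#' @export
d_biv_prob <- function(tau_i, tau_j, rho, ci, cj) {
  stopifnot(length(tau_i) == 1, ci %in% c(0, 1), cj %in% c(0, 1))
  pc <- .pair_cells(tau_i, tau_j, rho)
  pc$grad[1 + ci * 2 + cj, ]
}
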