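# Shared fixtures: everything is generated in code at test time.

# A random admissible parameter vector for a spec, jittered around
# moderate values (loadings well inside the unit ball).
random_theta <- function(spec, sd = 0.15) {
  lam <- pmin(pmax(runif(spec$nlam, 0.2, 0.8) + rnorm(spec$nlam, 0, sd / 3),
                   -0.95), 0.95)
  rho <- if (spec$nrho > 0) runif(spec$nrho, -0.3, 0.3) else numeric(0)
  tau <- rnorm(spec$p, 0, 0.8)
  th <- c(lam, rho, tau)
  stopifnot(theta_admissible(spec, th))
  th
}

# Small iid data set from the model.
sim_dataset <- function(spec, theta, n) {
  survey_dataset(generate_factor_data(spec, theta, n)$y)
}

# Finite-difference gradient of a scalar function.
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + eps; xm[k] <- xm[k] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}

# Scaled-down school population for structural tests.
small_school_pop <- function(spec, theta, misspec = FALSE) {
  generate_school_population(
    spec, theta,
    n_schools = c(A = 40, B = 100, C = 60),
    size_mean = 120, size_sd = 30,
    misspec = misspec)
}
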