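# Synthetic populations and survey samplers.
#
# Three sampling worlds are emulated: (A) informative selection from a flat
# factor-model population with inclusion probability 1/(1 + exp(y1*)); and
# a school population of ~2000 schools in three ability-stratified types
# (A: 400 schools / classes averaging 15 students, B: 1000 / 25, C: 600 /
# 20, school sizes Normal(500, 125) rounded) sampled by (B) two-stage
# probability-proportional-to-size cluster sampling and (C) stratified
# cluster sampling.

#' Generate data from the binary factor model
#'
#' Draws `N` independent units: `eta ~ N_q(0, Psi)`,
#' `y* = Lambda eta + eps`, `eps ~ N(0, I - diag(Lambda Psi Lambda'))`,
#' `y_i = [y*_i > tau_i]`.  With `misspec = TRUE` an extra latent variable
#' `z ~ N(0, 1)`, independent of `eta`, loads on a subset of items with
#' loadings equal to the item's factor loading; each affected `y*` is then
#' standardized back to unit variance, so the fitted factor model is
#' misspecified (power scenario).
#'
#' @inheritParams theta_unpack
#' @param N Number of units.
#' @param misspec Add the misspecification variable `z`?
#' @param z_items Items `z` loads on.  Default: all items except items 2,
#'   6, and 14 (where present) for one-factor models, and all items for
#'   multi-factor models.
#' @return List with `y` (`N x p` 0/1 matrix), `y1star` (first underlying
#'   variable, used by informative selection), and `eta` (`N x q`).
#' @export
generate_factor_data <- function(spec, theta, N, misspec = FALSE,
                                 z_items = NULL) {
  if (!theta_admissible(spec, theta)) stop("inadmissible theta")
  up <- theta_unpack(spec, theta)
  commun <- rowSums((up$Lambda %*% up$Psi) * up$Lambda)
  eta <- matrix(rnorm(N * spec$q), N, spec$q) %*% chol(up$Psi)
  eps <- matrix(rnorm(N * spec$p), N, spec$p) %*% diag(sqrt(1 - commun),
                                                       spec$p)
  ystar <- eta %*% t(up$Lambda) + eps
  if (misspec) {
    if (is.null(z_items)) {
      z_items <- if (spec$q == 1) setdiff(seq_len(spec$p), c(2, 6, 14))
      else seq_len(spec$p)
    }
    lam_z <- numeric(spec$p)
    first_load <- vapply(seq_len(spec$p), function(i)
      up$Lambda[i, which(spec$loading_pattern[i, ] == 1)[1]], 0)
    lam_z[z_items] <- first_load[z_items]
    z <- rnorm(N)
    ystar <- ystar + tcrossprod(z, lam_z)
    ystar <- sweep(ystar, 2, sqrt(1 + lam_z^2), "/")
  }
  y <- matrix(as.integer(sweep(ystar, 2, up$tau, ">")), N, spec$p)
  list(y = y, y1star = ystar[, 1], eta = eta)
}

# Fixed-size systematic probability-proportional-to-size draw on a
# randomized order; prob must sum to the (integer) sample size.
.systematic_pps <- function(prob) {
  ord <- sample.int(length(prob))
  cp <- cumsum(prob[ord])
  k <- round(cp[length(cp)])
  hits <- findInterval(runif(1) + seq_len(k) - 1, c(0, cp))
  sort(ord[hits])
}

#' Informative sample from a flat population
#'
#' Each unit gets selection propensity `pi_h = 1 / (1 + exp(y1*_h))`
#' (larger first underlying variable, smaller selection chance), rescaled
#' to inclusion probabilities summing to `n`, and a fixed-size systematic
#' unequal-probability sample is drawn.  Weights are the reciprocal
#' inclusion probabilities, making the design informative for the first
#' item's threshold in particular.
#'
#' @param pop Result of [generate_factor_data()].
#' @param n Target sample size.
#' @return A [survey_dataset()] with weights.
#' @export
informative_sample <- function(pop, n) {
  prop <- 1 / (1 + exp(pop$y1star))
  pr_inc <- n * prop / sum(prop)
  if (any(pr_inc >= 1)) pr_inc <- pmin(pr_inc, 1 - 1e-12)
  idx <- .systematic_pps(pr_inc)
  survey_dataset(pop$y[idx, , drop = FALSE], w = 1 / pr_inc[idx])
}

#' Generate the clustered school population
#'
#' Builds the ability-stratified school population: schools of three types
#' with rounded Normal school sizes; all students' factor data generated
#' from the model; students ranked by their first factor score and
#' allocated to type A (highest), then B, then C; within a school students
#' are assigned uniformly at random to `max(1, round(size / avg_class))`
#' classes.
#'
#' @inheritParams theta_unpack
#' @param n_schools Named integer vector of schools per type
#'   (default `c(A = 400, B = 1000, C = 600)`).
#' @param size_mean,size_sd School-size distribution (default 500, 125).
#' @param class_size Named average class sizes per type
#'   (default `c(A = 15, B = 25, C = 20)`).
#' @param misspec Generate item responses from the misspecified (power)
#'   model?  See [generate_factor_data()].
#' @return List with `y`, `eta1`, `school`, `class`, `type` (per student)
#'   and a `schools` data frame (`school`, `type`, `size`, `n_classes`).
#' @export
generate_school_population <- function(spec, theta,
                                       n_schools = c(A = 400, B = 1000,
                                                     C = 600),
                                       size_mean = 500, size_sd = 125,
                                       class_size = c(A = 15, B = 25,
                                                      C = 20),
                                       misspec = FALSE) {
  types <- rep(names(n_schools), n_schools)
  nsch <- length(types)
  sizes <- pmax(round(rnorm(nsch, size_mean, size_sd)), 2L)
  N <- sum(sizes)
  pop <- generate_factor_data(spec, theta, N, misspec = misspec)
  ord <- order(pop$eta[, 1], decreasing = TRUE)
  # seats for type A go to the highest-ability students, then B, then C
  school <- integer(N)
  pos <- 1
  for (ty in names(n_schools)) {
    sch_ids <- which(types == ty)
    block <- ord[pos:(pos + sum(sizes[sch_ids]) - 1)]
    block <- sample(block)                 # shuffle within the type
    school[block] <- rep(sch_ids, sizes[sch_ids])
    pos <- pos + sum(sizes[sch_ids])
  }
  n_classes <- pmax(1L, as.integer(round(sizes / class_size[types])))
  cls <- integer(N)
  for (b in seq_len(nsch)) {
    members <- which(school == b)
    cls[members] <- sample.int(n_classes[b], length(members),
                               replace = TRUE)
  }
  list(y = pop$y, eta1 = pop$eta[, 1], school = school, class = cls,
       type = types[school],
       schools = data.frame(school = seq_len(nsch), type = types,
                            size = sizes, n_classes = n_classes))
}

#' Number of PSUs drawn by each complex design
#'
#' Two-stage cluster sampling selects `floor(n / 21.5)` schools (21.5 is
#' the population-average class size); stratified cluster sampling selects
#' `floor(n / (15 + 20 + 25))` schools per stratum (three strata).
#'
#' @param n Target sample size.
#' @return Integer PSU count (total across strata for the stratified
#'   design).
#' @export
n_psus_cluster <- function(n) as.integer(floor(n / 21.5))

#' @rdname n_psus_cluster
#' @export
n_psus_stratified <- function(n) 3L * as.integer(floor(n / 60))

#' Two-stage cluster sample from the school population
#'
#' Selects `floor(n / 21.5)` schools by systematic PPS on school size, one
#' class by SRS within each selected school, and all students of that
#' class.  Student weights are the reciprocal of
#' `size_b / total_students * 1 / n_classes_b`.
#'
#' @param pop A [generate_school_population()] result.
#' @param n Target sample size.
#' @return A [survey_dataset()] with a single stratum and school PSUs.
#' @export
sample_two_stage_cluster <- function(pop, n) {
  nc <- n_psus_cluster(n)
  sch <- pop$schools
  pr <- nc * sch$size / sum(sch$size)
  sel <- .systematic_pps(pr)
  rows <- integer(0)
  wts <- numeric(0)
  for (b in sel) {
    cl <- sample.int(sch$n_classes[b], 1)
    members <- which(pop$school == b & pop$class == cl)
    rows <- c(rows, members)
    wts <- c(wts, rep(sum(sch$size) * sch$n_classes[b] / sch$size[b],
                      length(members)))
  }
  survey_dataset(pop$y[rows, , drop = FALSE], w = wts,
                 stratum = rep(1L, length(rows)),
                 psu = pop$school[rows])
}

#' Stratified cluster sample from the school population
#'
#' Selects `floor(n / 60)` schools per stratum (school type) by SRS, one
#' class by SRS within each school, and all its students.  Student weights
#' are the reciprocal of `n_a / N_a * 1 / n_classes_b` (all students of a
#' selected class are taken).
#'
#' @inheritParams sample_two_stage_cluster
#' @return A [survey_dataset()] with school-type strata and school PSUs.
#' @export
sample_stratified_cluster <- function(pop, n) {
  nc <- as.integer(floor(n / 60))
  sch <- pop$schools
  rows <- integer(0)
  wts <- numeric(0)
  for (ty in unique(sch$type)) {
    ids <- sch$school[sch$type == ty]
    sel <- sample(ids, nc)
    for (b in sel) {
      cl <- sample.int(sch$n_classes[b], 1)
      members <- which(pop$school == b & pop$class == cl)
      rows <- c(rows, members)
      wts <- c(wts, rep(length(ids) / nc * sch$n_classes[b],
                        length(members)))
    }
  }
  survey_dataset(pop$y[rows, , drop = FALSE], w = wts,
                 stratum = pop$type[rows], psu = pop$school[rows])
}

#' Replicated simulation studies
#'
#' Runs the package's estimation and fit-testing pipeline over repeated
#' samples from one of the synthetic designs and summarizes bias,
#' coverage, SD/SE ratios (informative design) or test rejection rates
#' (SRS and the complex designs).
#'
#' @param design `"informative"`, `"srs"`, `"two_stage_cluster"`, or
#'   `"stratified_cluster"`.
#' @param model Preset model label or number (see [preset_model()]).
#' @param n Sample size per replication.
#' @param reps Number of replications.
#' @param seed RNG seed (set once at entry).
#' @param misspec Generate from the misspecified (power) model?
#' @param pop_ratio Population-to-sample ratio for the informative design
#'   (default 100, i.e. n/N = 1%).
#' @param alpha Significance levels for rejection-rate summaries.
#' @param sigma2 Covariance estimator passed to [gof_tests()] for the SRS
#'   design ("model") and the complex designs ("multistage").
#' @return A list of per-replication results and summary tables; see the
#'   `summary` element.
#' @export
replicate_study <- function(design = c("informative", "srs",
                                       "two_stage_cluster",
                                       "stratified_cluster"),
                            model = 1, n = 500, reps = 100, seed = 1,
                            misspec = FALSE, pop_ratio = 100,
                            alpha = c(0.10, 0.05, 0.01),
                            sigma2 = NULL) {
  design <- match.arg(design)
  set.seed(seed)
  spec <- preset_model(model)
  theta0 <- preset_theta(model)
  if (design == "informative")
    return(.sim_informative(spec, theta0, n, reps, pop_ratio))
  if (is.null(sigma2))
    sigma2 <- if (design == "srs") "model" else "multistage"
  .sim_gof(spec, theta0, design, n, reps, misspec, alpha, sigma2)
}

# Simulation A: bias / coverage / SD-SE for unweighted and weighted
# estimation under informative selection.
.sim_informative <- function(spec, theta0, n, reps, pop_ratio) {
  m <- spec$m
  est <- array(NA_real_, c(reps, m, 2),
               dimnames = list(NULL, theta_names(spec), c("PML", "PMLW")))
  ses <- est
  for (r in seq_len(reps)) {
    pop <- generate_factor_data(spec, theta0, n * pop_ratio)
    samp <- informative_sample(pop, n)
    for (k in 1:2) {
      fit <- fit_pml(samp, spec, weighted = (k == 2))
      sw <- tryCatch(pml_sandwich(fit, "iid"), error = function(e) NULL)
      est[r, , k] <- fit$theta
      if (!is.null(sw)) ses[r, , k] <- sw$se
    }
  }
  summ <- lapply(1:2, function(k) {
    bias <- colMeans(est[, , k]) - theta0
    sd_emp <- apply(est[, , k], 2, sd)
    # dispersion about the TRUE value; for a biased estimator this is what
    # the conventional "SD over SE" diagnostic in the survey literature
    # reports (it equals the plain SD when the bias vanishes)
    rmse <- sqrt(colMeans(sweep(est[, , k], 2, theta0)^2))
    se_avg <- colMeans(ses[, , k], na.rm = TRUE)
    lo <- est[, , k] - 1.96 * ses[, , k]
    hi <- est[, , k] + 1.96 * ses[, , k]
    cover <- colMeans(sweep(lo, 2, theta0, "<=") &
                        sweep(hi, 2, theta0, ">="), na.rm = TRUE)
    data.frame(parameter = theta_names(spec), true = unname(theta0),
               bias = unname(bias), sd = unname(sd_emp),
               rmse = unname(rmse), mean_se = unname(se_avg),
               sd_se_ratio = unname(rmse / se_avg),
               coverage = unname(cover))
  })
  names(summ) <- c("PML", "PMLW")
  list(estimates = est, ses = ses, summary = summ)
}

# Simulations B/C: GOF rejection rates under SRS or a complex design.
.sim_gof <- function(spec, theta0, design, n, reps, misspec, alpha,
                     sigma2) {
  pvals <- NULL
  school_pop <- NULL
  if (design != "srs")
    school_pop <- generate_school_population(spec, theta0,
                                             misspec = misspec)
  for (r in seq_len(reps)) {
    data <- switch(design,
      srs = survey_dataset(generate_factor_data(spec, theta0, n,
                                                misspec = misspec)$y),
      two_stage_cluster = sample_two_stage_cluster(school_pop, n),
      stratified_cluster = sample_stratified_cluster(school_pop, n))
    row <- tryCatch({
      fit <- fit_pml(data, spec, weighted = TRUE)
      gg <- gof_tests(fit, sigma2 = sigma2)
      stats::setNames(gg$results$pvalue, gg$results$name)
    }, error = function(e) NULL)
    if (!is.null(row)) pvals <- rbind(pvals, row)
  }
  rej <- sapply(alpha, function(a) colMeans(pvals < a, na.rm = TRUE))
  colnames(rej) <- paste0("alpha_", alpha)
  list(pvalues = as.data.frame(pvals),
       summary = list(rejection = as.data.frame(rej),
                      n_effective = nrow(pvals)))
}
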