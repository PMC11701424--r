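# Synthetic populations and samplers.

test_that("factor data reproduces margins and pair moments", {
  set.seed(23)
  spec <- preset_model(1)
  th0 <- preset_theta(1)
  N <- 1e5
  pop <- generate_factor_data(spec, th0, N)
  tau <- theta_unpack(spec, th0)$tau
  mse <- sqrt(pnorm(-tau) * pnorm(tau) / N)
  expect_true(all(abs(colMeans(pop$y) - pnorm(-tau)) < 3 * mse))
  # implied (1,2) joint positive probability at rho = .56
  p11 <- biv_prob(tau[1], tau[2], 0.56, 1, 1)
  expect_lt(abs(mean(pop$y[, 1] * pop$y[, 2]) - p11),
            3 * sqrt(p11 * (1 - p11) / N))
})

test_that("misspecified generator keeps unit variances, spares items 2/6/14", {
  set.seed(24)
  spec <- preset_model(2)
  th0 <- preset_theta(2)
  N <- 2e5
  popm <- generate_factor_data(spec, th0, N, misspec = TRUE)
  tau <- theta_unpack(spec, th0)$tau
  mse <- sqrt(pnorm(-tau) * pnorm(tau) / N)
  # margins unchanged: y* is standardized back to unit variance
  expect_true(all(abs(colMeans(popm$y) - pnorm(-tau)) < 4 * mse))
  # the (2,6) pair excludes z, so its joint moment matches the null model
  p26 <- biv_prob(tau[2], tau[6], 0.7 * 0.7, 1, 1)
  expect_lt(abs(mean(popm$y[, 2] * popm$y[, 6]) - p26), 4 * sqrt(p26 / N))
  # a z-loaded pair matches the misspecified (not the null) tetrachoric:
  # rho = 2 * l1 * l3 / sqrt((1 + l1^2)(1 + l3^2))
  rho_mis <- 2 * 0.8 * 0.47 / sqrt((1 + 0.8^2) * (1 + 0.47^2))
  p13_mis <- biv_prob(tau[1], tau[3], rho_mis, 1, 1)
  p13_null <- biv_prob(tau[1], tau[3], 0.8 * 0.47, 1, 1)
  se13 <- sqrt(p13_mis * (1 - p13_mis) / N)
  expect_lt(abs(mean(popm$y[, 1] * popm$y[, 3]) - p13_mis), 4 * se13)
  expect_gt(mean(popm$y[, 1] * popm$y[, 3]), p13_null + 3 * se13)
})

test_that("informative selection: propensity, weights, and HT unbiasedness", {
  expect_equal(1 / (1 + exp(0)), 0.5)   # unit at y1* = 0, before scaling
  set.seed(25)
  spec <- preset_model(1)
  th0 <- preset_theta(1)
  pop <- generate_factor_data(spec, th0, 50000)
  samp <- informative_sample(pop, 500)
  expect_true(all(is.finite(samp$w) & samp$w > 0))
  expect_equal(samp$n, 500)
  # selection favours low y1*: unweighted item-1 mean is biased down,
  # weighted (Horvitz-Thompson) means are unbiased for population means
  reps <- 200
  wm <- um <- matrix(NA_real_, reps, spec$p)
  for (r in seq_len(reps)) {
    s <- informative_sample(pop, 500)
    wm[r, ] <- colSums(s$y * s$w) / sum(s$w)
    um[r, ] <- colMeans(s$y)
  }
  popmean <- colMeans(pop$y)
  mcse <- apply(wm, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(wm) - popmean) < 4 * mcse))
  expect_lt(colMeans(um)[1], popmean[1] - 0.05)
})

test_that("school population has the stated structure", {
  set.seed(26)
  spec <- preset_model(1)
  pop <- small_school_pop(spec, preset_theta(1))
  expect_equal(as.integer(table(pop$schools$type)[c("A", "B", "C")]),
               c(40L, 100L, 60L))
  expect_equal(nrow(pop$y), sum(pop$schools$size))
  # classes partition each school
  expect_true(all(pop$class >= 1 &
                    pop$class <= pop$schools$n_classes[pop$school]))
  # ability ordering: A above B above C on the first factor
  mu <- tapply(pop$eta1, pop$type, mean)
  expect_gt(mu[["A"]], mu[["B"]])
  expect_gt(mu[["B"]], mu[["C"]])
  # between-school intraclass correlation within the stated envelope
  icc <- vapply(seq_len(spec$p), function(i) {
    m <- tapply(pop$y[, i], pop$school, mean)
    nb <- tabulate(pop$school)
    msb <- sum(nb * (m[order(as.integer(names(m)))] -
                       mean(pop$y[, i]))^2) / (length(m) - 1)
    msw <- sum((pop$y[, i] - m[as.character(pop$school)])^2) /
      (nrow(pop$y) - length(m))
    n0 <- mean(nb)
    (msb - msw) / (msb + (n0 - 1) * msw)
  }, 0)
  expect_true(all(icc > 0.02 & icc < 0.6))
  expect_gt(max(icc), 0.05)
})

test_that("PSU counts follow the design arithmetic", {
  expect_equal(n_psus_cluster(500), 23L)
  expect_equal(n_psus_cluster(1000), 46L)
  expect_equal(n_psus_cluster(2500), 116L)
  expect_equal(n_psus_stratified(500), 24L)
})

test_that("complex samplers deliver labelled, weighted samples", {
  set.seed(27)
  spec <- preset_model(1)
  pop <- small_school_pop(spec, preset_theta(1))
  s1 <- sample_two_stage_cluster(pop, 500)
  expect_equal(length(unique(s1$psu)), n_psus_cluster(500))
  expect_lt(abs(s1$n - 500) / 500, 0.3)
  # weight formula: total / size * n_classes for the student's school
  b <- s1$psu[1]
  expect_equal(s1$w[1],
               sum(pop$schools$size) * pop$schools$n_classes[b] /
                 pop$schools$size[b])
  s2 <- sample_stratified_cluster(pop, 500)
  expect_equal(length(unique(s2$psu)), 24)
  expect_equal(sort(unique(s2$stratum)), c("A", "B", "C"))
  # stratified-cluster weighted means unbiased for population means
  reps <- 120
  wm <- matrix(NA_real_, reps, spec$p)
  for (r in seq_len(reps)) {
    s <- sample_stratified_cluster(pop, 500)
    wm[r, ] <- colSums(s$y * s$w) / sum(s$w)
  }
  popmean <- colMeans(pop$y)
  mcse <- apply(wm, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(wm) - popmean) < 4 * mcse))
})

test_that("replicate_study is reproducible and summarizes correctly", {
  r1 <- replicate_study("informative", model = 1, n = 300, reps = 3,
                        seed = 99)
  r2 <- replicate_study("informative", model = 1, n = 300, reps = 3,
                        seed = 99)
  expect_identical(r1$estimates, r2$estimates)
  expect_named(r1$summary, c("PML", "PMLW"))
  expect_equal(nrow(r1$summary$PML), preset_model(1)$m)
})
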