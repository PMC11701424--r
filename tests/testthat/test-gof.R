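# Limited-information goodness-of-fit statistics.

test_that("T2 maps pattern probabilities to moments", {
  T2 <- build_T2(2)
  # columns: patterns 00, 01, 10, 11; rows: pi1., pi.1, pi11
  expect_equal(T2, rbind(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 0, 0, 1)))
  T5 <- build_T2(5)
  expect_equal(rowSums(T5)[1:5], rep(2^4, 5))
  expect_equal(rowSums(T5)[6:15], rep(2^3, 10))
  expect_equal(qr(T5)$rank, 15)
  # any probability vector maps to valid moments
  set.seed(10)
  pr <- runif(32); pr <- pr / sum(pr)
  m <- drop(T5 %*% pr)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("sample moments equal T2 applied to pattern proportions", {
  set.seed(11)
  y <- matrix(rbinom(60, 1, 0.4), 20, 3)
  d <- survey_dataset(y, w = runif(20, 0.5, 2))
  p2 <- sample_moments(d)
  key <- y %*% c(4, 2, 1) + 1
  w <- d$w / sum(d$w)
  phat <- numeric(8)
  for (h in 1:20) phat[key[h]] <- phat[key[h]] + w[h]
  expect_equal(p2, drop(build_T2(3) %*% phat), tolerance = 1e-12)
  expect_equal(sample_moments(survey_dataset(matrix(1L, 5, 3))),
               rep(1, 6))
})

test_that("score identity: grad l_P = B(theta) (p2 - pi2)", {
  set.seed(12)
  for (model in c(1, 4)) {
    spec <- preset_model(model)
    th0 <- preset_theta(model)
    for (rep in 1:5) {
      d <- sim_dataset(spec, th0, 100)
      tab <- make_pairwise_table(d, spec)
      th <- random_theta(spec)
      lhs <- pml_score(spec, th, tab)
      rhs <- drop(build_B(spec, th) %*%
                    (sample_moments(d) - implied_moments(spec, th)$pi2))
      expect_lt(max(abs(lhs - rhs)), 1e-8)
    }
  }
})

test_that("Omega2 reduces to Sigma2 without estimation and is PSD at fits", {
  spec <- preset_model(1)
  th0 <- preset_theta(1)
  S2 <- sigma2_srs_model(spec, th0)
  O <- omega2_matrix(matrix(0, spec$S, spec$m), diag(spec$m),
                     matrix(0, spec$m, spec$S), S2)
  expect_equal(O, S2)

  set.seed(13)
  fit <- fit_pml(sim_dataset(spec, th0, 1000), spec)
  gg <- gof_tests(fit)
  ev <- eigen(gg$Omega2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # sqrt(n) e2 covariance has rank between S - m and S
  expect_lte(sum(ev > 1e-8 * max(ev)), spec$S)
  expect_gte(sum(ev > 1e-8 * max(ev)), spec$S - spec$m)
})

test_that("Wald statistic hand cases and simple-null equivalence", {
  r <- test_wald(c(0.1, 0), diag(c(0.01, 0.02)), n = 100, m = 0)
  expect_equal(r$statistic, 100)
  expect_equal(r$df, 2)
  r0 <- test_wald(c(0, 0), diag(c(0.01, 0.02)), n = 100, m = 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$pvalue, 1)
  # with m = 0 and full-rank Omega2 the Wald equals the simple-null form
  set.seed(14)
  e2 <- rnorm(4) / 10
  O <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  expect_equal(test_wald(e2, O, 50, 0)$statistic,
               simple_null_x2(e2, rep(0, 4), O, 50)$statistic,
               tolerance = 1e-10)
})

test_that("VCF Wald is basis- and reparameterization-invariant", {
  set.seed(15)
  spec <- preset_model(1)
  fit <- fit_pml(sim_dataset(spec, preset_theta(1), 800), spec)
  d <- fit$data
  e2 <- gof_residuals(d, fit)
  D2 <- jacobian_pi2(spec, fit$theta)
  S2 <- sigma2_srs_model(spec, fit$theta)
  x <- test_wald_vcf(e2, D2, S2, d$n)
  expect_equal(x$df, spec$S - spec$m)
  # nonsingular reparameterization of theta leaves the statistic unchanged
  A <- matrix(rnorm(spec$m^2), spec$m) + diag(spec$m) * 3
  x2 <- test_wald_vcf(e2, D2 %*% A, S2, d$n)
  expect_equal(x$statistic, x2$statistic, tolerance = 1e-8)
})

test_that("simple quadratic forms match hand computation", {
  e2 <- c(0.1, -0.1, 0, 0)
  O <- diag(4) * 0.05
  expect_equal(test_rss(e2, O, 100)$statistic, 2)
  set.seed(16)
  # Pearson expands to sum (obs - exp)^2 / exp over the S margins
  spec2 <- model_spec(2, 1)
  d <- sim_dataset(spec2, c(0.7, 0.5, 0.2, -0.3), 500)
  fit <- fit_pml(d, spec2)
  pi2 <- implied_moments(spec2, fit$theta)$pi2
  p2 <- sample_moments(d)
  pe <- test_pearson(p2 - pi2, diag(3) * 0.1, pi2, d$n)
  expect_equal(pe$statistic, d$n * sum((p2 - pi2)^2 / pi2))
  # multinomial weights vs brute-force quadratic form, p = 3
  spec3 <- model_spec(3, 1)
  th3 <- c(0.6, 0.5, 0.4, -0.2, 0.1, 0.4)
  pi23 <- implied_moments(spec3, th3)$pi2
  e23 <- rnorm(6) / 20
  Xi <- solve(diag(pi23) - tcrossprod(pi23))
  expect_equal(test_multinomial(e23, diag(6) * 0.1, pi23, 200)$statistic,
               200 * drop(t(e23) %*% Xi %*% e23), tolerance = 1e-10)
})

test_that("moment matching reproduces closed cases and MC tail mass", {
  mm <- moment_match(5, rep(1, 8))
  expect_equal(mm$scale, 1)
  expect_equal(mm$df, 8)
  expect_equal(mm$pvalue, pchisq(5, 8, lower.tail = FALSE))
  mm2 <- moment_match(3, c(2, 2))
  expect_equal(mm2$scale, 2)
  expect_equal(mm2$df, 2)
  # Monte-Carlo: matched chi-square tail close to the mixture's
  set.seed(17)
  delta <- c(2.1, 1.4, 0.9, 0.5, 0.2)
  draws <- colSums(delta * matrix(rchisq(5 * 1e5, 1), 5))
  q95 <- quantile(draws, 0.95)
  expect_lt(abs(moment_match(q95, delta)$pvalue - 0.05), 0.015)
})

test_that("full-pattern Pearson diagnostic behaves at small p", {
  spec2 <- model_spec(2, 1)
  set.seed(18)
  d <- sim_dataset(spec2, c(0.6, 0.5, -0.3, 0.2), 400)
  fit <- fit_pml(d, spec2)   # saturated: 2 items, 4 free parameters... m=4>S
  # saturated pairwise fit reproduces the 2x2 table: statistic ~ 0
  r <- full_pattern_pearson_oracle(d, spec2, fit$theta)
  expect_lt(r$statistic, 1e-4)
  expect_equal(full_pattern_pearson_oracle(d, spec2, fit$theta)$df,
               4 - 2 * 2 - 1)
  spec5 <- preset_model(1)
  set.seed(19)
  d5 <- sim_dataset(spec5, preset_theta(1), 300)
  expect_equal(full_pattern_pearson_oracle(
    d5, spec5, preset_theta(1))$df, 2^5 - 5 * 2 - 1)
  # textbook Pearson on an explicit 2x2 table
  y <- rbind(matrix(rep(c(1, 1), 30), ncol = 2, byrow = TRUE),
             matrix(rep(c(1, 0), 20), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 25), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 0), 25), ncol = 2, byrow = TRUE))
  dd <- survey_dataset(y)
  th <- c(0.5, 0.5, qnorm(1 - 0.5), qnorm(1 - 0.55))
  pr <- pattern_probs(spec2, th)
  obs <- c(25, 25, 20, 30) / 100
  expect_equal(full_pattern_pearson_oracle(dd, spec2, th)$statistic,
               100 * sum((obs - pr)^2 / pr), tolerance = 1e-10)
})

test_that("gof_tests returns the six statistics in fixed order", {
  set.seed(20)
  fit <- fit_pml(sim_dataset(preset_model(1), preset_theta(1), 800),
                 preset_model(1))
  gg <- gof_tests(fit)
  expect_equal(gg$results$name,
               c("Wald", "WaldVCF", "WaldDiag", "Pearson", "RSS",
                 "Multinomial"))
  expect_true(all(gg$results$statistic >= 0))
  expect_true(all(gg$results$pvalue >= 0 & gg$results$pvalue <= 1))
  expect_equal(gg$results$df[2], preset_model(1)$S - preset_model(1)$m)
})
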