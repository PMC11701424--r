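# Pairwise likelihood estimation and sandwich variance.

test_that("pairwise tables reproduce hand counts", {
  y <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  tab <- make_pairwise_table(survey_dataset(y))
  expect_equal(tab$cells[, 1], rep(0.25, 4))
  tab_w <- make_pairwise_table(survey_dataset(y, w = c(2, 1, 1, 0)))
  expect_equal(tab_w$cells[, 1], c(0.5, 0.25, 0.25, 0))
  expect_error(survey_dataset(y, w = rep(0, 4)), "zero")

  set.seed(1)
  d <- sim_dataset(preset_model(1), preset_theta(1), 200)
  tab_r <- make_pairwise_table(d)
  expect_equal(colSums(tab_r$cells), rep(1, 10))
})

test_that("score matches finite differences and the table layout", {
  set.seed(2)
  spec <- preset_model(1)
  d <- sim_dataset(spec, preset_theta(1), 400)
  tab <- make_pairwise_table(d, spec)
  for (rep in 1:3) {
    th <- random_theta(spec)
    sc <- pml_score(spec, th, tab)
    fd <- fd_grad(function(x) pairwise_loglik(spec, x, tab), th)
    expect_lt(max(abs(sc - fd)), 1e-6)
  }
})

test_that("noiseless recovery from a population-level table", {
  for (model in c(1, 4)) {
    spec <- preset_model(model)
    th0 <- preset_theta(model)
    tab <- implied_pairwise_table(spec, th0)
    expect_lt(max(abs(pml_score(spec, th0, tab))), 1e-12)
    fit <- fit_pml(tab, spec)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$theta - th0)), 1e-5)
  }
})

test_that("a single pair recovers the tetrachoric correlation", {
  # with p = 2, q = 1 the product lambda1 * lambda2 is identified as the
  # tetrachoric correlation of the 2x2 table; oracle = grid search
  spec <- model_spec(2, 1)
  set.seed(3)
  d <- sim_dataset(spec, c(0.8, 0.6, -0.4, 0.3), 3000)
  tab <- make_pairwise_table(d, spec)
  fit <- fit_pml(tab, spec)
  grid <- seq(-0.99, 0.99, by = 0.001)
  tau <- qnorm(1 - c(sum(tab$cells[c(3, 4), 1]), sum(tab$cells[c(2, 4), 1])))
  ll <- vapply(grid, function(r)
    sum(tab$cells[, 1] *
          log(biv_prob(tau[1], tau[2], r, c(0, 0, 1, 1), c(0, 1, 0, 1)))),
    0)
  rho_grid <- grid[which.max(ll)]
  expect_equal(prod(fit$theta[1:2]), rho_grid, tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("weight scaling is a no-op and unit weights equal no weights", {
  set.seed(4)
  spec <- preset_model(1)
  pop <- generate_factor_data(spec, preset_theta(1), 20000)
  d1 <- informative_sample(pop, 300)
  d2 <- survey_dataset(d1$y, w = 7.3 * d1$w)
  f1 <- fit_pml(d1, spec)
  f2 <- fit_pml(d2, spec)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-9)
  d3 <- survey_dataset(d1$y)
  expect_equal(fit_pml(d1, spec, weighted = FALSE)$theta,
               fit_pml(d3, spec)$theta, tolerance = 1e-9)
})

test_that("sensitivity matrix: analytic equals finite differences, PSD", {
  set.seed(5)
  spec <- preset_model(4)
  d <- sim_dataset(spec, preset_theta(4), 500)
  tab <- make_pairwise_table(d, spec)
  th <- random_theta(spec)
  # away from the optimum H may be indefinite; the warning is expected
  Ha <- suppressWarnings(sensitivity_H(spec, th, tab))
  Hf <- suppressWarnings(sensitivity_H(spec, th, tab, method = "fd"))
  expect_lt(max(abs(Ha - Hf)), 1e-6)
  expect_true(isSymmetric(Ha))
  fit <- fit_pml(d, spec)
  Hopt <- sensitivity_H(fit$spec, fit$theta, fit$table)
  expect_gt(min(eigen(Hopt, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("variability matrices: iid structure and cluster reduction", {
  spec <- preset_model(1)
  th0 <- preset_theta(1)
  set.seed(6)
  d1 <- sim_dataset(spec, th0, 1)
  J1 <- variability_J_iid(spec, th0, d1)
  expect_equal(qr(J1)$rank, 1)

  d <- sim_dataset(spec, th0, 600)
  fit <- fit_pml(d, spec)
  Ji <- variability_J_iid(spec, fit$theta, d)
  expect_gte(min(eigen(Ji, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  # singleton PSUs, one stratum, unit weights: J_cluster = n/(n-1) * J_iid
  # (the PSU-mean term is the pooled score, ~0 at the optimum)
  dc <- survey_dataset(d$y, stratum = rep(1, d$n), psu = seq_len(d$n))
  Jc <- variability_J_cluster(spec, fit$theta, dc)
  expect_lt(max(abs(Jc - d$n / (d$n - 1) * Ji)), 1e-9)
  # a stratum with a single PSU is refused
  dbad <- survey_dataset(d$y[1:10, ], stratum = c(1, rep(2, 9)),
                         psu = c(1, rep(2:4, 3)))
  expect_error(variability_J_cluster(spec, fit$theta, dbad), "single PSU")
})

test_that("cluster variability matrix matches a hand-computed toy", {
  spec <- model_spec(2, 1)
  y <- rbind(c(1, 1), c(0, 1), c(1, 0), c(0, 0), c(1, 1), c(0, 0))
  d <- survey_dataset(y, stratum = c(1, 1, 1, 1, 2, 2),
                      psu = c("a", "a", "b", "b", "c", "d"))
  th <- c(0.6, 0.5, -0.2, 0.1)
  us <- pmlbin:::.unit_scores(spec, th, d)$scores
  # hand assembly of the between-cluster estimator
  z <- rbind(us[1, ] + us[2, ], us[3, ] + us[4, ], us[5, ], us[6, ])
  J_hand <- matrix(0, 4, 4)
  zb1 <- colMeans(z[1:2, ]); zb2 <- colMeans(z[3:4, ])
  for (b in 1:2) J_hand <- J_hand + 2 * tcrossprod(z[b, ] - zb1)
  for (b in 3:4) J_hand <- J_hand + 2 * tcrossprod(z[b, ] - zb2)
  expect_equal(variability_J_cluster(spec, th, d), J_hand / 6,
               tolerance = 1e-12)
})

test_that("sandwich reduces to H^-1/n in the likelihood case", {
  spec <- preset_model(1)
  set.seed(7)
  d <- sim_dataset(spec, preset_theta(1), 300)
  fit <- fit_pml(d, spec)
  H <- sensitivity_H(spec, fit$theta, fit$table)
  sw <- sandwich_parts(H, H, d$n)
  expect_equal(sw$acov, solve(H) / d$n, tolerance = 1e-10)
  # invariance of SEs under unit reordering
  perm <- sample(d$n)
  dperm <- survey_dataset(d$y[perm, ])
  expect_equal(pml_sandwich(fit_pml(dperm, spec), "iid")$se,
               pml_sandwich(fit, "iid")$se, tolerance = 1e-7)
})

test_that("recovery from simulated data is close to truth", {
  set.seed(8)
  spec <- preset_model(1)
  th0 <- preset_theta(1)
  fit <- fit_pml(sim_dataset(spec, th0, 5000), spec)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta - th0)), 0.06)
})
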