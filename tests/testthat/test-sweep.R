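test_that("the full design enumerates 3,630 combinations and 10,890,000 jobs", {
  g <- sweep_grid()
  combos <- enumerate_grid(g)
  expect_equal(nrow(combos), 3630)
  expect_equal(attr(combos, "n_jobs"), 10890000)

  g1 <- sweep_grid(delta_bar_values = 0.5, omega_values = 0.5,
                   psi_values = 1, lambda_values = 0, scenarios = "specialist",
                   phi_values = 0.4, n_seeds = 1)
  expect_equal(nrow(enumerate_grid(g1)), 1)
})

test_that("sweep records share baselines: effect is exactly zero at omega = 0", {
  g <- sweep_grid(delta_bar_values = c(0.2, 0.6), omega_values = c(0, 0.4),
                  psi_values = c(0, 1), lambda_values = 0,
                  scenarios = "specialist", phi_values = 0.4, n_seeds = 2)
  res <- run_sweep(g, base_seed = 3)
  expect_s3_class(res, "cheat_sweep")
  expect_true(all(res$effect[res$omega == 0] == 0))
  # baseline shared across (delta_bar, psi): same persistence at omega = 0
  base <- res[res$omega == 0, ]
  expect_equal(length(unique(base$persistence[base$seed == 1])), 1)
  # effect consistency: persistence - baseline
  for (s in unique(res$seed)) {
    b <- unique(base$persistence[base$seed == s])
    sub <- res[res$seed == s & res$omega > 0, ]
    expect_equal(sub$effect, sub$persistence - b)
  }
})

test_that("variance decomposition recovers analytic variance ratios", {
  expect_error(variance_explained(1:5, rep(1, 5)), "groups")

  # no within-group noise -> 1
  g <- rep(1:4, each = 10)
  eff <- rep(c(1, 3, 5, 9), each = 10)
  expect_equal(variance_explained(eff, g), 1)

  # identical group means -> ~0
  set.seed(10)
  eff0 <- rnorm(400)
  g0 <- rep(1:4, each = 100)
  expect_lt(abs(variance_explained(eff0, g0)), 0.05)

  # known variance ratio: between-group variance vs total
  set.seed(11)
  n_g <- 40; n_per <- 200
  mu <- rnorm(n_g, sd = 2)            # between-group sd 2
  eff <- rep(mu, each = n_per) + rnorm(n_g * n_per, sd = 1)
  grp <- rep(seq_len(n_g), each = n_per)
  # analytic proportion = var_between / (var_between + var_within)
  analytic <- var(rep(mu, each = n_per)) / (var(rep(mu, each = n_per)) + 1)
  expect_equal(variance_explained(eff, grp), analytic, tolerance = 0.05)

  expect_warning(v <- variance_explained(rep(2, 10), rep(1:2, 5)), "zero")
  expect_true(is.na(v))
})

test_that("residual OLS recovers exact coefficients and matches normal equations", {
  set.seed(12)
  n <- 120
  dat <- data.frame(
    mean_r_P = runif(n, -0.4, -0.1), mean_r_A = runif(n, -0.4, -0.1),
    connectance = runif(n, 0.2, 0.4), nodf = runif(n, 20, 80),
    modularity = runif(n, 0.1, 0.5), phi = sample(c(0.2, 0.3, 0.4), n, TRUE))
  nodf_c <- dat$nodf - ave(dat$nodf, dat$phi)
  mod_c <- dat$modularity - ave(dat$modularity, dat$phi)
  dat$residual_effect <- 2 - 3 * dat$mean_r_P + 1.5 * dat$mean_r_A +
    4 * dat$connectance + 0.02 * nodf_c - 0.8 * mod_c

  fit <- residual_structure_model(dat)
  expect_equal(unname(fit$coefficients$estimate),
               c(2, -3, 1.5, 4, 0.02, -0.8), tolerance = 1e-8)

  # centering: within each phi class the centered nestedness means are 0
  for (p in unique(dat$phi)) {
    expect_lt(abs(mean(nodf_c[dat$phi == p])), 1e-10)
  }

  # noisy case: match the normal-equations oracle
  dat$residual_effect <- dat$residual_effect + rnorm(n, sd = 0.3)
  fit <- residual_structure_model(dat)
  nodf_c <- dat$nodf - ave(dat$nodf, dat$phi)
  mod_c <- dat$modularity - ave(dat$modularity, dat$phi)
  X <- cbind(1, dat$mean_r_P, dat$mean_r_A, dat$connectance, nodf_c, mod_c)
  beta <- solve(t(X) %*% X, t(X) %*% dat$residual_effect)
  expect_equal(unname(fit$coefficients$estimate), unname(drop(beta)),
               tolerance = 1e-8)

  dat$mean_r_A <- dat$mean_r_P  # force collinearity
  expect_error(residual_structure_model(dat), "collinear")
})
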