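test_that("similarity matrices are symmetric, unit-diagonal, and in [0, 1]", {
  set.seed(21)
  M <- matrix(runif(30), 5, 6)
  C <- matrix(runif(30) * rbinom(30, 1, 0.4), 5, 6)
  sim <- similarity_matrices(M, C)
  for (S in sim) {
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_equal(unname(diag(S)), rep(1, nrow(S)))
    expect_true(all(S >= 0 & S <= 1 + 1e-12))
  }

  # identical rows -> similarity 1; disjoint rows -> 0
  M2 <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  sim2 <- similarity_matrices(M2, matrix(0, 3, 3))
  expect_equal(sim2$Pi[1, 2], 1)
  expect_equal(sim2$Pi[1, 3], 0)
  # C = 0: shared-cheater similarity collapses to the identity pattern
  expect_equal(unname(sim2$Gamma), diag(3))
})

test_that("rhs respects absorbing extinction and the lambda switch", {
  sys <- two_species_system()
  d <- glv_rhs(P = 0, A = 2, M = sys$M, C = sys$C, r_P = sys$r_P,
               r_A = sys$r_A, params = sys$params)
  expect_equal(d$dP, 0)  # extinct plants stay extinct

  # with lambda = 0 the plant cheating-cost term vanishes for any C
  set.seed(5)
  M <- matrix(runif(16), 4, 4); C <- matrix(runif(16), 4, 4)
  P <- runif(4); A <- runif(4)
  r <- rep(-0.1, 4)
  d_noC <- glv_rhs(P, A, M, matrix(0, 4, 4), r, r, lambda_cost = 0)
  pars <- dynamics_params()
  # plant equation with C present but lambda 0, holding similarities fixed at
  # the no-cheating values so only the cost term could differ
  sim0 <- similarity_matrices(M, matrix(0, 4, 4))
  d_withC <- glv_rhs(P, A, M, C, r, r, lambda_cost = 0, sim = sim0)
  expect_equal(d_withC$dP, d_noC$dP, tolerance = 1e-12)

  expect_error(glv_rhs(c(-1, 1, 1, 1), A, M, C, r, r), "nonnegative")
  expect_error(glv_rhs(P, A, M, C, r, r, lambda_cost = 2), "alpha")
})

test_that("2-species equilibrium matches an independent root-finding oracle", {
  skip_if_not_installed("pracma")
  sys <- two_species_system()
  # tighten the variance rule so the sampled state sits at the fixed point
  # to better than the 1e-6 comparison tolerance
  sys$params$conv_tol <- 1e-18
  eq <- integrate_to_equilibrium(
    list(M = sys$M, C = sys$C, r_P = sys$r_P, r_A = sys$r_A, delta = 0L),
    params = sys$params)
  expect_true(eq$converged)
  expect_equal(eq$persistence, 100)

  root <- pracma::fsolve(function(x) {
    g <- two_species_rhs(x) / x  # per-capita rates at an interior equilibrium
    g
  }, c(0.2, 0.2))$x
  expect_lt(max(abs(c(eq$P, eq$A) - root)), 1e-6)
  # the package rhs vanishes at the oracle equilibrium
  d <- glv_rhs(root[1], root[2], sys$M, sys$C, sys$r_P, sys$r_A,
               params = sys$params)
  expect_lt(max(abs(c(d$dP, d$dA))), 1e-10)
})

test_that("no viable mutualism collapses to zero persistence", {
  com <- make_community(6, 6, phi = 0.4, seed = 4)
  com$r_P <- rep(-0.5, 6)
  com$r_A <- rep(-0.5, 6)
  eq <- integrate_to_equilibrium(com, cheating_config(0, 0, 0),
                                 dynamics_params(alpha = 0.001))
  expect_equal(eq$persistence, 0)
  expect_true(eq$stable)  # total extinction with negative rates is stable
})

test_that("omega = 0 trajectories are identical whatever delta_bar and psi", {
  com <- make_community(8, 8, phi = 0.4, seed = 6)
  eq1 <- integrate_to_equilibrium(com, cheating_config(0.8, 0, 1))
  eq2 <- integrate_to_equilibrium(com, cheating_config(0.2, 0, 0))
  expect_equal(eq1$P, eq2$P)
  expect_equal(eq1$A, eq2$A)
  expect_equal(eq1$steps_used, eq2$steps_used)
})

test_that("stability test matches an independently differenced Jacobian", {
  sys <- two_species_system()
  eq <- integrate_to_equilibrium(
    list(M = sys$M, C = sys$C, r_P = sys$r_P, r_A = sys$r_A, delta = 0L),
    params = sys$params)
  x <- c(eq$P, eq$A)
  # independent central differences on the closed-form 2-species RHS
  h <- 1e-6
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (two_species_rhs(xp) - two_species_rhs(xm)) / (2 * h)
  }
  expect_equal(eq$stable, max(Re(eigen(J)$values)) < 0)

  # logistic 1-species subsystem at carrying capacity is stable
  expect_true(check_stability(1, extinct_tol = 1e-5,
                              rhs = function(x) x * (1 - x)))
  # and unstable at the extinction boundary pushed slightly off
  expect_false(check_stability(1, extinct_tol = 1e-5,
                               rhs = function(x) x * (x - 0.5)))
})

test_that("persistence applies a strict threshold", {
  expect_equal(persistence(c(1, 1e-6, 0.5, 0)), 50)
  expect_equal(persistence(rep(1, 8)), 100)
  expect_equal(persistence(c(1e-5, 1)), 50)  # exactly at threshold = extinct
  expect_error(persistence(numeric(0)), "empty")
})

test_that("abundances stay nonnegative along a trajectory", {
  com <- make_community(10, 10, phi = 0.4, seed = 8)
  eq <- integrate_to_equilibrium(com, cheating_config(0.5, 0.9, 1, 0.3),
                                 keep_trajectory = TRUE)
  expect_true(all(eq$trajectory >= 0))
})

test_that("pollinator benefit is monotone in cheating strength at fixed abundances", {
  # alpha*x/(1 + beta*x + k) increases in x: more C never reduces the
  # pollinator gain term when abundances are held fixed
  alpha <- 1.5; beta <- 1; k <- 0.7
  x <- seq(0, 5, by = 0.1)
  gain <- alpha * x / (1 + beta * x + k)
  expect_true(all(diff(gain) > 0))
})
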