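test_that("the empirical backbone encodes I, Cprop and M = I(1 - C)", {
  net <- toy_field_network()
  bb <- empirical_backbone(net)
  # bird_1 x plant_1: legit 8, illegit 2 -> Cprop 0.2, I 1, M 0.8
  expect_equal(bb$I["plant_1", "bird_1"], 1)
  expect_equal(bb$Cprop["plant_1", "bird_1"], 0.2)
  expect_equal(bb$M["plant_1", "bird_1"], 0.8)

  # purely illegitimate pair
  net$legit_freq["plant_1", "bird_1"] <- 0
  bb <- empirical_backbone(net)
  expect_equal(bb$I["plant_1", "bird_1"], 0)
  expect_equal(bb$Cprop["plant_1", "bird_1"], 1)
  expect_equal(bb$M["plant_1", "bird_1"], 0)
  # ... unless the toggle excludes them
  bb2 <- empirical_backbone(net, include_illegit_only = FALSE)
  expect_equal(bb2$Cprop["plant_1", "bird_1"], 0)

  # no cheating anywhere -> M = I
  net0 <- toy_field_network()
  net0$illegit_freq[] <- 0
  bb0 <- empirical_backbone(net0)
  expect_equal(bb0$M, bb0$I)

  netz <- toy_field_network()
  netz$legit_freq[] <- 0; netz$illegit_freq[] <- 0
  expect_error(empirical_backbone(netz), "no interactions")
})

test_that("zero cheating gives exactly zero effect on every grid point", {
  net <- toy_field_network()
  net$illegit_freq[] <- 0
  bb <- empirical_backbone(net)
  eff <- effect_of_cheating(bb, alpha_values = c(1, 1.6), lambda_values = 0,
                            c_values = 1, n_seeds = 2)
  expect_true(all(eff$effect == 0))
})

test_that("the default grids span 60 parameter combinations", {
  g <- expand.grid(alpha = seq(1, 2, by = 0.2),
                   lambda = c(0, 0.05, 0.1, 0.15, 0.3), c = c(0.5, 1))
  expect_equal(nrow(g), 60)
  expect_true(all(g$lambda < g$alpha))  # mutualism condition holds everywhere
})

test_that("paired seeds make with/without runs share growth rates", {
  fd <- generate_field_dataset(field_config(n_sites = 2), seed = 3)
  bb <- empirical_backbone(fd$sites[[1]])
  eff <- effect_of_cheating(bb, alpha_values = 1.2, lambda_values = 0,
                            c_values = 0.5, n_seeds = 3, base_seed = 2)
  expect_equal(nrow(eff), 3)
  # rerunning reproduces the exact same effects (pure function of seeds)
  eff2 <- effect_of_cheating(bb, alpha_values = 1.2, lambda_values = 0,
                             c_values = 0.5, n_seeds = 3, base_seed = 2)
  expect_identical(eff, eff2)
})

test_that("randomization preserves total cheating mass to 1e-9", {
  fd <- generate_field_dataset(field_config(n_sites = 3), seed = 6)
  bb <- empirical_backbone(fd$sites[[2]])
  for (s in 1:20) {
    rb <- randomize_cheating(bb, seed = s)
    expect_lt(abs(sum(rb$C) - sum(bb$C)), 1e-9)
    expect_equal(rb$M, rb$I * (1 - rb$C))
  }
})

test_that("a single cheating packet moves uniformly over eligible cells", {
  # 3 x 3 toy with one cheating pair; eligible destinations are the 3 cells
  # of whichever single column is drawn as the cheater: 9 cells overall
  legit <- matrix(c(1, 0, 0,
                    0, 1, 0,
                    0, 0, 1), 3, 3,
                  dimnames = list(paste0("p", 1:3), paste0("b", 1:3)))
  ill <- matrix(0, 3, 3, dimnames = dimnames(legit))
  ill[1, 2] <- 1
  net <- structure(list(site_id = "toy3", elevation = 0,
                        legit_freq = legit, illegit_freq = ill),
                   class = "field_network")
  bb <- empirical_backbone(net)
  counts <- matrix(0, 3, 3)
  n_draws <- 6000
  for (s in seq_len(n_draws)) {
    rb <- randomize_cheating(bb, seed = s)
    counts <- counts + (rb$C > 0)
  }
  # uniform enumeration: each of the 9 cells equally likely
  expect_equal(sum(counts), n_draws)
  p_hat <- counts / n_draws
  se <- sqrt((1 / 9) * (8 / 9) / n_draws)
  expect_true(all(abs(p_hat - 1 / 9) < 5 * se))
})

test_that("z-scores clamp infinities and define 0/0 as zero", {
  # observation equal to every null value -> 0
  expect_equal(zscore_pipeline(0.5, c(0.5, 0.5, 0.5))$z, 0)
  # obs = 1.0 clamped to 0.99 against degenerate nulls at 0.5 -> +5
  expect_equal(zscore_pipeline(1, c(0.5, 0.5, 0.5))$z, 5)
  expect_equal(zscore_pipeline(0, c(0.5, 0.5, 0.5))$z, -5)

  # hand-computed z on 5 printed values
  nulls <- c(0.40, 0.45, 0.50, 0.55, 0.60)
  obs <- 0.70
  lo <- log(0.7 / 0.3)
  ln <- log(nulls / (1 - nulls))
  expected <- (lo - mean(ln)) / sd(ln)
  expect_equal(zscore_pipeline(obs, nulls)$z, expected, tolerance = 1e-12)

  # multi-seed averaging and bounds
  zc <- zscore_pipeline(c(0.7, 0.2), rbind(nulls, nulls))
  expect_equal(zc$site_z, mean(zc$z))
  expect_true(all(abs(zc$z) <= 5))
  expect_error(zscore_pipeline(0.5, 0.4), "2 null")
})
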