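test_that("count normalization applies the hours x 24 rule", {
  expect_equal(normalize_counts(12, 24), 12)
  expect_equal(normalize_counts(5, 120), 1)
  expect_equal(normalize_counts(0, 50), 0)
  M <- matrix(c(12, 5, 0, 10), 2, 2)
  f <- normalize_counts(M, c(24, 120))
  expect_equal(f[1, ], c(12, 0))
  expect_equal(f[2, ], c(1, 2))
  expect_error(normalize_counts(3, 0), "hours")
})

test_that("the generator is reproducible and respects its invariants", {
  fd1 <- generate_field_dataset(field_config(n_sites = 4), seed = 5)
  fd2 <- generate_field_dataset(field_config(n_sites = 4), seed = 5)
  expect_identical(fd1$sites, fd2$sites)
  for (net in fd1$sites) {
    expect_true(all(net$legit_freq >= 0))
    expect_true(all(net$illegit_freq >= 0))
    expect_true(all(colSums(net$legit_freq) > 0))  # every bird has a legit link
    expect_true(all(is.finite(net$plant_traits$corolla_length)))
  }
})

test_that("omega_true = 0 everywhere yields zero illegitimate entries", {
  cfg <- field_config(n_sites = 3, cheater_base = -50)  # nobody cheats
  fd <- generate_field_dataset(cfg, seed = 2)
  for (net in fd$sites) expect_true(all(net$illegit_freq == 0))
})

test_that("a zero elevation slope leaves cheating flat across elevation", {
  slopes <- vapply(1:12, function(s) {
    cfg <- field_config(n_sites = 8, elevation_slope = 0)
    fd <- generate_field_dataset(cfg, seed = s)
    est <- estimate_cheating_patterns(fd)
    ps <- est$per_site
    coef(glm_trend(overall_cheating ~ elevation, ps,
                   weights = ps$total_frequency))[["elevation"]]
  }, numeric(1))
  # slope estimates scatter around zero over seeds
  expect_lt(abs(mean(slopes)) / (sd(slopes) / sqrt(length(slopes))), 3)
})

test_that("estimators recover generator ground truth (signs and psi level)", {
  psi_hat <- numeric(0)
  div_slopes <- numeric(0)
  elev_slopes <- numeric(0)
  for (s in 1:8) {
    fd <- generate_field_dataset(field_config(), seed = s)
    est <- estimate_cheating_patterns(fd)
    tr <- cheating_trends(est)
    psi_hat <- c(psi_hat, mean(est$per_bird$innovative_proportion))
    div_slopes <- c(div_slopes,
                    coef(tr$frequency_vs_diversity)[["log_diversity"]])
    elev_slopes <- c(elev_slopes,
                     coef(tr$overall_vs_elevation)[["elevation"]])
  }
  expect_true(all(div_slopes < 0))   # specialists cheat more
  expect_true(all(elev_slopes < 0))  # cheating declines with elevation
  expect_lt(abs(mean(psi_hat) - 0.9), 0.15)
})

test_that("field datasets round-trip through the TSV directory layout", {
  fd <- generate_field_dataset(field_config(n_sites = 2), seed = 9)
  dir <- withr::local_tempdir()
  write_field_dataset(fd, dir)
  back <- read_field_dataset(dir)
  expect_equal(length(back$sites), 2)
  ids <- vapply(back$sites, `[[`, character(1), "site_id")
  for (net in fd$sites) {
    b <- back$sites[[match(net$site_id, ids)]]
    expect_equal(b$legit_freq, net$legit_freq, tolerance = 1e-10)
    expect_equal(b$illegit_freq, net$illegit_freq, tolerance = 1e-10)
    expect_equal(b$elevation, net$elevation)
  }
  expect_equal(back$ground_truth$psi_true, fd$ground_truth$psi_true)
})

test_that("hull distance separates inside from outside points", {
  X <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(cheatnet:::.hull_distance(c(1, 1), X), 0)
  expect_equal(cheatnet:::.hull_distance(c(4, 1), X), 2)
  expect_equal(cheatnet:::.hull_distance(c(3, 3), X), sqrt(2))
  # degenerate hulls: point and segment
  expect_equal(cheatnet:::.hull_distance(c(1, 1), rbind(c(0, 0))), sqrt(2))
  expect_equal(cheatnet:::.hull_distance(c(1, 1), rbind(c(0, 0), c(2, 0))), 1)
})
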