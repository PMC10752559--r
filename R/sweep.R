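#' Cheating-parameter sweep grid
#'
#' The default grid is the full theoretical design: proportion of cheaters
#' `delta_bar` from 0.1 to 1 by 0.1, cheating frequency `omega` from 0 to 1
#' by 0.1, innovative proportion `psi` from 0 to 1 by 0.1, mutualism cost
#' `lambda` in \{0, 0.15, 0.3\} (10 x 11 x 11 x 3 = 3,630 combinations),
#' crossed with both cheater scenarios, three connectance values and
#' `n_seeds` community replicates.
#'
#' @param delta_bar_values,omega_values,psi_values,lambda_values parameter
#'   grids.
#' @param scenarios cheater scenarios to run.
#' @param phi_values initial connectance values.
#' @param n_seeds number of community replicates (500 in the full design).
#' @param n_P,n_A guild sizes (20 + 20; 10 + 10 for the reduced variant).
#' @param interference_A pollinator-side interference strength (0 disables
#'   interference among pollinators only).
#' @return object of class `sweep_grid`.
#' @export
sweep_grid <- function(delta_bar_values = seq(0.1, 1, by = 0.1),
                       omega_values = seq(0, 1, by = 0.1),
                       psi_values = seq(0, 1, by = 0.1),
                       lambda_values = c(0, 0.15, 0.3),
                       scenarios = c("generalist", "specialist"),
                       phi_values = c(0.2, 0.3, 0.4),
                       n_seeds = 500L, n_P = 20L, n_A = 20L,
                       interference_A = 1) {
  structure(list(delta_bar_values = delta_bar_values,
                 omega_values = omega_values, psi_values = psi_values,
                 lambda_values = lambda_values, scenarios = scenarios,
                 phi_values = phi_values, n_seeds = as.integer(n_seeds),
                 n_P = as.integer(n_P), n_A = as.integer(n_A),
                 interference_A = interference_A),
            class = "sweep_grid")
}

#' Enumerate the cheating-parameter combinations of a grid
#'
#' @param grid a [sweep_grid()] object.
#' @return data frame of (delta_bar, omega, psi, lambda) combinations, with
#'   attribute `"n_jobs"` giving the full job count
#'   `n_seeds x combos x scenarios x connectances`.
#' @examples
#' g <- sweep_grid()
#' nrow(enumerate_grid(g))            # 3630
#' attr(enumerate_grid(g), "n_jobs")  # 10890000
#' @export
enumerate_grid <- function(grid) {
  combos <- expand.grid(delta_bar = grid$delta_bar_values,
                        omega = grid$omega_values,
                        psi = grid$psi_values,
                        lambda = grid$lambda_values,
                        KEEP.OUT.ATTRS = FALSE)
  attr(combos, "n_jobs") <- as.numeric(nrow(combos)) * grid$n_seeds *
    length(grid$scenarios) * length(grid$phi_values)
  combos
}

#' Run a cheating-parameter sweep
#'
#' Runs every (seed, combination, scenario, connectance) job of the grid and
#' differences each persistence value against the matched no-cheating
#' baseline: one `omega = 0` run per (seed, scenario, phi, lambda), reused
#' across all (delta_bar, psi) since cheating parameters are inert at
#' `omega = 0`, and sharing the community seed so the difference isolates
#' cheating. Jobs are pure functions of (seed, combination), so any
#' execution order yields the same table.
#'
#' @param grid a [sweep_grid()] object.
#' @param base_seed seed from which per-community seeds are derived.
#' @param params a [dynamics_params()] template (alpha, beta, tolerances).
#' @param structure_covariates also record connectance, NODF, modularity and
#'   mean growth rates of each community (needed by
#'   [residual_structure_model()]).
#' @param progress print a line per community.
#' @return object of classes `cheat_sweep`/`data.frame`: long-format records
#'   with columns seed, scenario, phi, delta_bar, omega, psi, lambda,
#'   persistence, effect, converged, stable (plus structure covariates when
#'   requested).
#' @export
run_sweep <- function(grid, base_seed = 1L, params = dynamics_params(),
                      structure_covariates = FALSE, progress = FALSE) {
  combos <- enumerate_grid(grid)
  params$c_interf_A <- grid$interference_A
  out <- vector("list", grid$n_seeds)
  for (s in seq_len(grid$n_seeds)) {
    seed_s <- derive_seed(base_seed, s)
    rows <- list()
    for (phi in grid$phi_values) {
      com <- make_community(grid$n_P, grid$n_A, phi = phi, seed = seed_s)
      struct <- if (structure_covariates) {
        list(connectance = connectance(com$IM), nodf = nodf(com$IM),
             modularity = bipartite_modularity(com$IM, seed = seed_s)$Q,
             mean_r_P = mean(com$r_P), mean_r_A = mean(com$r_A))
      } else NULL
      for (scen in grid$scenarios) {
        # matched no-cheating baselines, one per lambda
        base_pers <- vapply(unique(combos$lambda), function(lam) {
          eq <- integrate_to_equilibrium(
            com, cheating_config(0, 0, 0, lambda_cost = lam, scenario = scen),
            params)
          eq$persistence
        }, numeric(1))
        names(base_pers) <- as.character(unique(combos$lambda))
        for (k in seq_len(nrow(combos))) {
          cb <- combos[k, ]
          if (cb$omega == 0) {
            pers <- base_pers[[as.character(cb$lambda)]]
            conv <- TRUE; stab <- NA
          } else {
            eq <- integrate_to_equilibrium(
              com, cheating_config(cb$delta_bar, cb$omega, cb$psi,
                                   lambda_cost = cb$lambda, scenario = scen),
              params)
            pers <- eq$persistence
            conv <- eq$converged; stab <- eq$stable
          }
          rec <- data.frame(seed = s, scenario = scen, phi = phi,
                            delta_bar = cb$delta_bar, omega = cb$omega,
                            psi = cb$psi, lambda = cb$lambda,
                            persistence = pers,
                            effect = pers - base_pers[[as.character(cb$lambda)]],
                            converged = conv, stable = stab)
          if (!is.null(struct)) rec <- cbind(rec, as.data.frame(struct))
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
    out[[s]] <- do.call(rbind, rows)
    if (progress) message(sprintf("community %d/%d done", s, grid$n_seeds))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cheat_sweep", "data.frame")
  res
}

#' @export
print.cheat_sweep <- function(x, ...) {
  cat(sprintf("Cheating sweep: %d records, %d communities, scenarios: %s\n",
              nrow(x), length(unique(x$seed)),
              paste(unique(x$scenario), collapse = ", ")))
  cheat <- x$omega > 0
  cat(sprintf("  mean effect of cheating %.3f%% (range %.2f to %.2f)\n",
              mean(x$effect[cheat]), min(x$effect[cheat]), max(x$effect[cheat])))
  invisible(x)
}

#' Proportion of variance in the cheating effect explained by a grouping
#'
#' `1 - Vg / V`, where `V` is the total variance of the effect and `Vg` the
#' variance of the group-mean-centered effects (the residual effects once
#' parameter and scenario combinations are accounted for).
#'
#' @param effects numeric vector of cheating effects.
#' @param group grouping factor (e.g. the parameter x scenario combination).
#' @return proportion of variance explained; `NA` with a warning when the
#'   total variance is zero.
#' @export
variance_explained <- function(effects, group) {
  group <- interaction(as.data.frame(group), drop = TRUE)
  if (nlevels(group) < 2L || any(table(group) < 2L)) {
    stop("need >= 2 groups with >= 2 records each", call. = FALSE)
  }
  V <- stats::var(effects)
  if (!is.finite(V) || V == 0) {
    warning("total variance is zero; proportion undefined")
    return(NA_real_)
  }
  centered <- effects - stats::ave(effects, group)
  1 - stats::var(centered) / V
}

#' Linear model for the residual effect of cheating
#'
#' Explains residual (group-centered) cheating effects by mean plant and
#' animal growth rates and by the structure of the initial backbone:
#' connectance, NODF nestedness, and modularity. To break the correlation of
#' nestedness and modularity with connectance, both are centered on their
#' mean within each connectance class before fitting. Ordinary least squares
#' via [stats::lm()].
#'
#' @param data data frame with columns `residual_effect`, `mean_r_P`,
#'   `mean_r_A`, `connectance`, `nodf`, `modularity`, and `phi` (the
#'   connectance class used for centering).
#' @return list with the fitted `lm` object and `coefficients` table
#'   (estimate, standard error).
#' @export
residual_structure_model <- function(data) {
  needed <- c("residual_effect", "mean_r_P", "mean_r_A", "connectance",
              "nodf", "modularity", "phi")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  data$nodf_c <- data$nodf - stats::ave(data$nodf, data$phi)
  data$modularity_c <- data$modularity - stats::ave(data$modularity, data$phi)
  fit <- stats::lm(residual_effect ~ mean_r_P + mean_r_A + connectance +
                     nodf_c + modularity_c, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  list(fit = fit,
       coefficients = data.frame(estimate = sm$coefficients[, 1],
                                 std_error = sm$coefficients[, 2]))
}

#' Random-grid stability experiment
#'
#' Draws `n_sims` parameter combinations uniformly from the full sweep grid
#' (cheating parameters, cost, scenario, connectance), runs each on a fresh
#' community, and records whether the stopping rule reached a state that
#' passes the Jacobian stability test. Used to verify that the integration
#' protocol almost always lands on a stable steady equilibrium.
#'
#' @param n_sims number of simulations.
#' @param base_seed RNG seed.
#' @param grid a [sweep_grid()] supplying the value sets and guild sizes.
#' @param params a [dynamics_params()] template.
#' @return data frame with one row per simulation: sampled parameters,
#'   `converged`, `stable`, `persistence`, `steps_used`.
#' @export
sample_grid_simulations <- function(n_sims = 1000L, base_seed = 1L,
                                    grid = sweep_grid(),
                                    params = dynamics_params()) {
  rows <- vector("list", n_sims)
  for (k in seq_len(n_sims)) {
    set.seed(derive_seed(base_seed, k, 1L))
    db <- sample(grid$delta_bar_values, 1)
    om <- sample(grid$omega_values, 1)
    ps <- sample(grid$psi_values, 1)
    la <- sample(grid$lambda_values, 1)
    sc <- sample(grid$scenarios, 1)
    ph <- sample(grid$phi_values, 1)
    com <- make_community(grid$n_P, grid$n_A, phi = ph,
                          seed = derive_seed(base_seed, k, 2L))
    eq <- integrate_to_equilibrium(
      com, cheating_config(db, om, ps, lambda_cost = la, scenario = sc),
      params)
    rows[[k]] <- data.frame(
      delta_bar = db, omega = om, psi = ps, lambda = la, scenario = sc,
      phi = ph, converged = eq$converged,
      stable = isTRUE(eq$stable), persistence = eq$persistence,
      steps_used = eq$steps_used)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
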