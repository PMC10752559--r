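#' Build a dynamic-model backbone from an observed interaction network
#'
#' `I[i, j] = 1` where plant i and bird j interacted at least once
#' mutualistically; the per-pair cheating proportion is the illegitimate
#' frequency over the total frequency of the pair, and the legitimate
#' ability is `M = I * (1 - C)`. Pairs with only illegitimate records keep
#' `I = 0`, `C = 1`: they feed the cheating matrix only (`include_illegit_only`
#' toggles this). Species with no interactions at all are dropped.
#'
#' @param network a `field_network`.
#' @param include_illegit_only keep purely illegitimate pairs in `C`.
#' @return object of class `empirical_backbone`: list with `I`, `Cprop`,
#'   `M`, `C` (cheating strengths `Cprop` on eligible pairs), `n_dropped`.
#' @export
empirical_backbone <- function(network, include_illegit_only = TRUE) {
  leg <- network$legit_freq
  ill <- network$illegit_freq
  tot <- leg + ill
  if (sum(tot) == 0) stop("network has no interactions", call. = FALSE)
  keep_p <- rowSums(tot) > 0
  keep_b <- colSums(tot) > 0
  n_dropped <- sum(!keep_p) + sum(!keep_b)
  leg <- leg[keep_p, keep_b, drop = FALSE]
  ill <- ill[keep_p, keep_b, drop = FALSE]
  tot <- tot[keep_p, keep_b, drop = FALSE]
  I <- (leg > 0) * 1
  Cprop <- matrix(0, nrow(I), ncol(I), dimnames = dimnames(I))
  pos <- tot > 0
  Cprop[pos] <- ill[pos] / tot[pos]
  if (!include_illegit_only) Cprop[I == 0] <- 0
  M <- I * (1 - Cprop)
  C <- Cprop
  C[I == 0 & Cprop == 0] <- 0
  structure(list(I = I, Cprop = Cprop, M = M, C = C,
                 n_dropped = n_dropped, site_id = network$site_id),
            class = "empirical_backbone")
}

# One simulation of an empirical backbone with drawn growth rates.
.simulate_backbone <- function(backbone, lambda_cost, params, seed,
                               with_cheating = TRUE) {
  n_P <- nrow(backbone$I); n_A <- ncol(backbone$I)
  sys <- list(M = backbone$M,
              C = if (with_cheating) backbone$C else matrix(0, n_P, n_A),
              delta = as.integer(colSums(backbone$C) > 0),
              lambda_cost = lambda_cost,
              r_P = draw_growth_rates(n_P, derive_seed(seed, 11L)),
              r_A = draw_growth_rates(n_A, derive_seed(seed, 12L)))
  if (!with_cheating) sys$M <- backbone$I  # pure mutualistic ability
  integrate_to_equilibrium(sys, params = params)
}

#' Effect of observed cheating on persistence over a parameter grid
#'
#' For every (alpha, lambda, c) combination and growth-rate seed, runs the
#' dynamics parameterized with all observed interactions and again with
#' cheating removed (`C = 0`, `M = I`), sharing the growth-rate vectors so
#' the persistence difference isolates cheating.
#'
#' @param backbone an [empirical_backbone()].
#' @param alpha_values per-interaction benefit grid (default 1 to 2 by 0.2).
#' @param lambda_values mutualism-cost grid (default 0, 0.05, 0.1, 0.15,
#'   0.3).
#' @param c_values interference-strength grid (default 0.5 and 1).
#' @param n_seeds growth-rate vectors per combination (100 in the full
#'   design).
#' @param base_seed seed from which growth-rate seeds are derived.
#' @param params numerical controls template ([dynamics_params()]).
#' @return data frame with one row per (alpha, lambda, c, seed):
#'   `persistence_with`, `persistence_without`, `effect`, plus convergence
#'   flags; non-converged runs are kept but flagged.
#' @export
effect_of_cheating <- function(backbone,
                               alpha_values = seq(1, 2, by = 0.2),
                               lambda_values = c(0, 0.05, 0.1, 0.15, 0.3),
                               c_values = c(0.5, 1),
                               n_seeds = 100L, base_seed = 1L,
                               params = dynamics_params()) {
  grid <- expand.grid(alpha = alpha_values, lambda = lambda_values,
                      c_interf = c_values, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$lambda < grid$alpha, , drop = FALSE]
  rows <- vector("list", nrow(grid) * n_seeds)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    p <- params
    p$alpha <- grid$alpha[g]
    p$c_interf <- grid$c_interf[g]
    p$c_interf_A <- grid$c_interf[g]
    for (s in seq_len(n_seeds)) {
      seed_s <- derive_seed(base_seed, g, s)
      eq1 <- .simulate_backbone(backbone, grid$lambda[g], p, seed_s, TRUE)
      eq0 <- .simulate_backbone(backbone, grid$lambda[g], p, seed_s, FALSE)
      k <- k + 1L
      rows[[k]] <- data.frame(
        site_id = backbone$site_id, alpha = grid$alpha[g],
        lambda = grid$lambda[g], c_interf = grid$c_interf[g], seed = s,
        persistence_with = eq1$persistence,
        persistence_without = eq0$persistence,
        effect = eq1$persistence - eq0$persistence,
        converged = eq1$converged && eq0$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Randomize the cheating pattern of an empirical backbone
#'
#' Redraws the identity of the cheaters (same number of cheating birds,
#' chosen uniformly) and reassigns each observed nonzero cheating value as
#' an indivisible packet to a uniformly chosen cell of the new cheaters'
#' columns (no two packets on one cell), so the conservative/innovative
#' split is redrawn while the total amount of cheating `sum(C)` is
#' preserved exactly. `M` is recomputed as `I * (1 - C)`.
#'
#' @param backbone an [empirical_backbone()].
#' @param seed RNG seed.
#' @return a new `empirical_backbone` with randomized `C`, `Cprop`, `M`.
#' @export
randomize_cheating <- function(backbone, seed = 1L) {
  vals <- backbone$C[backbone$C > 0]
  if (length(vals) == 0L) stop("backbone has no cheating", call. = FALSE)
  n_P <- nrow(backbone$I); n_A <- ncol(backbone$I)
  n_cheaters <- sum(colSums(backbone$C > 0) > 0)
  if (n_P * n_cheaters < length(vals)) {
    stop("cannot preserve cheating mass: more packets than available cells",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  cheaters <- sample.int(n_A, n_cheaters)
  cells <- as.vector(outer(seq_len(n_P), (cheaters - 1L) * n_P, `+`))
  picked <- if (length(cells) == 1L) cells else sample(cells, length(vals))
  C <- matrix(0, n_P, n_A, dimnames = dimnames(backbone$I))
  C[picked] <- vals
  out <- backbone
  out$C <- C
  out$Cprop <- C
  out$M <- backbone$I * (1 - C)
  out
}

#' Z-scores of observed persistence against a null distribution
#'
#' Persistence values (proportions in `[0, 1]`) are logit-transformed after
#' adjusting 0 to 0.01 and 1 to 0.99; the z-score is the distance of the
#' observed value from the null mean in null standard deviations. A null
#' standard deviation of zero makes the score sign-definite infinite, which
#' is clamped to -5 / +5; the degenerate 0/0 case (observation equal to
#' every null value) is defined as 0.
#'
#' @param observed observed persistence values (one per growth-rate seed),
#'   as proportions in `[0, 1]`.
#' @param null_values matrix (seeds x randomizations) or vector of null
#'   persistence values.
#' @return object of class `null_comparison`: list with per-seed `z`
#'   (clamped to `[-5, 5]`) and their mean `site_z`.
#' @export
zscore_pipeline <- function(observed, null_values) {
  if (is.vector(null_values)) null_values <- matrix(null_values, nrow = 1L)
  if (ncol(null_values) < 2L) stop("need >= 2 null values", call. = FALSE)
  adj <- function(p) logit(pmin(pmax(p, 0.01), 0.99))
  z <- vapply(seq_along(observed), function(i) {
    lo <- adj(observed[i])
    ln <- adj(null_values[i, ])
    s <- stats::sd(ln)
    num <- lo - mean(ln)
    if (s == 0) {
      if (num == 0) 0 else sign(num) * 5
    } else {
      max(-5, min(5, num / s))
    }
  }, numeric(1))
  structure(list(z = z, site_z = mean(z)), class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("Null-model comparison: site z = %.3f over %d seeds (z in [%.2f, %.2f])\n",
              x$site_z, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}
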