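#' Dynamics parameters
#'
#' Parameters of the generalized Lotka-Volterra system with saturating
#' functional responses: the per-mutualistic-interaction benefit `alpha`, the
#' handling time `beta`, the within-guild interference strength `c` applied
#' through the niche-similarity matrices, and the competition-for-space
#' matrices (identity by default: intraspecific competition 1, interspecific
#' 0). Also carries the numerical controls of the equilibrium search.
#'
#' @param alpha per-mutualistic-interaction benefit (default 1.5).
#' @param beta per-interaction handling time (default 1).
#' @param c_interf within-guild interference strength for shared partners
#'   (default 1). `c_interf_A` overrides the pollinator-side value, e.g. 0 to
#'   disable interference among pollinators only.
#' @param c_interf_A pollinator-side interference; defaults to `c_interf`.
#' @param comp_P,comp_A competition-for-space matrices; `NULL` means identity.
#' @param max_steps iteration cap of the equilibrium search (default 8000).
#' @param conv_window trailing window length of the stopping rule (default 10).
#' @param conv_tol abundance-variance tolerance of the stopping rule
#'   (default 1e-14).
#' @param extinct_tol abundance threshold below which a species counts as
#'   extinct when scoring persistence (default 1e-5).
#' @return object of class `dynamics_params`.
#' @export
dynamics_params <- function(alpha = 1.5, beta = 1, c_interf = 1,
                            c_interf_A = c_interf,
                            comp_P = NULL, comp_A = NULL,
                            max_steps = 8000L, conv_window = 10L,
                            conv_tol = 1e-14, extinct_tol = 1e-5) {
  structure(list(alpha = alpha, beta = beta,
                 c_interf = c_interf, c_interf_A = c_interf_A,
                 comp_P = comp_P, comp_A = comp_A,
                 max_steps = as.integer(max_steps),
                 conv_window = as.integer(conv_window),
                 conv_tol = conv_tol, extinct_tol = extinct_tol),
            class = "dynamics_params")
}

# Cosine similarity between the rows of a strength matrix. All-zero rows get
# similarity 0 off-diagonal and 1 on the diagonal.
.cosine_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  S <- X %*% t(X)
  denom <- outer(nrm, nrm)
  out <- ifelse(denom > 0, S / denom, 0)
  # clip tiny floating-point overshoot
  out[out > 1] <- 1
  diag(out) <- 1
  out
}

#' Niche-similarity matrices for within-guild interference
#'
#' Interference among plants for shared pollinators is weighted by the
#' similarity of their legitimate interaction profiles (`Pi`, from rows of
#' `M`); dilution of cheating costs among plants sharing cheaters uses the
#' similarity of their illegitimate profiles (`Gamma`, from rows of `C`);
#' interference among pollinators uses the similarity of their full
#' interaction profiles (`Theta`, from columns of `M + C`). Similarity is the
#' cosine of the strength vectors: symmetric, in `[0, 1]`, and 1 for
#' identical niches.
#'
#' @param M legitimate strength matrix.
#' @param C cheating strength matrix.
#' @return list with matrices `Pi` (`n_P` x `n_P`), `Gamma` (`n_P` x `n_P`),
#'   `Theta` (`n_A` x `n_A`).
#' @export
similarity_matrices <- function(M, C) {
  list(Pi = .cosine_rows(M),
       Gamma = .cosine_rows(C),
       Theta = .cosine_rows(t(M + C)))
}

#' Right-hand side of the plant-pollinator cheating model
#'
#' Per-capita plant growth is the basal rate, plus the mutualistic balance
#' `(alpha - lambda) * sum_j M[i,j] A_j` saturating with handling time and
#' plant-plant interference (`Pi`), minus the cost of being cheated on,
#' `lambda * sum_j C[i,j] A_j` saturating analogously with cheater dilution
#' (`Gamma`), minus competition for space. Pollinators gain `alpha` from all
#' interactions (legitimate or not) but pay the mutualism cost `lambda` only
#' on legitimate ones; both enter one functional response saturating with all
#' interactions and pollinator-pollinator interference (`Theta`).
#'
#' @param P,A nonnegative abundance vectors.
#' @param M,C strength matrices (plants x pollinators).
#' @param r_P,r_A basal growth rates.
#' @param params a [dynamics_params()] object.
#' @param lambda_cost mutualism cost `Lambda` (must be < `alpha`).
#' @param sim similarity matrices from [similarity_matrices()]; computed on
#'   the fly when `NULL`.
#' @return list with `dP` and `dA` time derivatives.
#' @export
glv_rhs <- function(P, A, M, C, r_P, r_A, params = dynamics_params(),
                    lambda_cost = 0, sim = NULL) {
  if (any(!is.finite(P)) || any(!is.finite(A)) || any(P < 0) || any(A < 0)) {
    stop("abundances must be finite and nonnegative", call. = FALSE)
  }
  if (lambda_cost >= params$alpha) {
    stop("mutualism requires alpha > lambda_cost", call. = FALSE)
  }
  if (is.null(sim)) sim <- similarity_matrices(M, C)
  d <- .rhs_core(P, A, .sim_context(M, C, r_P, r_A, params, lambda_cost, sim))
  list(dP = d[seq_along(P)], dA = d[-seq_along(P)])
}

# Precomputed pieces shared by every RHS evaluation of one simulation.
.sim_context <- function(M, C, r_P, r_A, params, lambda_cost, sim) {
  n_P <- nrow(M); n_A <- ncol(M)
  comp_P <- if (is.null(params$comp_P)) diag(n_P) else params$comp_P
  comp_A <- if (is.null(params$comp_A)) diag(n_A) else params$comp_A
  list(M = M, C = C, MC = M + C, r_P = r_P, r_A = r_A,
       alpha = params$alpha, beta = params$beta,
       cP = params$c_interf * sim$Pi, cG = params$c_interf * sim$Gamma,
       cT = params$c_interf_A * sim$Theta,
       comp_P = comp_P, comp_A = comp_A,
       lambda = lambda_cost, n_P = n_P, n_A = n_A)
}

.rhs_core <- function(P, A, ctx) {
  MA <- drop(ctx$M %*% A)          # sum_j M_ij A_j
  CA <- drop(ctx$C %*% A)          # sum_j C_ij A_j
  PiP <- drop(ctx$cP %*% P)
  GaP <- drop(ctx$cG %*% P)
  gP <- ctx$r_P +
    (ctx$alpha - ctx$lambda) * MA / (1 + ctx$beta * MA + PiP) -
    ctx$lambda * CA / (1 + ctx$beta * CA + GaP) -
    drop(ctx$comp_P %*% P)
  num_A <- drop(crossprod(ctx$MC, P)) * ctx$alpha -
    ctx$lambda * drop(crossprod(ctx$M, P))
  den_A <- 1 + ctx$beta * drop(crossprod(ctx$MC, P)) + drop(ctx$cT %*% A)
  gA <- ctx$r_A + num_A / den_A - drop(ctx$comp_A %*% A)
  c(P * gP, A * gA)
}

#' Integrate the community dynamics to equilibrium
#'
#' Starts all abundances at 1 and integrates the system with a stiff-capable
#' adaptive solver (`deSolve::lsoda`), sampling the trajectory at unit time
#' steps. Integration stops as soon as the variance of every species'
#' abundance over the trailing `conv_window` samples falls below `conv_tol`,
#' or at `max_steps` samples. Species dipping below 1e-9 are clamped to zero
#' (extinction is absorbing in a multiplicative model; the clamp prevents
#' resurrection through floating-point noise). The equilibrium is then
#' checked for local stability via the Jacobian of the surviving-species
#' subsystem.
#'
#' @param community a [make_community()] object, or a list with `IM`-free
#'   fields `M`, `C`, `r_P`, `r_A` (e.g. an empirical backbone expansion).
#' @param config a [cheating_config()] object; ignored when `community`
#'   already carries `M` and `C`.
#' @param params a [dynamics_params()] object.
#' @param keep_trajectory keep the sampled trajectory matrix in the result.
#' @return object of class `glv_equilibrium`: list with `P`, `A` (final
#'   abundances), `converged`, `stable`, `persistence` (percent of species
#'   above `extinct_tol`), `steps_used`, and optionally `trajectory`.
#' @examples
#' com <- make_community(10, 10, phi = 0.4, seed = 3)
#' eq <- integrate_to_equilibrium(com, cheating_config(0.3, 0.4, 1))
#' eq$persistence
#' @export
integrate_to_equilibrium <- function(community, config = cheating_config(0, 0, 0),
                                     params = dynamics_params(),
                                     keep_trajectory = FALSE) {
  if (!is.null(community$M)) {
    M <- community$M; C <- community$C; delta <- community$delta
    lambda_cost <- if (!is.null(community$lambda_cost)) community$lambda_cost
                   else config$lambda_cost
  } else {
    sp <- strength_pair(community, config)
    M <- sp$M; C <- sp$C; delta <- sp$delta
    lambda_cost <- config$lambda_cost
  }
  if (lambda_cost >= params$alpha) {
    stop("mutualism requires alpha > lambda_cost", call. = FALSE)
  }
  sim <- similarity_matrices(M, C)
  ctx <- .sim_context(M, C, community$r_P, community$r_A, params, lambda_cost, sim)
  n <- ctx$n_P + ctx$n_A
  y <- rep(1, n)
  win <- params$conv_window
  # the solver is restarted per chunk; chunks grow geometrically so long
  # runs cost about one continuous solve while the stopping rule is still
  # evaluated at every unit-time sample
  chunk <- max(win, 10L)
  hist <- matrix(NA_real_, nrow = n, ncol = win)
  hist[, win] <- y
  n_hist <- 1L
  t_now <- 0L
  converged <- FALSE
  traj <- if (keep_trajectory) list(`0` = y) else NULL
  deriv <- function(t, y, p) list(.rhs_core(y[seq_len(ctx$n_P)],
                                            y[-seq_len(ctx$n_P)], ctx))
  while (t_now < params$max_steps && !converged) {
    len <- min(chunk, params$max_steps - t_now)
    sol <- tryCatch(
      deSolve::lsoda(y, times = 0:len, func = deriv, parms = NULL,
                     rtol = 1e-8, atol = 1e-10),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < len + 1L || any(!is.finite(sol))) {
      # solver failure: report a non-converged result at the last good state
      break
    }
    states <- t(sol[-1L, -1L, drop = FALSE])  # species x time
    states[states < 1e-9] <- 0
    for (s in seq_len(len)) {
      hist <- cbind(hist[, -1L, drop = FALSE], states[, s])
      n_hist <- min(n_hist + 1L, win)
      t_now <- t_now + 1L
      if (keep_trajectory) traj[[as.character(t_now)]] <- states[, s]
      if (n_hist == win) {
        # row variances over the window, centered on the newest sample to
        # keep the 1e-14 comparison clear of cancellation error
        d <- hist - hist[, win]
        rs <- .rowSums(d, n, win)
        v <- (.rowSums(d * d, n, win) - rs * rs / win) / (win - 1)
        if (max(v) < params$conv_tol) { converged <- TRUE; break }
      }
    }
    y <- hist[, win]
    chunk <- min(chunk * 2L, 640L)
  }
  y <- unname(hist[, win])
  P <- y[seq_len(ctx$n_P)]
  A <- y[-seq_len(ctx$n_P)]
  stable <- if (converged || t_now >= params$max_steps) {
    check_stability(y, ctx, extinct_tol = params$extinct_tol)
  } else NA
  res <- structure(list(
    P = P, A = A, delta = delta,
    converged = converged, stable = stable,
    persistence = persistence(c(P, A), params$extinct_tol),
    steps_used = t_now
  ), class = "glv_equilibrium")
  if (keep_trajectory) {
    res$trajectory <- do.call(rbind, traj)
  }
  res
}

#' @export
print.glv_equilibrium <- function(x, ...) {
  cat(sprintf("GLV equilibrium after %d steps: %s, %s\n", x$steps_used,
              if (isTRUE(x$converged)) "converged" else "not converged",
              if (isTRUE(x$stable)) "stable" else if (isFALSE(x$stable)) "unstable" else "stability undetermined"))
  cat(sprintf("  persistence %.1f%% (%d plants, %d pollinators surviving)\n",
              x$persistence, sum(x$P > 1e-5), sum(x$A > 1e-5)))
  invisible(x)
}

#' Local stability of an equilibrium
#'
#' Builds the Jacobian of the surviving-species subsystem by central finite
#' differences (step `1e-6 * max(1, |x|)`) and declares the state stable iff
#' the largest real part of its eigenvalues is below 1e-8. An empty
#' subsystem (total extinction, all growth rates negative) is stable.
#'
#' @param y full state vector (plants then pollinators).
#' @param ctx internal simulation context (as built by
#'   [integrate_to_equilibrium()]); alternatively pass `rhs` directly.
#' @param extinct_tol species at or below this abundance are excluded.
#' @param rhs optional function `y -> dy` overriding `ctx`.
#' @param tol eigenvalue tolerance.
#' @return logical flag.
#' @export
check_stability <- function(y, ctx = NULL, extinct_tol = 1e-5, rhs = NULL,
                            tol = 1e-8) {
  if (is.null(rhs)) {
    n_P <- ctx$n_P
    rhs <- function(z) .rhs_core(z[seq_len(n_P)], z[-seq_len(n_P)], ctx)
  }
  alive <- which(y > extinct_tol)
  if (length(alive) == 0L) return(TRUE)
  J <- jacobian_fd(function(z) { full <- y; full[alive] <- z; rhs(full)[alive] },
                   y[alive])
  ev <- eigen(J, only.values = TRUE)$values
  max(Re(ev)) < tol
}

#' Central-difference Jacobian
#'
#' @param f vector-valued function.
#' @param x evaluation point.
#' @param h_scale relative step size.
#' @return Jacobian matrix `d f_i / d x_j`.
#' @export
jacobian_fd <- function(f, x, h_scale = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- h_scale * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Network persistence
#'
#' Percentage of species whose equilibrium abundance exceeds the extinction
#' threshold (strictly greater).
#'
#' @param abundances nonnegative abundance vector (both guilds pooled).
#' @param extinct_tol extinction threshold (default 1e-5).
#' @return percentage in `[0, 100]`.
#' @export
persistence <- function(abundances, extinct_tol = 1e-5) {
  if (length(abundances) == 0L) stop("empty abundance vector", call. = FALSE)
  100 * sum(abundances > extinct_tol) / length(abundances)
}
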