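#' Cheating configuration
#'
#' Bundles the four cheating parameters: the proportion of pollinator species
#' cheating (`delta_bar`), the frequency with which those cheaters cheat
#' (`omega`), the proportion of innovative versus conservative cheating
#' (`psi`), and the per-interaction cost associated with mutualism
#' (`lambda_cost`). The cost is stored here but enters only the dynamics;
#' the mutualism condition `alpha > lambda_cost` is checked when the
#' configuration is paired with dynamics parameters.
#'
#' @param delta_bar proportion of pollinator species cheating, in `[0, 1]`.
#' @param omega cheating frequency of the cheaters, in `[0, 1]`.
#' @param psi proportion of innovative cheating, in `[0, 1]`; `1 - psi` is
#'   conservative.
#' @param lambda_cost per-interaction cost of mutualism, `>= 0`.
#' @param scenario which pollinators cheat: the most `"specialist"` or the
#'   most `"generalist"` species.
#' @return object of class `cheating_config`.
#' @export
cheating_config <- function(delta_bar, omega, psi, lambda_cost = 0,
                            scenario = c("specialist", "generalist")) {
  scenario <- match.arg(scenario)
  stopifnot_scalar_prob(delta_bar, "delta_bar")
  stopifnot_scalar_prob(omega, "omega")
  stopifnot_scalar_prob(psi, "psi")
  if (!is.numeric(lambda_cost) || length(lambda_cost) != 1L || lambda_cost < 0) {
    stop("`lambda_cost` must be a single number >= 0", call. = FALSE)
  }
  structure(list(delta_bar = delta_bar, omega = omega, psi = psi,
                 lambda_cost = lambda_cost, scenario = scenario),
            class = "cheating_config")
}

#' Legitimate interaction strengths
#'
#' A cheater diverts a fraction `omega` of its initial legitimate
#' interactions, so `M[i, j] = IM[i, j] * (1 - delta[j] * omega)`.
#'
#' @param IM binary backbone (plants x pollinators).
#' @param delta binary cheater flags per pollinator (or a `cheater_vector`).
#' @param omega cheating frequency in `[0, 1]`.
#' @return matrix `M` of legitimate per-capita strengths, zero off-backbone.
#' @export
legitimate_strengths <- function(IM, delta, omega) {
  delta <- .delta_flags(delta, ncol(IM))
  stopifnot_scalar_prob(omega, "omega")
  sweep(IM, 2L, 1 - delta * omega, `*`)
}

#' Cheating interaction strengths
#'
#' The diverted fraction `delta[j] * omega` of a cheater's interactions is
#' split into conservative cheating on existing mutualistic partners
#' (`(1 - psi)` share, on `IM = 1` cells) and innovative cheating on plants
#' outside the mutualistic niche (`psi` share, on `IM = 0` cells):
#' `C[i, j] = delta[j] * omega * ((1 - psi) * IM[i, j] + psi * (1 - IM[i, j]))`.
#'
#' @inheritParams legitimate_strengths
#' @param psi proportion of innovative cheating in `[0, 1]`.
#' @return matrix `C` of illegitimate per-capita strengths.
#' @export
cheating_strengths <- function(IM, delta, omega, psi) {
  delta <- .delta_flags(delta, ncol(IM))
  stopifnot_scalar_prob(omega, "omega")
  stopifnot_scalar_prob(psi, "psi")
  dw <- delta * omega
  sweep((1 - psi) * IM, 2L, dw, `*`) + sweep(psi * (1 - IM), 2L, dw, `*`)
}

#' Expand a community and cheating configuration into strength matrices
#'
#' @param community a [make_community()] object.
#' @param config a [cheating_config()] object.
#' @param seed tie-break seed forwarded to [assign_cheaters()].
#' @return list with `M`, `C`, and the realized `delta` cheater flags.
#' @export
strength_pair <- function(community, config, seed = community$seed) {
  cv <- assign_cheaters(community$IM, config$delta_bar, config$scenario,
                        seed = seed)
  list(M = legitimate_strengths(community$IM, cv$delta, config$omega),
       C = cheating_strengths(community$IM, cv$delta, config$omega, config$psi),
       delta = cv$delta)
}

.delta_flags <- function(delta, n_A) {
  if (inherits(delta, "cheater_vector")) delta <- delta$delta
  if (length(delta) != n_A || any(!delta %in% c(0, 1))) {
    stop("`delta` must be a binary vector with one flag per pollinator",
         call. = FALSE)
  }
  as.numeric(delta)
}
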