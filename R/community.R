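#' Draw Gaussian morphological traits
#'
#' One standard-normal trait per species in each guild. The trait positions
#' determine which plant-pollinator pairs can interact mutualistically (see
#' [build_backbone()]).
#'
#' @param n_P number of plant species.
#' @param n_A number of pollinator species.
#' @param seed RNG seed; the draw is reproducible for a fixed seed.
#' @return list with numeric vectors `plant` (length `n_P`) and `animal`
#'   (length `n_A`).
#' @export
draw_traits <- function(n_P, n_A, seed) {
  if (!is.numeric(n_P) || length(n_P) != 1L || n_P < 1 ||
      !is.numeric(n_A) || length(n_A) != 1L || n_A < 1) {
    stop("`n_P` and `n_A` must be positive counts", call. = FALSE)
  }
  set.seed(as.integer(seed))
  list(plant = stats::rnorm(n_P), animal = stats::rnorm(n_A))
}

# Trait-distance backbone for a given threshold d: a link exists where the
# plant and pollinator traits are within d of each other.
.backbone_at <- function(tp, ta, d) {
  outer(tp, ta, function(a, b) as.numeric(abs(a - b) <= d))
}

#' Build the binary mutualistic backbone at a target connectance
#'
#' Links are placed between trait-matching pairs: `IM[i, j] = 1` iff
#' `|plant_trait[i] - animal_trait[j] | <= d`, with the distance threshold `d`
#' found by bisection so that realized connectance is as close as possible to
#' the target `phi`. Species left isolated are given their single
#' nearest-trait partner. If the realized connectance still deviates from
#' `phi` by more than 0.05, traits are redrawn (up to `max_retries` times).
#' Trait-distance rules of this kind yield the nested structure typical of
#' Gaussian-trait mutualistic networks.
#'
#' @param traits list with `plant` and `animal` trait vectors
#'   (see [draw_traits()]).
#' @param phi target connectance in (0, 1].
#' @param seed RNG seed controlling trait redraws.
#' @param max_retries redraw budget before giving up.
#' @return binary matrix `n_P` x `n_A` with no empty rows or columns and
#'   `|mean(IM) - phi| <= 0.05`; the (possibly redrawn) traits are attached as
#'   attribute `"traits"`.
#' @export
build_backbone <- function(traits, phi, seed, max_retries = 50L) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi > 1) {
    stop("`phi` must be in (0, 1]", call. = FALSE)
  }
  tp <- traits$plant
  ta <- traits$animal
  n_P <- length(tp)
  n_A <- length(ta)
  for (attempt in seq_len(max_retries + 1L)) {
    IM <- .backbone_from_traits(tp, ta, phi)
    if (abs(mean(IM) - phi) <= 0.05) {
      dimnames(IM) <- list(paste0("P", seq_len(n_P)), paste0("A", seq_len(n_A)))
      attr(IM, "traits") <- list(plant = tp, animal = ta)
      return(IM)
    }
    set.seed(derive_seed(seed, attempt))
    tp <- stats::rnorm(n_P)
    ta <- stats::rnorm(n_A)
  }
  stop(sprintf(
    "could not reach connectance %.3g +/- 0.05 for %d x %d species after %d redraws",
    phi, n_P, n_A, max_retries), call. = FALSE)
}

.backbone_from_traits <- function(tp, ta, phi) {
  dist <- abs(outer(tp, ta, "-"))
  # Bisection on the threshold d; connectance is monotone in d, so search
  # between 0 (empty) and max distance (full).
  lo <- 0
  hi <- max(dist)
  target <- phi
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    if (mean(dist <= mid) < target) lo <- mid else hi <- mid
  }
  # Pick whichever bracket end realizes connectance closest to phi.
  cand <- c(lo, hi)
  realized <- vapply(cand, function(d) mean(dist <= d), numeric(1))
  d <- cand[which.min(abs(realized - phi))]
  IM <- (dist <= d) * 1
  # Reconnect isolated species through their nearest-trait partner.
  for (i in which(rowSums(IM) == 0)) IM[i, which.min(dist[i, ])] <- 1
  for (j in which(colSums(IM) == 0)) IM[which.min(dist[, j]), j] <- 1
  IM
}

#' Draw basal growth rates
#'
#' Growth rates are negative (obligatory mutualism: no guild persists alone)
#' and scaled to `[-0.5, -0.001]`. To sample a wide variety of growth-rate
#' vectors, each community draws its own beta-distribution shape parameters
#' `a, b ~ U[0.5, 5]`, draws `Beta(a, b)` values, and maps `[0, 1]` affinely
#' onto `[-0.5, -0.001]`.
#'
#' @param n number of species.
#' @param seed RNG seed.
#' @return numeric vector of length `n`, all values in `[-0.5, -0.001]`.
#' @export
draw_growth_rates <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  set.seed(as.integer(seed))
  shp <- stats::runif(2, 0.5, 5)
  x <- stats::rbeta(n, shp[1], shp[2])
  -0.5 + x * (0.5 - 0.001)
}

#' Assign cheater status to pollinators
#'
#' The number of cheaters is `round(delta_bar * n_A)` (half away from zero).
#' Under the `"specialist"` scenario the cheaters are the pollinators with
#' the fewest mutualistic partners (smallest column sums of `IM`); under
#' `"generalist"`, those with the most. Ties in degree are broken by a seeded
#' permutation of species indices so the assignment is reproducible.
#'
#' @param IM binary backbone matrix (plants x pollinators).
#' @param delta_bar target proportion of pollinator species cheating, in
#'   `[0, 1]`.
#' @param scenario `"specialist"` or `"generalist"`.
#' @param seed RNG seed for tie-breaking.
#' @return object of class `cheater_vector`: list with binary `delta` (length
#'   `n_A`), `scenario`, and `delta_bar`.
#' @export
assign_cheaters <- function(IM, delta_bar, scenario = c("specialist", "generalist"),
                            seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot_scalar_prob(delta_bar, "delta_bar")
  n_A <- ncol(IM)
  n_cheat <- round_half_away(delta_bar * n_A)
  degree <- colSums(IM)
  set.seed(derive_seed(seed, 7L))
  tie_break <- sample.int(n_A)
  ord <- order(if (scenario == "specialist") degree else -degree, tie_break)
  delta <- integer(n_A)
  if (n_cheat > 0) delta[ord[seq_len(n_cheat)]] <- 1L
  structure(list(delta = delta, scenario = scenario, delta_bar = delta_bar),
            class = "cheater_vector")
}

#' Generate a synthetic plant-pollinator community
#'
#' Bundles trait drawing, backbone construction and growth-rate drawing into
#' the community object consumed by the dynamics. All randomness flows from
#' `seed`, so a community is bit-reproducible.
#'
#' @param n_P,n_A guild sizes (plants, pollinators).
#' @param phi target connectance of the binary backbone.
#' @param seed RNG seed.
#' @return object of class `community`: list with `n_P`, `n_A`, `IM`,
#'   `plant_trait`, `animal_trait`, `r_P`, `r_A`, `phi`, `seed`.
#' @examples
#' com <- make_community(20, 20, phi = 0.4, seed = 1)
#' mean(com$IM)  # realized connectance, close to 0.4
#' @export
make_community <- function(n_P = 20L, n_A = 20L, phi = 0.4, seed = 1L) {
  traits <- draw_traits(n_P, n_A, seed = derive_seed(seed, 1L))
  IM <- build_backbone(traits, phi, seed = derive_seed(seed, 2L))
  traits <- attr(IM, "traits")  # possibly redrawn to hit connectance
  r_P <- draw_growth_rates(n_P, seed = derive_seed(seed, 3L))
  r_A <- draw_growth_rates(n_A, seed = derive_seed(seed, 4L))
  structure(list(
    n_P = as.integer(n_P), n_A = as.integer(n_A),
    IM = IM, plant_trait = traits$plant, animal_trait = traits$animal,
    r_P = r_P, r_A = r_A, phi = phi, seed = as.integer(seed)
  ), class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("Synthetic mutualistic community: %d plants x %d pollinators\n",
              x$n_P, x$n_A))
  cat(sprintf("  connectance %.3f (target %.3f), seed %d\n",
              mean(x$IM), x$phi, x$seed))
  cat(sprintf("  growth rates in [%.3f, %.3f]\n",
              min(x$r_P, x$r_A), max(x$r_P, x$r_A)))
  invisible(x)
}
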