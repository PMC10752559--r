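#' Proportion of cheater species at a site
#'
#' Share of bird species with at least one recorded illegitimate
#' interaction.
#'
#' @param network a `field_network` (see [generate_field_dataset()]).
#' @return fraction in `[0, 1]`.
#' @export
proportion_cheaters <- function(network) {
  n_birds <- ncol(network$illegit_freq)
  if (is.null(n_birds) || n_birds == 0L) stop("site has no birds", call. = FALSE)
  mean(colSums(network$illegit_freq) > 0)
}

#' Cheating frequency of a bird at a site
#'
#' Illegitimate interaction frequency divided by total interaction
#' frequency, both summed over all the bird's partners at the site.
#'
#' @param network a `field_network`.
#' @param bird bird name or column index; all birds when `NULL`.
#' @return proportion(s) in `[0, 1]`; `NA` for birds with zero total
#'   frequency (excluded from summaries).
#' @export
cheating_frequency <- function(network, bird = NULL) {
  ill <- colSums(network$illegit_freq)
  tot <- ill + colSums(network$legit_freq)
  out <- ifelse(tot > 0, ill / tot, NA_real_)
  if (is.null(bird)) out else out[[bird]]
}

#' Mutualistic partner diversity of each bird at a site
#'
#' Number of plant species with at least one recorded legitimate
#' interaction.
#'
#' @param network a `field_network`.
#' @return named integer vector.
#' @export
partner_diversity <- function(network) {
  colSums(network$legit_freq > 0)
}

#' Overall level of cheating at a site
#'
#' Illegitimate frequency divided by total frequency, both summed over all
#' plant-bird pairs of the site; the empirical counterpart of the
#' `delta_bar x omega` product of the dynamic model.
#'
#' @param network a `field_network`.
#' @return proportion in `[0, 1]`.
#' @export
overall_cheating <- function(network) {
  tot <- sum(network$legit_freq) + sum(network$illegit_freq)
  if (tot <= 0) stop("site has no recorded interactions", call. = FALSE)
  sum(network$illegit_freq) / tot
}

#' Proportion of innovative cheating of a bird
#'
#' Builds two weighted 2D kernel-density estimates over (corolla length,
#' curvature): the mutualistic niche, weighting each plant by its legitimate
#' interaction frequency with the bird, and the cheating space, weighted by
#' illegitimate frequencies. Interactions may be pooled over several sites.
#' Each density is normalized to sum to one on a shared grid; the overlap
#' (sum of the cell-wise minimum) is the proportion of conservative
#' cheating, and the innovative proportion is one minus the overlap. The
#' estimate is invariant to rescaling all of a bird's frequencies by a
#' positive constant. Plants with missing trait values are dropped (their
#' number is reported as attribute `"n_dropped"`).
#'
#' @param bird bird name.
#' @param networks a `field_network` or list of them.
#' @param bandwidth optional length-2 bandwidth (corolla, curvature);
#'   default is Silverman's rule per dimension on the weighted pooled
#'   points.
#' @param grid_n grid resolution per dimension (default 100).
#' @param pad fractional padding of the grid beyond the data range.
#' @return innovative proportion in `[0, 1]`, or `NA` when the bird lacks
#'   legitimate or illegitimate partners with trait data.
#' @export
innovative_proportion <- function(bird, networks, bandwidth = NULL,
                                  grid_n = 100L, pad = 0.1) {
  if (inherits(networks, "field_network")) networks <- list(networks)
  pts <- list(); wl <- list(); wi <- list()
  n_dropped <- 0L
  for (net in networks) {
    if (!bird %in% colnames(net$legit_freq)) next
    tr <- net$plant_traits
    ok <- is.finite(tr$corolla_length) & is.finite(tr$curvature)
    n_dropped <- n_dropped + sum(!ok)
    pts[[length(pts) + 1L]] <- cbind(tr$corolla_length[ok], tr$curvature[ok])
    wl[[length(wl) + 1L]] <- net$legit_freq[ok, bird]
    wi[[length(wi) + 1L]] <- net$illegit_freq[ok, bird]
  }
  P <- do.call(rbind, pts)
  w_leg <- unlist(wl); w_ill <- unlist(wi)
  if (is.null(P) || sum(w_leg) == 0 || sum(w_ill) == 0) {
    return(structure(NA_real_, n_dropped = n_dropped))
  }
  overlap <- kde2d_overlap(P, w_leg, w_ill, bandwidth = bandwidth,
                           grid_n = grid_n, pad = pad)
  structure(1 - overlap, n_dropped = n_dropped)
}

#' Overlap of two weighted 2D kernel densities
#'
#' Gaussian product kernels on a shared rectangular grid spanning the union
#' of the weighted point sets, padded by `pad` per side; each density is
#' normalized to sum to one over the grid and the overlap is the area under
#' the minimum of both (sum of cell-wise minima).
#'
#' @param points n x 2 matrix of coordinates.
#' @param w1,w2 nonnegative weight vectors (length n).
#' @param bandwidth length-2 bandwidths; `NULL` for Silverman's rule per
#'   dimension on the pooled weighted points (weighted sd and Kish effective
#'   sample size).
#' @param grid_n grid resolution per dimension.
#' @param pad fractional range padding.
#' @return overlap in `[0, 1]`.
#' @export
kde2d_overlap <- function(points, w1, w2, bandwidth = NULL, grid_n = 100L,
                          pad = 0.1) {
  use <- (w1 + w2) > 0
  points <- points[use, , drop = FALSE]
  w1 <- w1[use]; w2 <- w2[use]
  if (is.null(bandwidth)) {
    # one Silverman bandwidth per density: each niche is smoothed at its own
    # scale, so well-separated niches are not blurred into each other
    bw1 <- vapply(1:2, function(k) silverman_bw(points[, k], w1), numeric(1))
    bw2 <- vapply(1:2, function(k) silverman_bw(points[, k], w2), numeric(1))
  } else {
    bw1 <- bw2 <- rep_len(bandwidth, 2L)
  }
  rng <- apply(points, 2L, range)
  span <- pmax(rng[2, ] - rng[1, ], pmax(bw1, bw2), 1e-9)
  gx <- seq(rng[1, 1] - pad * span[1], rng[2, 1] + pad * span[1],
            length.out = grid_n)
  gy <- seq(rng[1, 2] - pad * span[2], rng[2, 2] + pad * span[2],
            length.out = grid_n)
  d1 <- .wkde2d(points, w1, gx, gy, bw1)
  d2 <- .wkde2d(points, w2, gx, gy, bw2)
  sum(pmin(d1 / sum(d1), d2 / sum(d2)))
}

# Weighted product-Gaussian KDE evaluated on the grid, unnormalized.
.wkde2d <- function(points, w, gx, gy, bw) {
  Kx <- outer(gx, points[, 1], function(g, p) stats::dnorm((g - p) / bw[1]))
  Ky <- outer(gy, points[, 2], function(g, p) stats::dnorm((g - p) / bw[2]))
  Kx %*% (w * t(Ky))
}

#' Weighted Silverman bandwidth
#'
#' Silverman's rule of thumb `0.9 * sigma * n_eff^(-1/5)` with the weighted
#' standard deviation and the Kish effective sample size
#' `(sum w)^2 / sum(w^2)`.
#'
#' @param x numeric vector.
#' @param w nonnegative weights.
#' @return bandwidth (floored at a small positive value for degenerate
#'   spreads).
#' @export
silverman_bw <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sigma <- sqrt(sum(w * (x - mu)^2))
  n_eff <- 1 / sum(w^2)
  max(0.9 * sigma * n_eff^(-1/5), 1e-3 * max(abs(x), 1))
}

#' Site-level and bird-level cheating-pattern estimates
#'
#' Applies all four estimators across a dataset: per site the proportion of
#' cheaters and the overall level of cheating; per (bird, site) the cheating
#' frequency and mutualistic partner diversity; per bird (pooled over
#' sites) the innovative proportion.
#'
#' @param dataset a `field_dataset`.
#' @param ... forwarded to [innovative_proportion()].
#' @return list with data frames `per_site`, `per_bird_site`, and `per_bird`.
#' @export
estimate_cheating_patterns <- function(dataset, ...) {
  per_site <- do.call(rbind, lapply(dataset$sites, function(net) {
    data.frame(site_id = net$site_id, elevation = net$elevation,
               proportion_cheaters = proportion_cheaters(net),
               overall_cheating = overall_cheating(net),
               total_frequency = sum(net$legit_freq) + sum(net$illegit_freq))
  }))
  per_bird_site <- do.call(rbind, lapply(dataset$sites, function(net) {
    cf <- cheating_frequency(net)
    data.frame(site_id = net$site_id, bird = names(cf),
               cheating_frequency = unname(cf),
               partner_diversity = unname(partner_diversity(net)),
               total_frequency = colSums(net$legit_freq) +
                 colSums(net$illegit_freq))
  }))
  birds <- sort(unique(per_bird_site$bird))
  psi_hat <- vapply(birds, function(b) {
    as.numeric(innovative_proportion(b, dataset$sites, ...))
  }, numeric(1))
  per_bird <- data.frame(bird = birds, innovative_proportion = psi_hat)
  list(per_site = per_site, per_bird_site = per_bird_site,
       per_bird = per_bird[!is.na(per_bird$innovative_proportion), ])
}
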