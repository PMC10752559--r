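#' Configuration of the synthetic field-data generator
#'
#' The generator emulates multi-site plant-bird interaction sampling with
#' camera traps over a tropical elevation gradient: per-pair legitimate and
#' illegitimate visit counts normalized by sampling hours, trait-matched
#' mutualistic niches (birds visit legitimately the plants whose corolla
#' their bill can reach), cheating that is predominantly innovative
#' (`psi_true`), more frequent in birds with few mutualistic partners
#' (`diversity_slope` < 0 on the logit of cheating frequency against log
#' partner diversity), and an overall level of cheating that declines with
#' elevation (`elevation_slope` < 0 on the logit, per standardized
#' elevation).
#'
#' @param n_sites number of sites along the gradient (default 17, as in a
#'   two-country camera-trap campaign).
#' @param elevation_range range in meters a.s.l.
#' @param n_plants,n_birds species-pool sizes per site.
#' @param mean_hours mean camera-sampling hours per plant.
#' @param dispersion negative-binomial size parameter of the visit counts
#'   (camera-trap counts are overdispersed).
#' @param psi_true proportion of innovative cheating the generator aims for.
#' @param omega_base logit-scale intercept of the cheating frequency.
#' @param diversity_slope logit-scale slope of cheating frequency against
#'   log partner diversity (negative: specialists cheat more).
#' @param elevation_slope logit-scale slope of cheating against
#'   standardized elevation (negative: cheating declines uphill).
#' @param cheater_base logit-scale intercept of the probability that a bird
#'   is a cheater at a site.
#' @param connectance_target fraction of plant-bird pairs with a legitimate
#'   link (sparsity of the network).
#' @param pool_plants,pool_birds regional species-pool sizes from which each
#'   site draws its community; species keep their traits across sites.
#' @return list of class `field_config`.
#' @export
field_config <- function(n_sites = 17L, elevation_range = c(700, 3500),
                         n_plants = 15L, n_birds = 10L, mean_hours = 200,
                         dispersion = 2, psi_true = 0.9,
                         omega_base = -1.2, diversity_slope = -0.8,
                         elevation_slope = -1.0, cheater_base = 0.8,
                         connectance_target = 0.3,
                         pool_plants = 45L, pool_birds = 25L) {
  structure(as.list(environment()), class = "field_config")
}

#' Generate a synthetic multi-site field dataset
#'
#' For each site, plant flowers get a corolla length (log-normal, mm) and a
#' curvature, birds get a bill length; a legitimate link is feasible where
#' the corolla is not longer than the bill can handle, pruned to the target
#' sparsity (every bird keeps at least one legitimate partner). Visit counts
#' are negative-binomial around per-pair daily rates and sampling hours, and
#' converted to frequencies by the `counts / hours * 24` rule. Cheating
#' birds divert visits: a share `psi_true` to plants outside the convex hull
#' of their legitimate partners in (corolla length, curvature) space
#' (weighted by distance from the hull), the rest onto their legitimate
#' partners. Per-bird cheating frequency decreases with partner diversity
#' and with elevation per the configured logit-linear slopes. Generator
#' ground truth is stored with the data for recovery tests.
#'
#' @param config a [field_config()].
#' @param seed RNG seed.
#' @return object of class `field_dataset`: list of `sites` (each a
#'   `field_network`) and `ground_truth`.
#' @export
generate_field_dataset <- function(config = field_config(), seed = 1L) {
  elev <- seq(config$elevation_range[1], config$elevation_range[2],
              length.out = config$n_sites)
  elev_z <- if (config$n_sites > 1) (elev - mean(elev)) / stats::sd(elev) else 0
  # regional species pool: traits and pairwise mutualistic abilities are
  # species(-pair) properties, stable across sites; sites differ in which
  # species are present and in sampling noise
  set.seed(derive_seed(seed, 0L))
  pool <- list(
    plant_id = sprintf("plant_%02d", seq_len(config$pool_plants)),
    corolla = stats::rlnorm(config$pool_plants, log(25), 0.45),
    curvature = stats::rbeta(config$pool_plants, 2, 5) * 60,
    bird_id = sprintf("bird_%02d", seq_len(config$pool_birds)),
    bill = stats::rlnorm(config$pool_birds, log(27), 0.30))
  # legitimate niche: corolla reachable by the bill, thinned to the target
  # sparsity; per-pair daily visit rates on the kept links
  feasible <- outer(pool$corolla, pool$bill, function(co, bi) co <= 1.15 * bi)
  keep_p <- min(1, config$connectance_target / max(mean(feasible), 1e-9))
  legit <- feasible &
    matrix(stats::runif(length(feasible)) < keep_p, nrow(feasible))
  for (j in which(colSums(legit) == 0)) {
    legit[which.min(pool$corolla / pool$bill[j]), j] <- TRUE
  }
  pool$rate <- matrix(0, config$pool_plants, config$pool_birds)
  pool$rate[legit] <- pmax(stats::rgamma(sum(legit), 1.5, 1.5), 0.05)
  sites <- vector("list", config$n_sites)
  truth <- vector("list", config$n_sites)
  any_out_of_niche <- FALSE
  any_cheating <- FALSE
  for (s in seq_len(config$n_sites)) {
    set.seed(derive_seed(seed, s))
    net <- .generate_site(config, s, elev[s], elev_z[s], pool)
    sites[[s]] <- net$network
    truth[[s]] <- net$truth
    any_out_of_niche <- any_out_of_niche || net$truth$had_out_of_niche
    any_cheating <- any_cheating || any(net$truth$omega_true > 0)
  }
  if (config$psi_true > 0 && any_cheating && !any_out_of_niche) {
    stop("infeasible config: psi_true > 0 but no site offers out-of-niche ",
         "plants for any cheater", call. = FALSE)
  }
  structure(list(
    sites = sites,
    ground_truth = list(per_site = truth, psi_true = config$psi_true,
                        diversity_slope = config$diversity_slope,
                        elevation_slope = config$elevation_slope)
  ), class = "field_dataset")
}

.generate_site <- function(config, s, elevation, elev_z, pool) {
  nP <- min(config$n_plants, config$pool_plants)
  p_idx <- sort(sample.int(config$pool_plants, nP))
  # birds present: a sample of the pool, kept only if a mutualistic partner
  # grows at the site (every bird needs >= 1 legitimate link)
  b_cand <- sort(sample.int(config$pool_birds,
                            min(config$n_birds, config$pool_birds)))
  b_idx <- b_cand[colSums(pool$rate[p_idx, b_cand, drop = FALSE] > 0) > 0]
  if (length(b_idx) == 0L) {
    b_idx <- b_cand[which.max(colSums(pool$rate[p_idx, b_cand, drop = FALSE]))]
    i_star <- p_idx[which.max(pool$rate[p_idx, b_idx])]
    if (pool$rate[i_star, b_idx] == 0) pool$rate[i_star, b_idx] <- 0.05
  }
  nB <- length(b_idx)
  corolla <- pool$corolla[p_idx]                       # mm
  curvature <- pool$curvature[p_idx]                   # degrees-like index
  bill <- pool$bill[b_idx]                             # mm
  hours <- stats::runif(nP, 0.5, 1.5) * config$mean_hours
  rate <- pool$rate[p_idx, b_idx, drop = FALSE]        # day^-1
  diversity <- colSums(rate > 0)
  cheater <- stats::runif(nB) < stats::plogis(config$cheater_base +
                                              config$elevation_slope * elev_z)
  omega <- stats::plogis(config$omega_base +
                         config$diversity_slope * (log(diversity) - log(3)) +
                         config$elevation_slope * elev_z)
  omega[!cheater] <- 0
  # illegitimate daily rates: R_j with R/(R+L) = omega_j
  illegit_rate <- matrix(0, nP, nB)
  had_out <- FALSE
  for (j in seq_len(nB)) {
    if (omega[j] <= 0) next
    L <- sum(rate[, j])
    R <- omega[j] / (1 - omega[j]) * L
    partners <- rate[, j] > 0
    w_out <- .out_of_niche_weights(corolla, curvature, partners)
    psi_j <- if (any(w_out > 0)) config$psi_true else 0
    had_out <- had_out || any(w_out > 0)
    if (psi_j > 0) {
      illegit_rate[, j] <- illegit_rate[, j] + psi_j * R * w_out / sum(w_out)
    }
    if (psi_j < 1) {
      illegit_rate[partners, j] <- illegit_rate[partners, j] +
        (1 - psi_j) * R * rate[partners, j] / L
    }
  }
  draw_counts <- function(rates) {
    mu <- sweep(rates, 1L, hours / 24, `*`)
    cnt <- matrix(0L, nP, nB)
    pos <- mu > 0
    cnt[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = config$dispersion)
    cnt
  }
  legit_counts <- draw_counts(rate)
  # keep every bird observed at least once legitimately
  for (j in which(colSums(legit_counts) == 0)) {
    i <- which.max(rate[, j])
    legit_counts[i, j] <- 1L
  }
  illegit_counts <- draw_counts(illegit_rate)
  plant_ids <- pool$plant_id[p_idx]
  bird_ids <- pool$bird_id[b_idx]
  dn <- list(plant_ids, bird_ids)
  dimnames(legit_counts) <- dn; dimnames(illegit_counts) <- dn
  network <- structure(list(
    site_id = sprintf("site_%02d", s),
    elevation = elevation,
    legit_freq = normalize_counts(legit_counts, hours),
    illegit_freq = normalize_counts(illegit_counts, hours),
    legit_counts = legit_counts, illegit_counts = illegit_counts,
    sampling_hours = stats::setNames(hours, plant_ids),
    plant_traits = data.frame(plant = plant_ids, corolla_length = corolla,
                              curvature = curvature),
    bird_bill_length = stats::setNames(bill, bird_ids)
  ), class = "field_network")
  list(network = network,
       truth = list(site_id = network$site_id, elevation = elevation,
                    cheater = stats::setNames(cheater, bird_ids),
                    omega_true = stats::setNames(omega, bird_ids),
                    had_out_of_niche = had_out))
}

# Innovative-cheating placement weights: distance of each non-partner plant
# from the convex hull of the bird's legitimate partners in standardized
# (corolla length, curvature) space. Only plants strictly outside the hull
# are eligible (cheating inside the trait niche is conservative in kind),
# weighted by their distance so the out-of-niche bias grows with trait
# mismatch.
.out_of_niche_weights <- function(corolla, curvature, partners) {
  pts <- cbind(corolla / stats::sd(corolla),
               curvature / max(stats::sd(curvature), 1e-9))
  w <- numeric(length(corolla))
  out <- !partners
  if (!any(out)) return(w)
  d <- vapply(which(out), function(i) {
    .hull_distance(pts[i, ], pts[partners, , drop = FALSE])
  }, numeric(1))
  w[out] <- d^2
  w
}

# Euclidean distance from point p to the convex hull of points X (0 inside).
.hull_distance <- function(p, X) {
  if (nrow(X) == 1L) return(sqrt(sum((p - X[1, ])^2)))
  if (nrow(X) == 2L) return(.seg_dist(p, X[1, ], X[2, ]))
  h <- grDevices::chull(X)
  V <- X[h, , drop = FALSE]
  if (.in_hull(p, V)) return(0)
  k <- nrow(V)
  min(vapply(seq_len(k), function(i) {
    .seg_dist(p, V[i, ], V[if (i == k) 1L else i + 1L, ])
  }, numeric(1)))
}

.seg_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

# Point-in-convex-polygon test (vertices in hull order).
.in_hull <- function(p, V) {
  k <- nrow(V)
  s <- vapply(seq_len(k), function(i) {
    a <- V[i, ]; b <- V[if (i == k) 1L else i + 1L, ]
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }, numeric(1))
  all(s <= 1e-12) || all(s >= -1e-12)
}

#' Convert visit counts to daily interaction frequencies
#'
#' `frequency = counts / sampling_hours * 24`, in interactions per day.
#'
#' @param counts matrix (plants x birds) or vector of visit counts.
#' @param hours sampling hours per plant (recycled along rows for a matrix).
#' @return frequencies with the same shape as `counts`.
#' @export
normalize_counts <- function(counts, hours) {
  if (any(hours <= 0 & .row_totals(counts) > 0)) {
    stop("zero or negative sampling hours with nonzero counts", call. = FALSE)
  }
  hours_safe <- ifelse(hours > 0, hours, 1)
  if (is.matrix(counts)) {
    sweep(counts, 1L, hours_safe, `/`) * 24
  } else {
    counts / hours_safe * 24
  }
}

.row_totals <- function(counts) {
  if (is.matrix(counts)) rowSums(counts) else counts
}

#' @export
print.field_dataset <- function(x, ...) {
  ele <- vapply(x$sites, `[[`, numeric(1), "elevation")
  cat(sprintf("Synthetic field dataset: %d sites, %.0f-%.0f m a.s.l.\n",
              length(x$sites), min(ele), max(ele)))
  cat(sprintf("  generator truth: psi %.2f, diversity slope %.2f, elevation slope %.2f\n",
              x$ground_truth$psi_true, x$ground_truth$diversity_slope,
              x$ground_truth$elevation_slope))
  invisible(x)
}

#' Write / read a field dataset as per-site TSV directories
#'
#' Each site gets a directory with `legitimate.tsv` and `illegitimate.tsv`
#' (frequency matrices), `plants.tsv` (traits and sampling hours),
#' `birds.tsv` (bill lengths) and `site.json` (elevation); the dataset root
#' gets `ground_truth.json`.
#'
#' @param dataset a `field_dataset`.
#' @param path directory to create.
#' @return `path`, invisibly (`write`); a `field_dataset` without counts
#'   (`read`).
#' @export
write_field_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (net in dataset$sites) {
    d <- file.path(path, net$site_id)
    dir.create(d, showWarnings = FALSE)
    write_matrix_tsv(net$legit_freq, file.path(d, "legitimate.tsv"))
    write_matrix_tsv(net$illegit_freq, file.path(d, "illegitimate.tsv"))
    plants <- cbind(net$plant_traits,
                    sampling_hours = unname(net$sampling_hours))
    utils::write.table(plants, file.path(d, "plants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(bird = names(net$bird_bill_length),
                 bill_length = unname(net$bird_bill_length)),
      file.path(d, "birds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(site_id = net$site_id,
                              elevation = net$elevation),
                         file.path(d, "site.json"), auto_unbox = TRUE)
  }
  jsonlite::write_json(dataset$ground_truth,
                       file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_dataset
#' @param path directory produced by [write_field_dataset()].
#' @export
read_field_dataset <- function(path) {
  site_dirs <- list.dirs(path, recursive = FALSE)
  sites <- lapply(site_dirs, function(d) {
    meta <- jsonlite::read_json(file.path(d, "site.json"))
    plants <- utils::read.delim(file.path(d, "plants.tsv"))
    birds <- utils::read.delim(file.path(d, "birds.tsv"))
    structure(list(
      site_id = meta$site_id, elevation = meta$elevation,
      legit_freq = read_matrix_tsv(file.path(d, "legitimate.tsv")),
      illegit_freq = read_matrix_tsv(file.path(d, "illegitimate.tsv")),
      sampling_hours = stats::setNames(plants$sampling_hours, plants$plant),
      plant_traits = plants[, c("plant", "corolla_length", "curvature")],
      bird_bill_length = stats::setNames(birds$bill_length, birds$bird)
    ), class = "field_network")
  })
  truth <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                               simplifyVector = TRUE)
  structure(list(sites = sites, ground_truth = truth),
            class = "field_dataset")
}
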