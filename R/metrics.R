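#' Connectance of a binary interaction matrix
#'
#' @param IM binary matrix.
#' @return realized links divided by all possible links.
#' @export
connectance <- function(IM) {
  if (length(IM) == 0L) stop("empty matrix", call. = FALSE)
  mean(IM != 0)
}

#' NODF nestedness
#'
#' Binary NODF (nestedness based on overlap and decreasing fill): for every
#' ordered pair of rows with strictly decreasing fill, the paired overlap is
#' the share of the sparser row's links also present in the denser row (x100);
#' pairs with equal fill contribute zero. Same over column pairs; NODF is the
#' mean over all row and column pairs.
#'
#' @param IM binary matrix with no empty rows or columns.
#' @return score in `[0, 100]`.
#' @export
nodf <- function(IM) {
  IM <- (IM != 0) * 1
  if (any(rowSums(IM) == 0) || any(colSums(IM) == 0)) {
    stop("NODF is undefined with empty rows or columns; prune first",
         call. = FALSE)
  }
  mean(c(.nodf_pairs(IM), .nodf_pairs(t(IM))))
}

# Paired-overlap contributions over all row pairs of X.
.nodf_pairs <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(numeric(0))
  fill <- rowSums(X)
  shared <- X %*% t(X)
  out <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      lo_fill <- min(fill[i], fill[j])
      out[k] <- if (fill[i] == fill[j]) 0 else 100 * shared[i, j] / lo_fill
    }
  }
  out
}

# Barber bipartite modularity of a given partition. Labels are shared across
# guilds: row_lab (length n_P) and col_lab (length n_A).
barber_Q <- function(IM, row_lab, col_lab) {
  m <- sum(IM)
  if (m == 0) return(0)
  ki <- rowSums(IM)
  dj <- colSums(IM)
  B <- IM - outer(ki, dj) / m
  same <- outer(row_lab, col_lab, "==")
  sum(B[same]) / m
}

#' Bipartite modularity (Barber's Q)
#'
#' Finds a module partition of the bipartite network maximizing Barber's
#' modularity with a label-propagation + agglomeration heuristic in the
#' spirit of LPAwb+: labels are seeded on the rows, propagated back and forth
#' by greedy Q-improving moves until stationary, and the resulting modules
#' are then greedily merged while any merge increases Q. The best partition
#' over `restarts` seeded initializations is returned; results are
#' deterministic for a fixed seed, and Q never decreases as `restarts` grows.
#' For small networks (<= 12 species total) `method = "exhaustive"` searches
#' all assignments into up to `max_modules` modules.
#'
#' @param IM binary matrix.
#' @param seed RNG seed for the restarts.
#' @param restarts number of label-propagation restarts (default 20).
#' @param method `"lpa"` (default) or `"exhaustive"` (small matrices only).
#' @param max_modules module cap for the exhaustive search.
#' @return list with `Q` and `labels` (list of `row` and `col` integer
#'   labels).
#' @export
bipartite_modularity <- function(IM, seed = 1L, restarts = 20L,
                                 method = c("lpa", "exhaustive"),
                                 max_modules = 4L) {
  method <- match.arg(method)
  IM <- (IM != 0) * 1
  if (method == "exhaustive") {
    n <- nrow(IM) + ncol(IM)
    if (n > 12L) stop("exhaustive search only for <= 12 species", call. = FALSE)
    return(.modularity_exhaustive(IM, max_modules))
  }
  best <- list(Q = -Inf, labels = NULL)
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r))
    cand <- .lpa_once(IM)
    if (cand$Q > best$Q) best <- cand
  }
  best
}

.lpa_once <- function(IM) {
  n_P <- nrow(IM); n_A <- ncol(IM)
  row_lab <- sample.int(n_P)      # seeded random initial labels on rows
  col_lab <- rep(NA_integer_, n_A)
  # initial column labels: best row label among neighbours
  for (j in seq_len(n_A)) {
    nb <- which(IM[, j] > 0)
    col_lab[j] <- if (length(nb)) row_lab[nb[1]] else n_P + j
  }
  m <- sum(IM)
  ki <- rowSums(IM); dj <- colSums(IM)
  repeat {
    changed <- FALSE
    # move each column to the label maximizing its Q contribution
    for (j in seq_len(n_A)) {
      labs <- unique(c(row_lab, col_lab[j]))
      gain <- vapply(labs, function(L) {
        sel <- row_lab == L
        sum(IM[sel, j]) - dj[j] * sum(ki[sel]) / m
      }, numeric(1))
      newl <- labs[which.max(gain)]
      if (newl != col_lab[j]) { col_lab[j] <- newl; changed <- TRUE }
    }
    for (i in seq_len(n_P)) {
      labs <- unique(c(col_lab, row_lab[i]))
      gain <- vapply(labs, function(L) {
        sel <- col_lab == L
        sum(IM[i, sel]) - ki[i] * sum(dj[sel]) / m
      }, numeric(1))
      newl <- labs[which.max(gain)]
      if (newl != row_lab[i]) { row_lab[i] <- newl; changed <- TRUE }
    }
    if (!changed) break
  }
  # agglomeration stage: merge module pairs while Q increases
  repeat {
    labs <- unique(c(row_lab, col_lab))
    Q0 <- barber_Q(IM, row_lab, col_lab)
    best_gain <- 0; best_pair <- NULL
    if (length(labs) > 1L) {
      for (a in seq_along(labs)[-length(labs)]) {
        for (b in (a + 1):length(labs)) {
          rl <- row_lab; cl <- col_lab
          rl[rl == labs[b]] <- labs[a]
          cl[cl == labs[b]] <- labs[a]
          g <- barber_Q(IM, rl, cl) - Q0
          if (g > best_gain + 1e-12) { best_gain <- g; best_pair <- c(a, b) }
        }
      }
    }
    if (is.null(best_pair)) break
    row_lab[row_lab == labs[best_pair[2]]] <- labs[best_pair[1]]
    col_lab[col_lab == labs[best_pair[2]]] <- labs[best_pair[1]]
  }
  list(Q = barber_Q(IM, row_lab, col_lab),
       labels = list(row = row_lab, col = col_lab))
}

.modularity_exhaustive <- function(IM, max_modules) {
  n_P <- nrow(IM); n_A <- ncol(IM)
  n <- n_P + n_A
  K <- min(max_modules, n)
  best <- list(Q = -Inf, labels = NULL)
  idx <- rep(1L, n)
  repeat {
    rl <- idx[seq_len(n_P)]; cl <- idx[n_P + seq_len(n_A)]
    Q <- barber_Q(IM, rl, cl)
    if (Q > best$Q) best <- list(Q = Q, labels = list(row = rl, col = cl))
    # next assignment in base K
    p <- 1L
    while (p <= n) {
      idx[p] <- idx[p] + 1L
      if (idx[p] <= K) break
      idx[p] <- 1L
      p <- p + 1L
    }
    if (p > n) break
  }
  best
}

#' Structural report of a binary backbone
#'
#' @param IM binary matrix.
#' @param seed,restarts forwarded to [bipartite_modularity()].
#' @return list with `connectance`, `nodf`, `modularity`, `module_assignment`.
#' @export
structure_report <- function(IM, seed = 1L, restarts = 20L) {
  mod <- bipartite_modularity(IM, seed = seed, restarts = restarts)
  list(connectance = connectance(IM), nodf = nodf(IM),
       modularity = mod$Q, module_assignment = mod$labels)
}
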