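# Small deterministic fixtures shared across test files.

# 2-species system (1 plant, 1 pollinator, IM = 1, no cheating) used as the
# analytically tractable oracle case. r = -0.02 admits a stable interior
# equilibrium (2x^2 - (0.5 + 2r)x - r = 0 has real roots); much more
# negative rates make extinction the only equilibrium.
two_species_system <- function(r = -0.02, alpha = 1.5, beta = 1, c_interf = 1) {
  list(
    M = matrix(1, 1, 1), C = matrix(0, 1, 1),
    r_P = r, r_A = r, delta = 0L,
    params = dynamics_params(alpha = alpha, beta = beta, c_interf = c_interf)
  )
}

# RHS of the 2-species system as plain closed-form functions of (P, A),
# written independently of the package RHS code.
two_species_rhs <- function(x, r = -0.02, alpha = 1.5, beta = 1) {
  P <- x[1]; A <- x[2]
  # single pair: similarity matrices are 1x1 identities
  dP <- P * (r + alpha * A / (1 + beta * A + P) - P)
  dA <- A * (r + alpha * P / (1 + beta * P + A) - A)
  c(dP, dA)
}

# A tiny field network with hand-countable entries.
toy_field_network <- function() {
  legit <- matrix(c(8, 0,
                    0, 4,
                    2, 0), nrow = 3, byrow = TRUE,
                  dimnames = list(paste0("plant_", 1:3), paste0("bird_", 1:2)))
  illegit <- matrix(c(2, 0,
                      0, 1,
                      0, 0), nrow = 3, byrow = TRUE,
                    dimnames = dimnames(legit))
  structure(list(
    site_id = "toy", elevation = 1000,
    legit_freq = legit, illegit_freq = illegit,
    sampling_hours = stats::setNames(rep(24, 3), rownames(legit)),
    plant_traits = data.frame(plant = rownames(legit),
                              corolla_length = c(10, 20, 40),
                              curvature = c(5, 10, 30)),
    bird_bill_length = stats::setNames(c(15, 25), colnames(legit))
  ), class = "field_network")
}

# Random binary matrix with no empty rows/columns.
random_backbone <- function(n_r, n_c, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    X <- matrix(rbinom(n_r * n_c, 1, p), n_r, n_c)
    if (all(rowSums(X) > 0) && all(colSums(X) > 0)) return(X)
  }
}

# Naive NODF: explicit loops over ordered pairs, used as an oracle.
nodf_bruteforce_accept <- function(X) {
  contrib <- function(M) {
    n <- nrow(M)
    out <- c()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) {
        fi <- sum(M[i, ]); fj <- sum(M[j, ])
        if (fi == fj) {
          out <- c(out, 0)
        } else {
          lo <- if (fi > fj) j else i
          shared <- sum(M[i, ] == 1 & M[j, ] == 1)
          out <- c(out, 100 * shared / sum(M[lo, ]))
        }
      }
    }
    out
  }
  mean(c(contrib(X), contrib(t(X))))
}
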