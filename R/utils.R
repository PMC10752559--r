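#' Round half away from zero
#'
#' Deterministic rounding used wherever a proportion is converted to a count
#' (e.g. the number of cheaters), avoiding platform-dependent banker's
#' rounding of [base::round()].
#'
#' @param x numeric vector.
#' @return integer vector, |x| rounded up at exact .5.
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Derive a child seed from a base seed and integer indices, staying below
# 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

logit <- function(p) log(p / (1 - p))
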