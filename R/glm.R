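#' Logit-link GLM trend fit for proportion data
#'
#' Iteratively reweighted least squares for a binomial or quasibinomial GLM
#' with logit link, used for the cheating-pattern trend analyses: proportion
#' responses (cheating frequency, proportion of cheaters, overall cheating)
#' with total interaction frequencies as binomial weights. Under the
#' quasibinomial family the coefficient covariance is scaled by the Pearson
#' dispersion estimate. Each model term is screened with a Wald chi-squared
#' test (all coefficients of the term jointly zero, full-model covariance);
#' with at most one interaction and centered predictors this matches the
#' type II Wald analysis-of-deviance table.
#'
#' @param formula model formula; the response is a proportion in `[0, 1]`.
#' @param data data frame.
#' @param weights binomial denominators (e.g. total interaction frequency);
#'   defaults to 1.
#' @param family `"quasibinomial"` or `"binomial"`.
#' @param max_iter,tol IRLS controls.
#' @return object of class `glm_trend`: list with `coefficients` (estimate,
#'   std_error, z or t value), `vcov`, `dispersion`, `wald` (per-term
#'   chi-squared, df, p), `converged`, `fitted`, and the model frame.
#' @export
glm_trend <- function(formula, data, weights = NULL,
                      family = c("quasibinomial", "binomial"),
                      max_iter = 50L, tol = 1e-10) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  w_prior <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1)) {
    stop("response must be proportions in [0, 1]", call. = FALSE)
  }
  beta <- numeric(ncol(X))
  # intercept warm start
  mu0 <- min(max(stats::weighted.mean(y, w_prior), 1e-3), 1 - 1e-3)
  if ("(Intercept)" %in% colnames(X)) beta[1] <- logit(mu0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    W <- w_prior * mu * (1 - mu)        # logit link: var = mu(1-mu), dmu/deta same
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtWX <- crossprod(X, W * X)
    fit <- tryCatch(solve(XtWX, crossprod(X, W * z)), error = function(e) NULL)
    if (is.null(fit)) {
      stop("IRLS normal equations are singular (separation or collinearity)",
           call. = FALSE)
    }
    delta <- max(abs(fit - beta))
    beta <- drop(fit)
    if (delta < tol * max(1, max(abs(beta)))) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  pearson <- sum(w_prior * (y - mu)^2 / pmax(mu * (1 - mu), 1e-12))
  df_resid <- n - ncol(X)
  dispersion <- if (family == "quasibinomial") pearson / df_resid else 1
  W <- w_prior * mu * (1 - mu)
  vcov <- solve(crossprod(X, W * X)) * dispersion
  se <- sqrt(diag(vcov))
  coefs <- data.frame(estimate = beta, std_error = se,
                      statistic = beta / se, row.names = colnames(X))
  # per-term Wald chi-squared
  assign <- attr(X, "assign")
  terms_lab <- attr(stats::terms(formula, data = data), "term.labels")
  wald <- do.call(rbind, lapply(seq_along(terms_lab), function(k) {
    idx <- which(assign == k)
    stat <- tryCatch(
      drop(t(beta[idx]) %*% solve(vcov[idx, idx, drop = FALSE], beta[idx])),
      error = function(e) NA_real_)  # degenerate fit (zero dispersion)
    data.frame(term = terms_lab[k], chisq = stat, df = length(idx),
               p_value = stats::pchisq(stat, length(idx), lower.tail = FALSE))
  }))
  structure(list(coefficients = coefs, vcov = vcov, dispersion = dispersion,
                 wald = wald, converged = converged, fitted = mu,
                 family = family, formula = formula, model = mf,
                 weights = w_prior),
            class = "glm_trend")
}

#' @export
print.glm_trend <- function(x, ...) {
  cat(sprintf("%s logit GLM%s (dispersion %.3f)\n", x$family,
              if (x$converged) "" else " [NOT CONVERGED]", x$dispersion))
  print(round(x$coefficients, 4))
  cat("Wald tests:\n")
  print(x$wald, row.names = FALSE)
  invisible(x)
}

#' @export
coef.glm_trend <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' Elevation and diversity trends of cheating patterns
#'
#' Fits the three trend models of the empirical analysis: proportion of
#' cheaters and overall cheating against elevation (quasibinomial, site
#' level, weighted by total site frequency), and cheating frequency against
#' log partner diversity (binomial, bird x site level, weighted by the
#' bird's total frequency). The latter is the fixed-effects analogue of a
#' mixed model with site and bird intercepts.
#'
#' @param estimates output of [estimate_cheating_patterns()].
#' @return list of three `glm_trend` fits: `cheaters_vs_elevation`,
#'   `overall_vs_elevation`, `frequency_vs_diversity`.
#' @export
cheating_trends <- function(estimates) {
  ps <- estimates$per_site
  pbs <- estimates$per_bird_site
  pbs <- pbs[is.finite(pbs$cheating_frequency) & pbs$partner_diversity > 0, ]
  pbs$log_diversity <- log(pbs$partner_diversity)
  list(
    cheaters_vs_elevation = glm_trend(
      proportion_cheaters ~ elevation, ps,
      weights = ps$total_frequency, family = "quasibinomial"),
    overall_vs_elevation = glm_trend(
      overall_cheating ~ elevation, ps,
      weights = ps$total_frequency, family = "quasibinomial"),
    frequency_vs_diversity = glm_trend(
      cheating_frequency ~ log_diversity, pbs,
      weights = pbs$total_frequency, family = "binomial")
  )
}
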