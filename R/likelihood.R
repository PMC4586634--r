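#' Model structure specification
#'
#' Describes which of the candidate model structures is fit: fixed-effect
#' versus random-intercept rate models, crossed with how the
#' misclassification is treated. The four corrected models of interest are
#' fixed/known, fixed/unknown, random/known and random/unknown; `misclass =
#' "none"` is the naive analysis that takes the observed labels at face
#' value (se = sp = 1).
#'
#' @param effects `"fixed"` (no random intercepts), `"random"`
#'   (cluster random intercepts on both log-rates with a common standard
#'   deviation sigma), or `"correlated"` (bivariate normal intercepts with
#'   sigma1, sigma2 and correlation rho).
#' @param misclass `"unknown"` (beta priors on se and sp), `"known"` (fixed
#'   values supplied at fit time), or `"none"` (naive, se = sp = 1).
#' @param p number of non-exposure covariates.
#' @return An object of class `"mcpois_spec"`.
#' @export
mcpois_spec <- function(effects = c("fixed", "random", "correlated"),
                        misclass = c("unknown", "known", "none"),
                        p = 0L) {
  effects <- match.arg(effects)
  misclass <- match.arg(misclass)
  structure(list(effects = effects, misclass = misclass, p = as.integer(p)),
            class = "mcpois_spec")
}

effects_code <- function(effects)
  match(effects, c("fixed", "random", "correlated")) - 1L
misclass_code <- function(misclass)
  match(misclass, c("none", "known", "unknown")) - 1L

#' Cause-specific rates implied by a parameter state
#'
#' Evaluates the log-linear rate models for the two cause-specific streams:
#' `lambda_i = exp(beta0 + beta1 x_i + z_i' beta (+ eA_k))` for the cause of
#' interest and the analogous `mu_i` with the `gamma` coefficients (and
#' `eB_k`). Rates are per unit person-time; expected counts are `t_i *
#' rate`.
#'
#' @param state a named list with elements `beta`, `gamma` (coefficient
#'   vectors, intercept first, exposure second) and, for random-intercept
#'   specs, `e_lambda`, `e_mu` (one entry per cluster).
#' @param data an [mcp_data] object.
#' @param spec an [mcpois_spec].
#' @return A list with positive vectors `lambda` and `mu`.
#' @export
case_rates <- function(state, data, spec) {
  X <- design_matrix(data)
  q <- ncol(X)
  if (length(state$beta) != q || length(state$gamma) != q)
    stop("coefficient length ", length(state$beta), " does not match the ",
         q, "-column design")
  eta_l <- drop(X %*% state$beta)
  eta_m <- drop(X %*% state$gamma)
  if (spec$effects != "fixed") {
    if (is.null(data$cluster))
      stop("random-intercept spec requires cluster labels in the data")
    K <- max(data$cluster)
    if (length(state$e_lambda) != K || length(state$e_mu) != K)
      stop("random-effect vectors must have one entry per cluster (K = ", K, ")")
    eta_l <- eta_l + state$e_lambda[data$cluster]
    eta_m <- eta_m + state$e_mu[data$cluster]
  } else if (!is.null(state$e_lambda) && any(state$e_lambda != 0))
    stop("fixed-effects spec but non-zero random intercepts supplied")
  lambda <- exp(eta_l)
  mu <- exp(eta_m)
  if (any(!is.finite(lambda)) || any(!is.finite(mu))) {
    bad <- which(!is.finite(lambda) | !is.finite(mu))[1]
    stop("non-finite rate at unit ", bad, " (linear predictor overflow)")
  }
  list(lambda = lambda, mu = mu)
}

#' Observed-data log-likelihood under cross-misclassification
#'
#' The marginal likelihood of the observed labeled counts: `w1_i` and
#' `w2_i` are independently Poisson with means `t_i (lambda_i se + mu_i (1 -
#' sp))` and `t_i (lambda_i (1 - se) + mu_i sp)`. The two mixture rates sum
#' to `lambda_i + mu_i` for any `se`, `sp`, so total event counts are
#' conserved; only the split between the two labels is distorted. The value
#' is a true log-pmf (factorial constants included). A zero mixture rate
#' combined with a positive count yields `-Inf` rather than an error.
#'
#' @param state named list with `beta`, `gamma`, `se`, `sp` and random
#'   intercepts as in [case_rates]. `se`/`sp` are ignored (forced to 1) for
#'   `misclass = "none"` specs.
#' @param data an [mcp_data] object.
#' @param spec an [mcpois_spec].
#' @return The log-likelihood, a single number.
#' @export
observed_loglik <- function(state, data, spec) {
  check_counts(data$w1, "w1"); check_counts(data$w2, "w2")
  r <- case_rates(state, data, spec)
  if (spec$misclass == "none") { se <- 1; sp <- 1 }
  else { se <- state$se; sp <- state$sp }
  if (se <= 0 || se > 1 || sp <= 0 || sp > 1)
    stop("se and sp must lie in (0, 1]")
  m1 <- data$t * pmax(r$lambda * se + r$mu * (1 - sp), 1e-300)
  m2 <- data$t * pmax(r$lambda * (1 - se) + r$mu * sp, 1e-300)
  sum(data$w1 * log(m1) + data$w2 * log(m2) -
        data$t * (r$lambda + r$mu) -
        lgamma(data$w1 + 1) - lgamma(data$w2 + 1))
}

#' Brute-force latent-count probability (testing oracle)
#'
#' Computes `log P(w1, w2)` for a single unit by enumerating the latent true
#' counts and misclassified counts directly: `y1 ~ Poisson(t lambda)`, `y2 ~
#' Poisson(t mu)`, `u1 ~ Binomial(y1, 1 - se)` (true cases labeled other),
#' `u2 ~ Binomial(y2, 1 - sp)` (true non-cases labeled as cases), and `w1 =
#' y1 - u1 + u2`, `w2 = y2 + u1 - u2`. Because relabeling conserves the
#' total, only latent pairs with `y1 + y2 = w1 + w2` contribute, so the
#' enumeration is exact. This function exists to validate the closed-form
#' marginal likelihood in [observed_loglik]; it is deliberately independent
#' of that code path.
#'
#' @param lambda,mu positive true rates.
#' @param se,sp sensitivity and specificity in (0, 1].
#' @param t positive person-time.
#' @param w1,w2 observed non-negative integer counts.
#' @param cap enumeration bound on the latent total; must be at least
#'   `w1 + w2` (the conservation identity truncates the sum exactly there).
#' @return log probability of observing `(w1, w2)`.
#' @export
latent_count_oracle <- function(lambda, mu, se, sp, t, w1, w2,
                                cap = w1 + w2) {
  stopifnot(lambda > 0, mu > 0, t > 0, w1 >= 0, w2 >= 0,
            se > 0, se <= 1, sp > 0, sp <= 1)
  total <- w1 + w2
  if (cap < total)
    stop("cap (", cap, ") too small: latent totals up to ", total,
         " carry non-negligible mass")
  terms <- numeric(0)
  for (y1 in 0:total) {
    y2 <- total - y1
    # u2 - u1 = w1 - y1 fixes u2 once u1 is chosen
    u1s <- max(0L, y1 - w1):min(y1, w2)
    if (length(u1s) == 0 || u1s[1] > min(y1, w2)) next
    inner <- 0
    for (u1 in u1s) {
      u2 <- w1 - y1 + u1
      if (u2 < 0 || u2 > y2) next
      inner <- inner + dbinom(u1, y1, 1 - se) * dbinom(u2, y2, 1 - sp)
    }
    if (inner > 0)
      terms <- c(terms,
                 dpois(y1, t * lambda, log = TRUE) +
                   dpois(y2, t * mu, log = TRUE) + log(inner))
  }
  if (!length(terms)) return(-Inf)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}
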