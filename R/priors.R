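#' Prior specification
#'
#' Collects all prior settings: diffuse independent normal priors
#' `N(0, coef_sd^2)` for every regression coefficient (note `coef_sd` is a
#' standard deviation, not a variance or precision), beta priors for the
#' sensitivity and specificity when they are treated as unknown, and
#' uniform priors for the random-intercept scale parameters -- `sigma ~
#' Unif(0, sigma_upper)` in the common-variance model, `sigma1 ~ Unif(0,
#' sigma1_upper)`, `sigma2 ~ Unif(0, sigma2_upper)` and `rho ~ Unif(-1, 1)`
#' in the correlated model. The default `coef_sd = 10` allows multiplicative
#' rate effects spanning many orders of magnitude and is effectively flat
#' relative to the likelihood in typical registry-sized data; `sigma_upper =
#' 5` is usually far above any plausible log-rate heterogeneity but should
#' be checked per application.
#'
#' @param coef_sd positive prior standard deviation for all coefficients.
#' @param se,sp length-2 positive vectors `c(a, b)` of beta parameters for
#'   the sensitivity and specificity priors (used by `misclass = "unknown"`
#'   models). Defaults to the flat `Beta(1, 1)`.
#' @param sigma_upper,sigma1_upper,sigma2_upper positive upper bounds of the
#'   uniform priors on the random-intercept standard deviations.
#' @return An object of class `"mcpois_priors"`.
#' @seealso [beta_from_validation()], [beta_from_mode_percentile()] for
#'   constructing the `se`/`sp` beta parameters.
#' @export
mcpois_priors <- function(coef_sd = 10, se = c(1, 1), sp = c(1, 1),
                          sigma_upper = 5, sigma1_upper = 5,
                          sigma2_upper = 5) {
  stopifnot(coef_sd > 0, length(se) == 2, length(sp) == 2,
            all(se > 0), all(sp > 0), sigma_upper > 0,
            sigma1_upper > 0, sigma2_upper > 0)
  structure(list(coef_sd = coef_sd, se = as.numeric(se), sp = as.numeric(sp),
                 sigma_upper = sigma_upper, sigma1_upper = sigma1_upper,
                 sigma2_upper = sigma2_upper),
            class = "mcpois_priors")
}

#' Beta prior from gold-standard validation data
#'
#' If `m` subjects with gold-standard (e.g. autopsy-confirmed) cause labels
#' are available and the fallible classifier labeled `w` of them correctly,
#' the likelihood for the classification probability is binomial and the
#' flat-prior conjugate update gives a `Beta(w + 1, m - w + 1)` prior.
#'
#' @param m number of validated subjects (positive integer).
#' @param w number correctly labeled, `0 <= w <= m`.
#' @return Numeric `c(a, b)` beta parameters.
#' @examples
#' beta_from_validation(10, 9) # Beta(10, 2)
#' @export
beta_from_validation <- function(m, w) {
  if (length(m) != 1 || length(w) != 1 || m < 1 || m != round(m))
    stop("m must be a positive integer")
  if (w < 0 || w > m || w != round(w))
    stop("w must be an integer in [0, m]")
  c(a = w + 1, b = m - w + 1)
}

#' Beta prior from an elicited mode and lower percentile
#'
#' Solves for the `Beta(a, b)` with `a, b > 1` whose mode is `mode` and
#' whose cumulative probability at `tail_value` equals `tail_prob` -- the
#' "most likely value is M, with a 5% chance of being below L" style of
#' expert statement. With the mode fixed, `b = 1 + (a - 1)(1 - mode)/mode`,
#' and `a` is found by one-dimensional root search: increasing `a`
#' concentrates the density around the mode and monotonically reduces the
#' lower-tail mass.
#'
#' An accompanying "could be as high as U" statement over-determines the
#' two-parameter family and is not used as a constraint; check it
#' afterwards with [pbeta()] if desired.
#'
#' @param mode elicited most likely value, in (0, 1).
#' @param tail_prob lower-tail probability (e.g. 0.05).
#' @param tail_value the elicited lower value, `0 < tail_value < mode`.
#' @return Numeric `c(a, b)`.
#' @examples
#' beta_from_mode_percentile(0.8, 0.05, 0.7) # roughly Beta(40, 10)
#' @export
beta_from_mode_percentile <- function(mode, tail_prob = 0.05, tail_value) {
  stopifnot(mode > 0, mode < 1, tail_prob > 0, tail_prob < 0.5)
  if (tail_value >= mode || tail_value <= 0)
    stop("tail_value must satisfy 0 < tail_value < mode")
  b_of <- function(a) 1 + (a - 1) * (1 - mode) / mode
  f <- function(a) pbeta(tail_value, a, b_of(a)) - tail_prob
  lo <- 1 + 1e-9
  if (f(lo) < 0)
    stop("elicitation infeasible: even the flattest unimodal beta puts less ",
         "than tail_prob below tail_value")
  hi <- 2
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
  if (f(hi) > 0)
    stop("elicitation infeasible: tail_value too close to the mode")
  a <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  c(a = a, b = b_of(a))
}

#' Mean and standard deviation of a beta distribution
#'
#' @param params numeric `c(a, b)`, both positive.
#' @return Named numeric `c(mean, sd)`.
#' @examples
#' beta_moments(c(45, 5)) # mean 0.90, sd 0.042
#' @export
beta_moments <- function(params) {
  a <- params[[1]]; b <- params[[2]]
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("beta parameters must be positive")
  s <- a + b
  c(mean = a / s, sd = sqrt(a * b / (s^2 * (s + 1))))
}

#' Joint log prior density of a parameter state
#'
#' Sums the log densities of every active prior block: normal for each
#' regression coefficient, beta for `se`/`sp` when unknown, uniform for the
#' random-intercept scale parameters and correlation, and `N(0, sigma^2)`
#' (or the bivariate normal) for the random intercepts themselves. Returns
#' `-Inf` outside the support.
#'
#' @param state named list as in [observed_loglik], plus `sigma` or
#'   `sigma1`/`sigma2`/`rho` for random-intercept specs.
#' @param priors an [mcpois_priors].
#' @param spec an [mcpois_spec].
#' @return The log prior density (up to no additive constant; all
#'   normalizing constants are included).
#' @export
log_prior <- function(state, priors, spec) {
  lp <- sum(dnorm(state$beta, 0, priors$coef_sd, log = TRUE)) +
    sum(dnorm(state$gamma, 0, priors$coef_sd, log = TRUE))
  if (spec$misclass == "unknown") {
    if (state$se <= 0 || state$se >= 1 || state$sp <= 0 || state$sp >= 1)
      return(-Inf)
    lp <- lp + dbeta(state$se, priors$se[1], priors$se[2], log = TRUE) +
      dbeta(state$sp, priors$sp[1], priors$sp[2], log = TRUE)
  }
  if (spec$effects == "random") {
    if (state$sigma <= 0 || state$sigma >= priors$sigma_upper) return(-Inf)
    lp <- lp - log(priors$sigma_upper) +
      sum(dnorm(state$e_lambda, 0, state$sigma, log = TRUE)) +
      sum(dnorm(state$e_mu, 0, state$sigma, log = TRUE))
  } else if (spec$effects == "correlated") {
    if (state$sigma1 <= 0 || state$sigma1 >= priors$sigma1_upper ||
        state$sigma2 <= 0 || state$sigma2 >= priors$sigma2_upper ||
        state$rho <= -1 || state$rho >= 1) return(-Inf)
    lp <- lp - log(priors$sigma1_upper) - log(priors$sigma2_upper) - log(2)
    s1 <- state$sigma1; s2 <- state$sigma2; r <- state$rho
    za <- state$e_lambda / s1; zb <- state$e_mu / s2
    lp <- lp + sum(-log(2 * pi) - log(s1 * s2) - 0.5 * log(1 - r^2) -
                     (za^2 - 2 * r * za * zb + zb^2) / (2 * (1 - r^2)))
  }
  lp
}
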