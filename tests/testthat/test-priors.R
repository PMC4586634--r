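test_that("validation data gives the conjugate beta prior", {
  expect_equal(beta_from_validation(10, 9), c(a = 10, b = 2))
  expect_equal(beta_from_validation(1, 0), c(a = 1, b = 2))
  expect_equal(unname(beta_moments(beta_from_validation(2, 1))["mean"]), 0.5)
  expect_error(beta_from_validation(5, 6), "w must be")
  expect_error(beta_from_validation(0, 0), "positive integer")

  # the prior mean is the flat-prior posterior mean (w + 1) / (m + 2)
  for (m in 1:50)
    for (w in c(0L, m %/% 2, m))
      expect_equal(unname(beta_moments(beta_from_validation(m, w))["mean"]),
                   (w + 1) / (m + 2))
})

test_that("mode/percentile elicitation recovers the expert beta priors", {
  # specificity: most likely 0.8, 5% chance below 0.7. The elicited prior
  # carries the same center and spread as the conventional Beta(40, 10)
  # rough summary of those statements (which itself puts 4.8%, not exactly
  # 5%, below 0.7 -- the statements over-determine a two-parameter family,
  # so agreement is in moments, not in raw parameters).
  sp <- beta_from_mode_percentile(0.8, 0.05, 0.7)
  expect_equal(unname((sp[1] - 1) / (sp[1] + sp[2] - 2)), 0.8,
               tolerance = 1e-8)
  msp <- beta_moments(sp)
  expect_lt(abs(msp["mean"] - 0.8), 0.02)
  expect_lt(abs(msp["sd"] / 0.056 - 1), 0.25)

  # sensitivity: most likely 0.7, 5% chance below 0.6 -> moments of the
  # conventional Beta(35, 15) summary
  se <- beta_from_mode_percentile(0.7, 0.05, 0.6)
  expect_equal(unname((se[1] - 1) / (se[1] + se[2] - 2)), 0.7,
               tolerance = 1e-8)
  mse <- beta_moments(se)
  expect_lt(abs(mse["mean"] - 0.7), 0.02)
  expect_lt(abs(mse["sd"] / 0.064 - 1), 0.25)

  # symmetric elicitation gives a symmetric beta
  sym <- beta_from_mode_percentile(0.5, 0.1, 0.3)
  expect_equal(unname(sym[1]), unname(sym[2]), tolerance = 1e-6)

  # self-consistency: the returned prior reproduces the tail statement
  for (args in list(c(0.8, 0.05, 0.7), c(0.7, 0.05, 0.6), c(0.6, 0.2, 0.5))) {
    p <- beta_from_mode_percentile(args[1], args[2], args[3])
    expect_equal(pbeta(args[3], p[1], p[2]), args[2], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }

  expect_error(beta_from_mode_percentile(0.8, 0.05, 0.85), "tail_value")
  # a tail statement flatter than any unimodal beta is infeasible
  expect_error(beta_from_mode_percentile(0.9, 0.45, 0.1), "infeasible")
})

test_that("beta moments match the known mean/sd values", {
  expect_equal(beta_moments(c(45, 5)), c(mean = 0.9, sd = 0.042),
               tolerance = 0.01)
  expect_equal(beta_moments(c(40, 10)), c(mean = 0.8, sd = 0.056),
               tolerance = 0.01)
  expect_equal(beta_moments(c(35, 15)), c(mean = 0.7, sd = 0.064),
               tolerance = 0.01)
  expect_equal(beta_moments(c(1, 1)), c(mean = 0.5, sd = sqrt(1 / 12)))
  expect_error(beta_moments(c(-1, 2)), "positive")
})

test_that("log prior sums its active blocks and respects supports", {
  priors <- mcpois_priors(se = c(45, 5), sp = c(40, 10))
  spec <- mcpois_spec("random", "unknown", p = 0)
  st <- list(beta = c(0.3, -0.2), gamma = c(0.1, 0), se = 0.88, sp = 0.79,
             sigma = 0.4, e_lambda = c(0.1, -0.2), e_mu = c(0, 0.3))

  manual <- sum(dnorm(c(st$beta, st$gamma), 0, 10, log = TRUE)) +
    dbeta(0.88, 45, 5, log = TRUE) + dbeta(0.79, 40, 10, log = TRUE) +
    dunif(0.4, 0, 5, log = TRUE) +
    sum(dnorm(c(st$e_lambda, st$e_mu), 0, 0.4, log = TRUE))
  expect_equal(log_prior(st, priors, spec), manual)

  # outside the Unif(0, D) support
  st_bad <- st; st_bad$sigma <- priors$sigma_upper + 1
  expect_identical(log_prior(st_bad, priors, spec), -Inf)

  # additivity: dropping the se/sp block changes the value by exactly it
  spec_known <- mcpois_spec("random", "known", p = 0)
  expect_equal(log_prior(st, priors, spec) -
                 log_prior(st, priors, spec_known),
               dbeta(0.88, 45, 5, log = TRUE) +
                 dbeta(0.79, 40, 10, log = TRUE))

  # normal scale family: doubling coef_sd costs log(2) per coefficient at 0
  st0 <- list(beta = 0, gamma = 0, se = 0.9, sp = 0.8)
  spec0 <- mcpois_spec("fixed", "unknown", p = -1)
  d1 <- log_prior(st0, mcpois_priors(coef_sd = 10, se = c(45, 5),
                                     sp = c(40, 10)), spec0)
  d2 <- log_prior(st0, mcpois_priors(coef_sd = 20, se = c(45, 5),
                                     sp = c(40, 10)), spec0)
  expect_equal(d1 - d2, 2 * log(2))
})

test_that("correlated-intercept prior matches the bivariate normal density", {
  priors <- mcpois_priors()
  spec <- mcpois_spec("correlated", "none", p = 0)
  st <- list(beta = c(0, 0), gamma = c(0, 0), sigma1 = 0.2, sigma2 = 0.4,
             rho = 0.5, e_lambda = c(0.1, -0.3), e_mu = c(0.2, 0.1))
  S <- matrix(c(0.04, 0.5 * 0.2 * 0.4, 0.5 * 0.2 * 0.4, 0.16), 2)
  dens <- sum(vapply(1:2, function(k) {
    e <- c(st$e_lambda[k], st$e_mu[k])
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(e %*% solve(S) %*% e)
  }, 0))
  manual <- sum(dnorm(c(0, 0, 0, 0), 0, 10, log = TRUE)) -
    log(5) - log(5) - log(2) + dens
  expect_equal(log_prior(st, priors, spec), manual)
  st$rho <- 1.2
  expect_identical(log_prior(st, priors, spec), -Inf)
})
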