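test_that("case_rates evaluates the log-linear rate models", {
  d <- mcp_data(w1 = c(0L, 0L), w2 = c(0L, 0L), t = c(1, 1), x = c(1, 0),
                z = data.frame(z1 = c(1, 0), z2 = c(1, 0)))
  spec <- mcpois_spec("fixed", "known", p = 2)

  # all-zero coefficients give unit rates whatever the covariates
  r0 <- case_rates(list(beta = rep(0, 4), gamma = rep(0, 4)), d, spec)
  expect_equal(r0$lambda, c(1, 1))
  expect_equal(r0$mu, c(1, 1))

  # worked-example coefficients, hand arithmetic
  st <- list(beta = c(-1, 0.5, -0.5, 0.1), gamma = c(-2, -0.3, 0.2, 0.5))
  r <- case_rates(st, d, spec)
  expect_equal(r$lambda[1], exp(-0.9))
  expect_equal(r$mu[2], exp(-2))

  # random intercept enters additively on the log scale
  d2 <- mcp_data(w1 = 0L, w2 = 0L, t = 1, x = 0, cluster = 1L)
  r2 <- case_rates(list(beta = c(-2, -0.3), gamma = c(-2, -0.3),
                        e_lambda = 0.4, e_mu = 0.4),
                   d2, mcpois_spec("random", "known", p = 0))
  expect_equal(r2$mu, exp(-1.6))

  # structural errors
  expect_error(case_rates(list(beta = c(0, 0), gamma = rep(0, 4)), d, spec),
               "does not match")
  expect_error(case_rates(list(beta = c(800, 0, 0, 0), gamma = rep(0, 4)),
                          d, spec), "unit 1")
})

test_that("observed log-likelihood reduces to product Poisson when se = sp = 1", {
  d <- mcp_data(w1 = 2L, w2 = 3L, t = 1, x = 0)
  spec <- mcpois_spec("fixed", "known", p = 0)
  st <- list(beta = c(0, 0), gamma = c(0, 0), se = 1, sp = 1)
  expect_identical(observed_loglik(st, d, spec),
                   dpois(2, 1, log = TRUE) + dpois(3, 1, log = TRUE))
  expect_equal(observed_loglik(st, d, spec), -2 - log(12))

  # the naive spec forces se = sp = 1 and matches the explicit path exactly
  st2 <- list(beta = c(-0.4, 0), gamma = c(0.2, 0), se = 0.6, sp = 0.7)
  st2_unit <- within(st2, { se <- 1; sp <- 1 })
  expect_identical(observed_loglik(st2, d, mcpois_spec("fixed", "none", 0)),
                   observed_loglik(st2_unit, d, spec))
})

test_that("likelihood is invariant under the label-swap symmetry", {
  spec <- mcpois_spec("fixed", "unknown", p = 0)
  for (s in 1:10) {
    st <- rand_state(2, seed = s)
    set.seed(100 + s)
    w <- rpois(2, 3)
    d <- mcp_data(w1 = w[1], w2 = w[2], t = runif(1, 0.5, 2), x = 1)
    dsw <- mcp_data(w1 = w[2], w2 = w[1], t = d$t, x = 1)
    stsw <- list(beta = st$gamma, gamma = st$beta, se = st$sp, sp = st$se)
    expect_identical(observed_loglik(st, d, spec),
                     observed_loglik(stsw, dsw, spec))
  }
})

test_that("latent-count enumeration oracle behaves at its trivial corners", {
  # no misclassification: only the direct path contributes
  expect_equal(latent_count_oracle(0.7, 1.3, 1, 1, 2, 3L, 1L),
               dpois(3, 1.4, log = TRUE) + dpois(1, 2.6, log = TRUE))
  # (0, 0) observed: only y1 = y2 = 0, whatever se and sp
  for (sesp in list(c(1, 1), c(0.8, 0.7), c(0.55, 0.95)))
    expect_equal(latent_count_oracle(0.5, 0.25, sesp[1], sesp[2], 3, 0L, 0L),
                 -3 * 0.75)
  expect_error(latent_count_oracle(1, 1, 0.9, 0.9, 1, 4L, 3L, cap = 5),
               "cap")
})

test_that("closed-form marginal likelihood equals the enumeration oracle", {
  spec <- mcpois_spec("fixed", "unknown", p = 0)
  set.seed(42)
  checked <- 0
  for (rep in 1:60) {
    lambda <- runif(1, 0.1, 2); mu <- runif(1, 0.1, 2)
    se <- runif(1, 0.4, 1); sp <- runif(1, 0.4, 1)
    t <- runif(1, 0.3, 1.5)
    w <- c(sample(0:4, 1), sample(0:3, 1))
    if (sum(w) > 6) next
    st <- list(beta = c(log(lambda), 0), gamma = c(log(mu), 0),
               se = se, sp = sp)
    d <- mcp_data(w1 = w[1], w2 = w[2], t = t, x = 0)
    expect_equal(observed_loglik(st, d, spec),
                 latent_count_oracle(lambda, mu, se, sp, t, w[1], w[2]),
                 tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gte(checked, 50)
})

test_that("mixture rates conserve the total event rate", {
  # E[w1] + E[w2] = t (lambda + mu) for any se, sp: the mixture weights
  # (se, 1-sp) and (1-se, sp) are column sums of a stochastic relabeling
  set.seed(7)
  for (i in 1:20) {
    lam <- runif(1, 0, 3); mu <- runif(1, 0, 3)
    se <- runif(1); sp <- runif(1); t <- runif(1, 0.1, 5)
    m1 <- t * (lam * se + mu * (1 - sp))
    m2 <- t * (lam * (1 - se) + mu * sp)
    expect_equal(m1 + m2, t * (lam + mu))
  }
})

test_that("zero mixture rate with a positive count yields -Inf, not an error", {
  d <- mcp_data(w1 = 0L, w2 = 2L, t = 1, x = 0)
  # se = 1, sp = 1 and lambda-only: w2 has rate mu = exp(-200) ~ floored
  st <- list(beta = c(0, 0), gamma = c(-800, 0), se = 1, sp = 1)
  ll <- observed_loglik(st, d, mcpois_spec("fixed", "known", 0))
  expect_lt(ll, -1000)
})

test_that("compiled likelihood agrees with the reference implementation", {
  tr <- study_scenario()
  d <- simulate_counts(tr, seed = 3)
  X <- cbind(1, d$x, d$z1, d$z2)
  K <- max(d$cluster)
  for (s in 1:10) {
    st <- rand_state(4, K = K, seed = 200 + s)
    a <- observed_loglik(st, d, mcpois_spec("random", "unknown", p = 2))
    b <- mcpois:::.mcp_loglik(d$w1, d$w2, d$t, X, d$cluster - 1L, K, 1L,
                              st$beta, st$gamma, st$e_lambda, st$e_mu,
                              st$se, st$sp)
    expect_equal(a, b, tolerance = 1e-10)
  }
})
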