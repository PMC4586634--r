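test_that("chain initialization is deterministic and respects se + sp > 1", {
  spec <- mcpois_spec("random", "unknown", p = 2)
  ctl <- quick_control(chains = 4)
  pri <- study_priors()
  i1 <- initialize_chains(spec, pri, ctl, n_clusters = 8, seed = 5)
  i2 <- initialize_chains(spec, pri, ctl, n_clusters = 8, seed = 5)
  expect_identical(i1, i2)
  expect_length(i1, 4)
  for (st in i1) {
    expect_gt(st$se + st$sp, 1)
    expect_true(st$sigma > 0.05 && st$sigma < 1)
    expect_length(st$e_lambda, 8)
  }

  # flat-ish priors still give valid starts via rejection
  flat <- initialize_chains(spec, mcpois_priors(), ctl, n_clusters = 2,
                            seed = 1)
  for (st in flat) expect_gt(st$se + st$sp, 1)

  # priors concentrated on worse-than-random classification are refused
  bad <- mcpois_priors(se = c(1, 400), sp = c(1, 400))
  expect_error(initialize_chains(spec, bad, ctl, n_clusters = 2, seed = 1),
               "worse-than-random")

  # known misclassification uses the fixed values untouched
  known <- initialize_chains(mcpois_spec("fixed", "known", 0), pri,
                             quick_control(chains = 1), se = 0.7, sp = 0.8,
                             seed = 2)
  expect_equal(known[[1]]$se, 0.7)
  expect_equal(known[[1]]$sp, 0.8)
})

test_that("identical seeds reproduce the draw matrix bit for bit", {
  d <- fixed_effects_data(seed = 1, se = 0.9, sp = 0.8)
  ctl <- quick_control(chains = 2, burn = 300, keep = 300)
  f1 <- mcpois(cbind(w1, w2) ~ x + z1 + z2, data = d, misclass = "unknown",
               effects = "random", priors = study_priors(), control = ctl,
               seed = 77)
  f2 <- mcpois(cbind(w1, w2) ~ x + z1 + z2, data = d, misclass = "unknown",
               effects = "random", priors = study_priors(), control = ctl,
               seed = 77)
  expect_identical(f1$draws, f2$draws)
  f3 <- mcpois(cbind(w1, w2) ~ x + z1 + z2, data = d, misclass = "unknown",
               effects = "random", priors = study_priors(), control = ctl,
               seed = 78)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("naive posterior agrees with the Poisson GLM at large counts", {
  d <- fixed_effects_data(seed = 11) # se = sp = 1, counts in the hundreds
  fit <- mcpois(cbind(w1, w2) ~ x + z1 + z2, data = d, misclass = "none",
                effects = "fixed", control = quick_control(burn = 2000,
                                                           keep = 2000),
                seed = 3)
  s <- summary(fit, pars = c("beta0", "beta1", "gamma0", "gamma1"))$table
  g1 <- glm(w1 ~ x + z1 + z2 + offset(log(t)), poisson, data = d)
  g2 <- glm(w2 ~ x + z1 + z2 + offset(log(t)), poisson, data = d)
  ref <- c(coef(g1)[1:2], coef(g2)[1:2])
  ses <- c(sqrt(diag(vcov(g1)))[1:2], sqrt(diag(vcov(g2)))[1:2])
  # posterior mean within a third of a standard error of the MLE, and
  # posterior sd within 20% of the asymptotic one
  expect_true(all(abs(s[, "mean"] - ref) < 0.35 * ses))
  expect_true(all(abs(s[, "sd"] / ses - 1) < 0.2))
  expect_true(all(s[, "rhat"] < 1.05))
})

test_that("posterior summaries follow the stated quantile and diagnostic rules", {
  fake <- structure(list(draws = cbind(theta = rep(1.5, 1000)),
                         chain = rep(1:2, each = 500),
                         control = quick_control(chains = 2, keep = 500)),
                    class = "mcpois")
  s <- summary(fake)
  expect_equal(unname(s$table[1, c("mean", "lower", "upper")]),
               c(1.5, 1.5, 1.5))
  expect_equal(s$degenerate, "theta")

  # the equal-tailed interval uses the default empirical quantile rule
  fake2 <- structure(list(draws = cbind(theta = as.numeric(1:1000)),
                          chain = rep(1:2, each = 500),
                          control = quick_control(chains = 2, keep = 500)),
                     class = "mcpois")
  s2 <- summary(fake2)
  expect_equal(unname(s2$table[1, "lower"]), 25.975)
  expect_equal(unname(s2$table[1, "upper"]), 975.025)

  # two iid chains from the same distribution: R-hat near 1
  set.seed(8)
  fake3 <- structure(list(draws = cbind(theta = rnorm(4000)),
                          chain = rep(1:2, each = 2000),
                          control = quick_control(chains = 2, keep = 2000)),
                     class = "mcpois")
  expect_lt(summary(fake3)$table[1, "rhat"], 1.05)
  expect_gt(summary(fake3)$table[1, "ess"], 2000)

  expect_error(summary(fake, level = 0.99999), "quantile")
})

test_that("effective sample size and R-hat agree with coda on iid chains", {
  skip_if_not_installed("coda")
  set.seed(12)
  x <- rnorm(3000)
  ess <- mcpois:::ess_basic(x, rep(1:3, each = 1000))
  ess_coda <- unname(coda::effectiveSize(coda::mcmc(x)))
  expect_lt(abs(ess - ess_coda) / ess_coda, 0.25)
})

test_that("cut mode reproduces the se/sp priors exactly", {
  d <- simulate_counts(study_scenario(), seed = 2)
  f <- mcpois(cbind(w1, w2) ~ x + z1 + z2, data = d, effects = "random",
              misclass = "unknown", priors = study_priors(),
              control = quick_control(chains = 1, burn = 200, keep = 5000,
                                      cut_se_sp = TRUE), seed = 9)
  ks_se <- suppressWarnings(ks.test(f$draws[, "se"], pbeta, 45, 5))
  ks_sp <- suppressWarnings(ks.test(f$draws[, "sp"], pbeta, 40, 10))
  expect_lt(unname(ks_se$statistic), 0.05)
  expect_lt(unname(ks_sp$statistic), 0.05)
})

test_that("with the likelihood off the sampler recovers its priors", {
  d <- simulate_counts(study_scenario(), seed = 2)
  f <- mcpois(cbind(w1, w2) ~ x + z1 + z2, data = d, effects = "random",
              misclass = "unknown", priors = study_priors(),
              control = quick_control(chains = 2, burn = 2000, keep = 4000,
                                      prior_only = TRUE), seed = 10)
  s <- summary(f, pars = c("beta0", "beta1", "gamma2", "se", "sp", "sigma"))
  tab <- s$table
  moments <- rbind(
    beta0 = c(0, 10), beta1 = c(0, 10), gamma2 = c(0, 10),
    se = beta_moments(c(45, 5)), sp = beta_moments(c(40, 10)),
    sigma = c(2.5, 5 / sqrt(12)))
  for (p in rownames(tab)) {
    mcse <- tab[p, "sd"] / sqrt(max(tab[p, "ess"], 4))
    expect_lt(abs(tab[p, "mean"] - moments[p, 1]), 4 * mcse)
    expect_lt(abs(tab[p, "sd"] / moments[p, 2] - 1), 0.25)
  }
})

test_that("point-mass beta priors converge to the known-misclassification fit", {
  d <- fixed_effects_data(seed = 21, se = 0.8, sp = 0.9)
  ctl <- quick_control(chains = 2, burn = 2000, keep = 2000)
  f_known <- mcpois(cbind(w1, w2) ~ x + z1 + z2, data = d, effects = "fixed",
                    misclass = "known", se = 0.8, sp = 0.9, control = ctl,
                    seed = 5)
  f_point <- mcpois(cbind(w1, w2) ~ x + z1 + z2, data = d, effects = "fixed",
                    misclass = "unknown",
                    priors = mcpois_priors(se = 1e6 * c(0.8, 0.2),
                                           sp = 1e6 * c(0.9, 0.1)),
                    control = ctl, seed = 6)
  for (p in c("beta1", "gamma1")) {
    m1 <- summary(f_known, pars = p)$table
    m2 <- summary(f_point, pars = p)$table
    mc <- sqrt(m1[1, "sd"]^2 / m1[1, "ess"] + m2[1, "sd"]^2 / m2[1, "ess"])
    expect_lt(abs(m1[1, "mean"] - m2[1, "mean"]), 4 * mc + 0.01)
  }
})

test_that("misclassification models report structural errors cleanly", {
  d <- fixed_effects_data(seed = 1)
  expect_error(mcpois(cbind(w1, w2) ~ x, data = d, misclass = "known",
                      control = quick_control()), "requires fixed")
  d$cluster <- NULL
  expect_error(mcpois(cbind(w1, w2) ~ x, data = d, effects = "random",
                      misclass = "none", control = quick_control()),
               "cluster")
})
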