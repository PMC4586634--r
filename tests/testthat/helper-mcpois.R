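# shared fixtures: everything is generated in code, no stored data

quick_control <- function(chains = 2, burn = 1000, keep = 1000, ...) {
  suppressWarnings(mcpois_control(chains = chains, burn = burn, keep = keep,
                                  ...))
}

# a small fixed-effects dataset with big counts (coefficients well identified)
fixed_effects_data <- function(seed = 11, se = 1, sp = 1) {
  tr <- truth_config(beta = c(-1, 0.5, -0.5, 0.1),
                     gamma = c(-2, -0.3, 0.2, 0.5),
                     se = se, sp = sp, t = 1000, design = make_design(3, 4))
  simulate_counts(tr, seed = seed)
}

# canonical study priors: se ~ Beta(45, 5), sp ~ Beta(40, 10)
study_priors <- function() mcpois_priors(se = c(45, 5), sp = c(40, 10))

rand_state <- function(q, K = 0, seed) {
  set.seed(seed)
  st <- list(beta = rnorm(q, 0, 0.3), gamma = rnorm(q, 0, 0.3),
             se = runif(1, 0.55, 1), sp = runif(1, 0.55, 1))
  if (K > 0) {
    st$sigma <- runif(1, 0.1, 1)
    st$e_lambda <- rnorm(K, 0, 0.3)
    st$e_mu <- rnorm(K, 0, 0.3)
  }
  st
}
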