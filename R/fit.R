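#' Draw overdispersed starting states for the MCMC chains
#'
#' Coefficients start at `N(0, 0.5^2)` draws; when `data` is supplied the
#' two intercepts are centered instead at the log observed average rates
#' of their streams (`log(mean(w1/t))`, `log(mean(w2/t))`). That anchoring
#' matters: the likelihood is invariant under the label-swap symmetry
#' (exchange the two streams and replace `(se, sp)` by `(1-sp, 1-se)`),
#' and a chain whose starting coefficients implicitly assign stream 1 the
#' low rate can settle in the mirror-image mode -- locally stable but of
#' negligible posterior mass under any realistic prior -- and never
#' escape. For the same reason, when the misclassification parameters are
#' unknown, `se` and `sp` start at prior draws redrawn until
#' `se + sp > 1`. Random-intercept scales start at `Unif(0.05, 1)` draws
#' and the intercepts themselves at small normal perturbations.
#' Deterministic given `seed`.
#'
#' @param spec an [mcpois_spec].
#' @param priors an [mcpois_priors].
#' @param control an [mcpois_control]; supplies `chains` and the default
#'   `seed`.
#' @param n_clusters number of clusters (random-intercept specs only).
#' @param se,sp fixed values for `misclass = "known"` specs.
#' @param seed integer seed.
#' @param data optional [mcp_data]; anchors the starting intercepts at the
#'   observed stream rates.
#' @return A list of `control$chains` named parameter states.
#' @export
initialize_chains <- function(spec, priors, control, n_clusters = 0L,
                              se = NULL, sp = NULL, seed = control$seed,
                              data = NULL) {
  q <- spec$p + 2L
  centers <- c(0, 0)
  if (!is.null(data) && all(c("w1", "w2", "t") %in% names(data)))
    centers <- c(log(max(mean(data$w1 / data$t), 1e-12)),
                 log(max(mean(data$w2 / data$t), 1e-12)))
  set.seed(seed)
  lapply(seq_len(control$chains), function(ch) {
    st <- list(beta = rnorm(q, 0, 0.5), gamma = rnorm(q, 0, 0.5))
    st$beta[1] <- st$beta[1] + centers[1]
    st$gamma[1] <- st$gamma[1] + centers[2]
    if (spec$misclass == "unknown") {
      ok <- FALSE
      for (i in 1:1000) {
        st$se <- rbeta(1, priors$se[1], priors$se[2])
        st$sp <- rbeta(1, priors$sp[1], priors$sp[2])
        if (st$se + st$sp > 1) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not draw starting values with se + sp > 1 after 1000 ",
             "tries; the se/sp priors concentrate on worse-than-random ",
             "classification")
    } else if (spec$misclass == "known") {
      st$se <- se; st$sp <- sp
    } else {
      st$se <- 1; st$sp <- 1
    }
    if (spec$effects == "random") {
      st$sigma <- runif(1, 0.05, 1)
      st$e_lambda <- rnorm(n_clusters, 0, 0.1)
      st$e_mu <- rnorm(n_clusters, 0, 0.1)
    } else if (spec$effects == "correlated") {
      st$sigma1 <- runif(1, 0.05, 1)
      st$sigma2 <- runif(1, 0.05, 1)
      st$rho <- runif(1, -0.5, 0.5)
      st$e_lambda <- rnorm(n_clusters, 0, 0.1)
      st$e_mu <- rnorm(n_clusters, 0, 0.1)
    }
    st
  })
}

state_to_vector <- function(st, spec, K) {
  v <- c(st$beta, st$gamma, st$se, st$sp)
  if (spec$effects == "random") v <- c(v, st$sigma)
  if (spec$effects == "correlated") v <- c(v, st$sigma1, st$sigma2, st$rho)
  if (spec$effects != "fixed") v <- c(v, st$e_lambda, st$e_mu)
  v
}

param_names <- function(spec, q, K) {
  nm <- c(paste0("beta", 0:(q - 1)), paste0("gamma", 0:(q - 1)), "se", "sp")
  if (spec$effects == "random") nm <- c(nm, "sigma")
  if (spec$effects == "correlated") nm <- c(nm, "sigma1", "sigma2", "rho")
  if (spec$effects != "fixed")
    nm <- c(nm, paste0("eA", seq_len(K)), paste0("eB", seq_len(K)))
  nm
}

#' Fit a Bayesian Poisson regression with misclassified outcome counts
#'
#' Samples from the posterior of the log-linear two-stream Poisson model in
#' which the observed labeled counts `w1` (cause of interest) and `w2`
#' (other causes) have Poisson means `t (lambda se + mu (1 - sp))` and `t
#' (lambda (1 - se) + mu sp)`, with `log lambda = X beta (+ eA_k)` and
#' `log mu = X gamma (+ eB_k)`. Sampling is blockwise adaptive random-walk
#' Metropolis on the marginal likelihood (the latent true counts are never
#' imputed): componentwise updates for the coefficients, a logit-scale walk
#' for `(se, sp)`, bounded walks for the random-intercept scale parameters
#' and one-cluster-at-a-time intercept updates. Proposal scales adapt
#' during burn-in only.
#'
#' @param formula a two-column count response and covariates, e.g.
#'   `cbind(w1, w2) ~ x + z1 + z2`. The first right-hand-side term is
#'   treated as the exposure of interest (its coefficients are `beta1` and
#'   `gamma1`).
#' @param data a data frame (typically an [mcp_data]).
#' @param t person-time: a one-sided formula (`~ t`), a column name, or a
#'   numeric vector. Defaults to the `t` column of `data`.
#' @param cluster cluster labels for random-intercept models, same
#'   conventions as `t`; defaults to the `cluster` column when present.
#' @param effects,misclass model structure, see [mcpois_spec].
#' @param se,sp fixed sensitivity/specificity for `misclass = "known"`.
#' @param priors an [mcpois_priors].
#' @param control an [mcpois_control].
#' @param seed overrides `control$seed` when supplied.
#' @return An object of class `"mcpois"`: a list with the draw matrix
#'   (`chains * keep` rows, one column per parameter), chain ids,
#'   acceptance rates, and the fit ingredients. `print`, `summary`, `coef`,
#'   `plot`, `as.matrix` and `as.data.frame` methods are provided.
#' @examples
#' tr <- truth_config(beta = c(-1, 0.5), gamma = c(-2, -0.3),
#'                    se = 0.9, sp = 0.8, t = 500,
#'                    design = data.frame(x = rep(0:1, each = 4)))
#' d <- simulate_counts(tr, seed = 1)
#' fit <- mcpois(cbind(w1, w2) ~ x, data = d, misclass = "known",
#'               se = 0.9, sp = 0.8,
#'               control = mcpois_control(chains = 2, burn = 500,
#'                                        keep = 500, seed = 1))
#' summary(fit)
#' @export
mcpois <- function(formula, data, t = NULL, cluster = NULL,
                   effects = c("fixed", "random", "correlated"),
                   misclass = c("unknown", "known", "none"),
                   se = NULL, sp = NULL,
                   priors = mcpois_priors(),
                   control = mcpois_control(),
                   seed = NULL) {
  effects <- match.arg(effects)
  misclass <- match.arg(misclass)
  if (!is.null(seed)) control$seed <- as.integer(seed)
  cl_call <- match.call()

  mf <- model.frame(formula, data)
  Y <- model.response(mf)
  if (is.null(dim(Y)) || ncol(Y) != 2)
    stop("the response must be a two-column count matrix, e.g. cbind(w1, w2)")
  w1 <- as.integer(Y[, 1]); w2 <- as.integer(Y[, 2])
  check_counts(w1, "w1"); check_counts(w2, "w2")
  X <- model.matrix(attr(mf, "terms"), mf)
  if (colnames(X)[1] != "(Intercept)")
    stop("the model must include an intercept")
  q <- ncol(X)
  n <- nrow(X)

  tvec <- resolve_column(t, data, "t", n)
  if (any(tvec <= 0)) stop("person-time t must be positive")
  if (effects != "fixed") {
    clvec <- resolve_column(cluster, data, "cluster", n, required = TRUE,
                            what = "random-intercept models need cluster labels")
    check_cluster(clvec, n)
    clvec <- as.integer(clvec)
    K <- max(clvec)
  } else { clvec <- rep(1L, n); K <- 0L }

  if (misclass == "known") {
    if (is.null(se) || is.null(sp))
      stop("misclass = \"known\" requires fixed se and sp values")
    stopifnot(se > 0, se <= 1, sp > 0, sp <= 1)
    if (se + sp <= 1) warning("fixed se + sp <= 1: the labels are modeled ",
                              "as worse than random")
    se_fix <- se; sp_fix <- sp
  } else if (misclass == "none") { se_fix <- 1; sp_fix <- 1 }
  else { se_fix <- NA_real_; sp_fix <- NA_real_ }

  spec <- mcpois_spec(effects, misclass, p = q - 2L)
  inits <- initialize_chains(spec, priors, control, n_clusters = K,
                             se = se_fix, sp = sp_fix,
                             data = data.frame(w1 = w1, w2 = w2, t = tvec))
  nm <- param_names(spec, q, K)

  # scalar proposal-scale vector mirroring the kernel's block layout
  sc <- control$scales
  scales <- c(rep(sc$coef, 2 * q), rep(sc$sesp, 2), rep(sc$var, 3),
              rep(sc$re, 2 * max(K, 1)), rep(sc$sweep, 2 * q), rep(sc$sesp, 2))

  set.seed(control$seed)
  chain_seeds <- sample.int(2147483646L, control$chains)
  draws <- vector("list", control$chains)
  accepts <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    set.seed(chain_seeds[ch])
    res <- .mcp_run_chain(w1, w2, tvec, X, clvec - 1L, K,
                          effects_code(effects), misclass_code(misclass),
                          inits[[ch]]$se, inits[[ch]]$sp,
                          priors$se[1], priors$se[2],
                          priors$sp[1], priors$sp[2],
                          priors$coef_sd, priors$sigma_upper,
                          priors$sigma1_upper, priors$sigma2_upper,
                          control$burn, control$keep, control$thin,
                          state_to_vector(inits[[ch]], spec, K), scales,
                          control$cut_se_sp, control$prior_only)
    colnames(res$draws) <- nm
    draws[[ch]] <- res$draws
    accepts[[ch]] <- res$accept
  }

  structure(list(draws = do.call(rbind, draws),
                 chain = rep(seq_len(control$chains), each = control$keep),
                 parameters = nm,
                 covariates = colnames(X),
                 accept = accepts,
                 spec = spec, priors = priors, control = control,
                 se_fixed = se_fix, sp_fixed = sp_fix,
                 n = n, K = K, call = cl_call),
            class = "mcpois")
}

resolve_column <- function(arg, data, default, n, required = FALSE,
                           what = NULL) {
  v <- if (is.null(arg)) data[[default]]
  else if (inherits(arg, "formula")) eval(arg[[2]], data, environment(arg))
  else if (is.character(arg) && length(arg) == 1) data[[arg]]
  else arg
  if (is.null(v)) {
    if (required) stop(what %||% paste0("column '", default, "' not found"))
    if (default == "t") stop("person-time t not supplied and no 't' column")
  }
  if (length(v) != n) stop("'", default, "' must have one value per row")
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
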