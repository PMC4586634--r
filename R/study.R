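#' Model definition for the study harness
#'
#' A lightweight bundle of the arguments the harness passes to [mcpois] for
#' each analysis model. The four corrected models are `effects =
#' "random"`/`"fixed"` crossed with `misclass = "known"`/`"unknown"`; the
#' naive analysis is `misclass = "none"`.
#'
#' @inheritParams mcpois
#' @param cut fit with the Monte Carlo sensitivity (cut) mode.
#' @return A list of class `"mcp_model"`.
#' @export
mcp_model <- function(effects = "random", misclass = "unknown",
                      se = NULL, sp = NULL, priors = mcpois_priors(),
                      cut = FALSE) {
  structure(list(effects = effects, misclass = misclass, se = se, sp = sp,
                 priors = priors, cut = cut), class = "mcp_model")
}

#' Canonical simulation-study scenario
#'
#' The overdispersed two-stream generating configuration used throughout
#' the package's replication studies: three binary covariates in full
#' factorial with 3 replicates per pattern (n = 24), person-time 1000 per
#' observation, cause-of-interest log-rate `-1 + 0.5 x - 0.5 z1 + 0.1 z2`
#' and other-cause log-rate `-2 - 0.3 x + 0.2 z1 + 0.5 z2`, and
#' observation-level random intercepts with variance `sigma2` on both
#' log-rates. The exposure truths are therefore `beta1 = 0.5` (sensitivity
#' stream) and `gamma1 = -0.3` (specificity stream).
#'
#' @param sigma2 random-intercept variance.
#' @param se,sp true sensitivity and specificity.
#' @return An [truth_config] object.
#' @export
study_scenario <- function(sigma2 = 0.10, se = 0.9, sp = 0.8) {
  truth_config(beta = c(-1, 0.5, -0.5, 0.1),
               gamma = c(-2, -0.3, 0.2, 0.5),
               se = se, sp = sp, re = "common", sigma = sqrt(sigma2),
               t = 1000, design = make_design(3, 3, cluster = "unit"))
}

#' Clustered worked-example scenario
#'
#' Eight clusters of four observations whose covariate patterns mix
#' exposure levels within cluster, correlated bivariate random intercepts
#' (`sigma1 = 0.2`, `sigma2 = 0.4`, `rho = 0.5`), person-time 1000,
#' cause-of-interest log-rate `-1 + 0.5 x - 0.5 z1 + 0.1 z2`, other-cause
#' log-rate `-2 - 0.3 x + 0.2 z1 + 0.5 z2`, true `se = 0.75`, `sp = 0.8`.
#'
#' @return An [truth_config] object.
#' @export
worked_example_scenario <- function() {
  truth_config(beta = c(-1, 0.5, -0.5, 0.1),
               gamma = c(-2, -0.3, 0.2, 0.5),
               se = 0.75, sp = 0.8, re = "correlated",
               sigma1 = 0.2, sigma2 = 0.4, rho = 0.5,
               t = 1000, design = make_design(3, 4, cluster = "crossed"))
}

formula_for <- function(data) {
  zcols <- setdiff(names(data), c("unit", "cluster", "t", "w1", "w2", "x"))
  stats::as.formula(paste("cbind(w1, w2) ~ x",
                          if (length(zcols))
                            paste("+", paste(zcols, collapse = " + "))
                          else ""),
                    env = baseenv())
}

fit_model <- function(model, data, control, seed) {
  ctl <- control
  ctl$cut_se_sp <- isTRUE(model$cut)
  mcpois(formula_for(data), data = data,
         effects = model$effects, misclass = model$misclass,
         se = model$se, sp = model$sp, priors = model$priors,
         control = ctl, seed = seed)
}

truth_values <- function(truth) {
  q <- length(truth$beta)
  v <- c(setNames(truth$beta, paste0("beta", 0:(q - 1))),
         setNames(truth$gamma, paste0("gamma", 0:(q - 1))),
         se = truth$se, sp = truth$sp)
  if (truth$re == "common") v <- c(v, sigma = truth$sigma)
  if (truth$re == "correlated")
    v <- c(v, sigma1 = truth$sigma1, sigma2 = truth$sigma2, rho = truth$rho)
  v
}

#' Replicate-level simulation study
#'
#' Repeats, `R` times: simulate a dataset from `truth`, fit every model in
#' `models`, and record the posterior mean, equal-tailed 95% interval,
#' interval width and truth-coverage indicator for each tracked parameter.
#' Replicates whose tracked split-chain R-hat exceeds `rhat_max` are refit
#' once with doubled burn-in and excluded (with a logged count) if still
#' not converged -- never silently dropped.
#'
#' Replicate seeds are derived from `seed` by fixed integer strides, so any
#' scenario is reproducible in isolation and results are invariant to the
#' order in which replicates run.
#'
#' @param truth an [truth_config] describing the generating process.
#' @param models named list of [mcp_model] definitions.
#' @param R number of replicates.
#' @param control an [mcpois_control] used for every fit.
#' @param seed master integer seed.
#' @param track character vector of parameter names to monitor.
#' @param rhat_max convergence screen threshold.
#' @return An object of class `"mcp_study"`: `replicates` (one row per
#'   replicate x model x parameter), `summary` (per model x parameter:
#'   average posterior mean, average width, empirical coverage, and Monte
#'   Carlo standard errors of each), `excluded` counts, and the tracked
#'   truth values.
#' @export
run_study <- function(truth, models, R = 200,
                      control = mcpois_control(chains = 2, burn = 2000,
                                               keep = 2000),
                      seed = 1, track = c("beta1", "gamma1"),
                      rhat_max = 1.1) {
  stopifnot(R >= 1, !is.null(names(models)), all(nzchar(names(models))))
  tv <- truth_values(truth)
  miss <- setdiff(track, names(tv))
  if (length(miss)) stop("tracked parameter(s) without a truth value: ",
                         paste(miss, collapse = ", "))
  rows <- list()
  excluded <- setNames(integer(length(models)), names(models))
  for (r in seq_len(R)) {
    d <- simulate_counts(truth, seed = seed + 7919L * r)
    for (mi in seq_along(models)) {
      mname <- names(models)[mi]
      fseed <- seed + 104729L * r + 13L * mi
      fit <- fit_model(models[[mi]], d, control, fseed)
      s <- summary(fit, pars = track)$table
      if (any(is.finite(s[, "rhat"]) & s[, "rhat"] > rhat_max)) {
        ctl2 <- control; ctl2$burn <- 2L * control$burn
        fit <- fit_model(models[[mi]], d, ctl2, fseed + 1L)
        s <- summary(fit, pars = track)$table
        if (any(is.finite(s[, "rhat"]) & s[, "rhat"] > rhat_max)) {
          excluded[mname] <- excluded[mname] + 1L
          next
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, model = mname, parameter = track,
        mean = s[track, "mean"],
        lower = s[track, "lower"], upper = s[track, "upper"],
        width = s[track, "upper"] - s[track, "lower"],
        cover = as.numeric(s[track, "lower"] <= tv[track] &
                             tv[track] <= s[track, "upper"]),
        row.names = NULL)
    }
  }
  reps <- do.call(rbind, rows)
  if (is.null(reps)) {
    warning("every replicate failed the convergence screen")
    reps <- data.frame(replicate = integer(0), model = character(0),
                       parameter = character(0), mean = numeric(0),
                       lower = numeric(0), upper = numeric(0),
                       width = numeric(0), cover = numeric(0))
  }
  agg <- do.call(rbind, lapply(split(reps, reps[c("model", "parameter")],
                                     drop = TRUE),
                               summarize_cell))
  rownames(agg) <- NULL
  structure(list(replicates = reps, summary = agg, excluded = excluded,
                 truth = tv[track], R = R, seed = seed),
            class = "mcp_study")
}

summarize_cell <- function(g) {
  n <- nrow(g)
  cov <- mean(g$cover)
  data.frame(model = g$model[1], parameter = g$parameter[1], n = n,
             avg_mean = mean(g$mean),
             mcse_mean = stats::sd(g$mean) / sqrt(n),
             avg_width = mean(g$width),
             mcse_width = stats::sd(g$width) / sqrt(n),
             coverage = cov,
             mcse_coverage = sqrt(cov * (1 - cov) / n))
}

#' @export
print.mcp_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicates (seed %d)\n", x$R, x$seed))
  cat("truth:", paste(sprintf("%s = %.3g", names(x$truth), x$truth),
                      collapse = ", "), "\n")
  if (any(x$excluded > 0))
    cat("excluded non-converged replicates:",
        paste(sprintf("%s: %d", names(x$excluded), x$excluded),
              collapse = ", "), "\n")
  df <- x$summary
  df[4:9] <- lapply(df[4:9], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Robustness of the corrected models to mis-stated se/sp
#'
#' Crosses an assumed sensitivity/specificity (fixed values for the
#' known-misclassification random-intercept model; prior centers for its
#' unknown-misclassification counterpart) against a grid of true
#' specificities, with the true sensitivity mildly shifted from the assumed
#' value. Reports bias and coverage per cell.
#'
#' @param true_sp grid of true specificities used to generate the data.
#' @param true_se true sensitivity used to generate the data.
#' @param assumed_se,assumed_sp the analyst's values: fixed in the
#'   known-misclassification model, prior centers (via the supplied
#'   `priors`) in the unknown-misclassification model.
#' @param priors beta priors for the unknown-misclassification model;
#'   default `Beta(35, 15)` for se (mean 0.7) and `Beta(40, 10)` for sp
#'   (mean 0.8).
#' @param sigma2 generating random-intercept variance.
#' @param R replicates per cell.
#' @param control,seed,track as in [run_study].
#' @return A list of class `"mcp_robustness"` with one [run_study] result
#'   per true specificity, plus a combined `summary` table keyed by
#'   `true_sp`.
#' @export
run_robustness <- function(true_sp = c(0.9, 0.8, 0.7, 0.6), true_se = 0.75,
                           assumed_se = 0.7, assumed_sp = 0.8,
                           priors = mcpois_priors(se = c(35, 15),
                                                  sp = c(40, 10)),
                           sigma2 = 0.10, R = 100,
                           control = mcpois_control(chains = 2, burn = 2000,
                                                    keep = 2000),
                           seed = 1, track = c("beta1", "gamma1")) {
  stopifnot(length(true_sp) >= 1)
  models <- list(
    known = mcp_model(effects = "random", misclass = "known",
                      se = assumed_se, sp = assumed_sp),
    prior = mcp_model(effects = "random", misclass = "unknown",
                      priors = priors))
  studies <- list()
  tabs <- list()
  for (i in seq_along(true_sp)) {
    st <- run_study(study_scenario(sigma2 = sigma2, se = true_se,
                                   sp = true_sp[i]),
                    models, R = R, control = control,
                    seed = seed + 1000003L * (i - 1L), track = track)
    studies[[i]] <- st
    tabs[[i]] <- cbind(true_sp = true_sp[i], st$summary)
  }
  structure(list(studies = studies, summary = do.call(rbind, tabs),
                 true_se = true_se, assumed = c(se = assumed_se,
                                                sp = assumed_sp)),
            class = "mcp_robustness")
}

#' @export
print.mcp_robustness <- function(x, ...) {
  cat(sprintf("Robustness sweep: true se = %.3g, assumed (se, sp) = (%.3g, %.3g)\n",
              x$true_se, x$assumed["se"], x$assumed["sp"]))
  df <- x$summary
  df[5:10] <- lapply(df[5:10], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fixed-(se, sp) grid sensitivity analysis
#'
#' Refits the known-misclassification model at each supplied `(se, sp)`
#' pair (for example an optimistic / most likely / pessimistic triple
#' elicited from an expert) and the unknown-misclassification model once
#' with the supplied priors, and reports the exposure coefficient `beta1`
#' posterior mean and equal-tailed 95% interval for each. When the data
#' carry essentially no information about `se` and `sp`, the prior-based
#' fit is a Monte Carlo sensitivity analysis; set `cut = TRUE` to force the
#' se/sp posteriors to equal their priors exactly.
#'
#' @param data an [mcp_data] object.
#' @param pairs a list of `c(se, sp)` pairs or a two-column matrix.
#' @param priors beta priors for the prior-based fit.
#' @param effects random-effect structure used by all fits.
#' @param control,seed as in [mcpois].
#' @param cut use the cut (prior-only se/sp) mode for the prior-based fit.
#' @param parameter which coefficient to report (default `"beta1"`).
#' @return A data frame of class `"mcp_sensitivity"` with columns `model`,
#'   `se`, `sp`, `mean`, `lower`, `upper`; the grid envelope is available
#'   through [conservative_interval()].
#' @export
run_sensitivity <- function(data, pairs, priors, effects = "random",
                            control = mcpois_control(chains = 2,
                                                     burn = 2000,
                                                     keep = 2000),
                            seed = 1, cut = FALSE, parameter = "beta1") {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  stopifnot(length(pairs) >= 1)
  f <- formula_for(data)
  rows <- list()
  for (i in seq_along(pairs)) {
    pr <- as.numeric(pairs[[i]])
    fit <- mcpois(f, data = data, effects = effects, misclass = "known",
                  se = pr[1], sp = pr[2], control = control,
                  seed = seed + i)
    s <- summary(fit, pars = parameter)$table
    rows[[i]] <- data.frame(model = "fixed", se = pr[1], sp = pr[2],
                            mean = s[1, "mean"], lower = s[1, "lower"],
                            upper = s[1, "upper"])
  }
  ctl <- control; ctl$cut_se_sp <- isTRUE(cut)
  fit <- mcpois(f, data = data, effects = effects, misclass = "unknown",
                priors = priors, control = ctl, seed = seed)
  s <- summary(fit, pars = parameter)$table
  rows[[length(rows) + 1L]] <-
    data.frame(model = if (cut) "prior-cut" else "prior",
               se = NA_real_, sp = NA_real_, mean = s[1, "mean"],
               lower = s[1, "lower"], upper = s[1, "upper"])
  out <- do.call(rbind, rows)
  class(out) <- c("mcp_sensitivity", "data.frame")
  attr(out, "parameter") <- parameter
  out
}

#' Conservative envelope interval over a sensitivity grid
#'
#' The envelope of the fixed-(se, sp) grid intervals: the smallest lower
#' limit paired with the largest upper limit. For a grid spanning
#' optimistic to pessimistic misclassification assumptions this is the
#' deliberately conservative combined interval.
#'
#' @param report an [run_sensitivity] result, or any data frame with
#'   `lower` and `upper` columns (and optionally a `model` column, in which
#'   case only `model == "fixed"` rows enter the envelope).
#' @return Named numeric `c(lower, upper)`.
#' @export
conservative_interval <- function(report) {
  if (!is.data.frame(report) || !all(c("lower", "upper") %in% names(report)))
    stop("report must contain lower and upper interval limits")
  if ("model" %in% names(report) && any(report$model == "fixed"))
    report <- report[report$model == "fixed", ]
  if (nrow(report) == 0) stop("no grid entries to combine")
  c(lower = min(report$lower), upper = max(report$upper))
}
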