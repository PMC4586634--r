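#' @export
print.mcpois <- function(x, ...) {
  cat("Bayesian misclassified-count Poisson regression\n")
  cat("  effects:", x$spec$effects, "  misclassification:", x$spec$misclass)
  if (x$spec$misclass == "known")
    cat(sprintf(" (se = %.3g, sp = %.3g)", x$se_fixed, x$sp_fixed))
  if (x$control$cut_se_sp) cat("  [cut: se/sp sampled from priors]")
  cat("\n")
  cat(sprintf("  %d units%s, %d chains x %d kept draws (burn-in %d, thin %d)\n",
              x$n, if (x$K > 0) sprintf(", %d clusters", x$K) else "",
              x$control$chains, x$control$keep, x$control$burn,
              x$control$thin))
  s <- summary(x)
  keep <- !grepl("^e[AB]", rownames(s$table))
  print(round(s$table[keep, , drop = FALSE], 3))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' Per-parameter posterior mean, standard deviation, equal-tailed credible
#' interval (empirical quantiles), split-chain R-hat and effective sample
#' size.
#'
#' @param object an [mcpois] fit.
#' @param level credible level (default 0.95).
#' @param pars optional character vector of parameter names to keep.
#' @param ... unused.
#' @return An object of class `"summary.mcpois"` whose `table` element is a
#'   numeric matrix with columns `mean`, `sd`, `lower`, `upper`, `rhat`,
#'   `ess`.
#' @export
summary.mcpois <- function(object, level = 0.95, pars = NULL, ...) {
  stopifnot(level > 0, level < 1)
  draws <- object$draws
  if (nrow(draws) < 100)
    stop("need at least 100 retained draws to summarize")
  if (nrow(draws) * (1 - level) / 2 < 1)
    stop("too few draws for the requested quantile level")
  if (!is.null(pars)) {
    miss <- setdiff(pars, colnames(draws))
    if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
    draws <- draws[, pars, drop = FALSE]
  }
  alpha <- (1 - level) / 2
  tab <- t(apply(draws, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      lower = unname(quantile(v, alpha)),
      upper = unname(quantile(v, 1 - alpha)))))
  rhat <- apply(draws, 2, split_rhat, chain = object$chain)
  ess <- apply(draws, 2, ess_basic, chain = object$chain)
  tab <- cbind(tab, rhat = rhat, ess = ess)
  structure(list(table = tab, level = level,
                 degenerate = rownames(tab)[tab[, "sd"] == 0]),
            class = "summary.mcpois")
}

#' @export
print.summary.mcpois <- function(x, ...) {
  cat(sprintf("Posterior summary (equal-tailed %g%% intervals)\n",
              100 * x$level))
  print(round(x$table, 4))
  if (length(x$degenerate))
    cat("note: degenerate (constant) draws for:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mcpois <- function(object, ...) {
  q <- length(object$covariates)
  nm <- c(paste0("beta", 0:(q - 1)), paste0("gamma", 0:(q - 1)))
  colMeans(object$draws[, nm])
}

#' @export
as.matrix.mcpois <- function(x, ...) x$draws

#' Flat draw table
#'
#' One row per retained iteration with chain and iteration columns, the
#' format written by [write_draws()].
#'
#' @param x an [mcpois] fit.
#' @param ... unused.
#' @export
as.data.frame.mcpois <- function(x, ...) {
  data.frame(chain = x$chain,
             iteration = rep(seq_len(x$control$keep), x$control$chains),
             x$draws, check.names = FALSE)
}

#' Write posterior draws as delimited text
#'
#' @param fit an [mcpois] fit.
#' @param path output path.
#' @param config optional config list recorded as a hash in the header.
#' @export
write_draws <- function(fit, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comments(fit$control$seed, config), con)
  write.csv(as.data.frame(fit), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trace plots
#'
#' @param x an [mcpois] fit.
#' @param pars parameters to plot (default: the exposure coefficients and,
#'   when sampled, se and sp).
#' @param ... passed to [graphics::plot].
#' @export
plot.mcpois <- function(x, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- c("beta1", "gamma1")
    if (x$spec$misclass == "unknown") pars <- c(pars, "se", "sp")
  }
  pars <- intersect(pars, colnames(x$draws))
  old <- par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  for (p in pars) {
    plot(x$draws[, p], type = "n", ylab = p, xlab = "", ...)
    for (ch in unique(x$chain)) {
      idx <- which(x$chain == ch)
      lines(idx, x$draws[idx, p], col = ch)
    }
  }
  invisible(x)
}
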