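#' MCMC settings
#'
#' @param chains number of independent chains.
#' @param burn burn-in iterations per chain (proposal scales adapt only
#'   here, targeting 20--40% acceptance, and are frozen afterwards).
#' @param keep retained iterations per chain after thinning.
#' @param thin thinning interval.
#' @param seed integer seed; together with the settings it fully determines
#'   the draws.
#' @param scales optional named list of initial proposal scales with any of
#'   the elements `coef`, `sesp`, `var`, `re`, `sweep` (single numbers); defaults are
#'   adapted away during burn-in anyway.
#' @param cut_se_sp if `TRUE`, the sensitivity and specificity are redrawn
#'   from their priors every iteration with no likelihood feedback -- the
#'   Monte Carlo sensitivity ("cut") mode, in which their posteriors match
#'   their priors by construction.
#' @param prior_only if `TRUE`, the likelihood is switched off and the
#'   sampler targets the prior (a validation hook; posterior moments should
#'   then reproduce prior moments).
#' @return An object of class `"mcpois_control"`.
#' @export
mcpois_control <- function(chains = 4, burn = 5000, keep = 5000, thin = 1,
                           seed = 1L, scales = NULL, cut_se_sp = FALSE,
                           prior_only = FALSE) {
  stopifnot(chains >= 1, burn >= 0, keep >= 1, thin >= 1)
  if (keep * thin + burn < 1000)
    warning("fewer than 1000 total iterations per chain; ",
            "summaries may be unreliable")
  defaults <- list(coef = 0.02, sesp = 0.25, var = 0.1, re = 0.05,
                   sweep = 0.1)
  if (!is.null(scales)) {
    unknown <- setdiff(names(scales), names(defaults))
    if (length(unknown)) stop("unknown scale block(s): ",
                              paste(unknown, collapse = ", "))
    defaults[names(scales)] <- scales
  }
  structure(list(chains = as.integer(chains), burn = as.integer(burn),
                 keep = as.integer(keep), thin = as.integer(thin),
                 seed = as.integer(seed), scales = defaults,
                 cut_se_sp = isTRUE(cut_se_sp),
                 prior_only = isTRUE(prior_only)),
            class = "mcpois_control")
}
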