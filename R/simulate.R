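#' Full-factorial binary covariate designs
#'
#' Builds the 2^p full factorial over binary covariates, each pattern
#' repeated `replicates` times. The first covariate `x` (the exposure)
#' varies slowest, so patterns 1..2^(p-1) are unexposed. Three cluster
#' conventions are offered:
#'
#' * `"pattern"`: replicates of the same covariate pattern share a cluster
#'   (K = 2^p) -- clustered sampling by covariate cell;
#' * `"unit"`: every observation is its own random-effect level (K = n) --
#'   pure overdispersion;
#' * `"crossed"`: K = 2^p clusters, each holding `replicates` distinct
#'   patterns chosen so exposure levels mix within cluster (with p = 3 and
#'   4 replicates every cluster is exactly balanced in `x`); this is the
#'   design of the clustered worked example, where the exposure contrast is
#'   estimated within clusters.
#'
#' @param n_binary number of binary covariates (>= 1); the first is the
#'   exposure `x`, the rest are `z1`, `z2`, ...
#' @param replicates observations per covariate pattern.
#' @param cluster cluster assignment rule.
#' @return A data frame with columns `x`, `z1`, ..., and `cluster`.
#' @examples
#' nrow(make_design(3, 3)) # 24 rows, 8 patterns
#' @export
make_design <- function(n_binary, replicates = 1,
                        cluster = c("pattern", "unit", "crossed")) {
  cluster <- match.arg(cluster)
  stopifnot(n_binary >= 1, replicates >= 1)
  n_pat <- 2L^n_binary
  # exposure x varies slowest
  grid <- expand.grid(rep(list(0:1), n_binary))[, n_binary:1, drop = FALSE]
  names(grid) <- c("x", if (n_binary > 1) paste0("z", seq_len(n_binary - 1)))
  pat <- rep(seq_len(n_pat), each = replicates)
  repl <- rep(seq_len(replicates), n_pat)
  out <- grid[pat, , drop = FALSE]
  rownames(out) <- NULL
  out$cluster <- switch(cluster,
    pattern = pat,
    unit = seq_along(pat),
    crossed = ((pat - 1L + 2L * (repl - 1L)) %% n_pat) + 1L)
  out
}

#' True generating configuration for the simulator
#'
#' @param beta,gamma true coefficient vectors (intercept, exposure, then
#'   any z covariates) for the cause-of-interest and other-cause log-rates.
#' @param se,sp true sensitivity and specificity in (0, 1]. A warning is
#'   issued if `se + sp <= 1` (a worse-than-random classifier).
#' @param re random-intercept structure: `"none"`, `"common"` (shared sd
#'   `sigma`), or `"correlated"` (`sigma1`, `sigma2`, `rho`).
#' @param sigma,sigma1,sigma2,rho random-intercept parameters.
#' @param t person-time per observation (scalar or per-row vector).
#' @param design data frame with the covariate columns (`x`, `z1`, ...) and,
#'   for random-intercept structures, a `cluster` column; see
#'   [make_design()].
#' @return An object of class `"mcp_truth"`.
#' @export
truth_config <- function(beta, gamma, se = 1, sp = 1,
                         re = c("none", "common", "correlated"),
                         sigma = 0, sigma1 = 0, sigma2 = 0, rho = 0,
                         t = 1000, design) {
  re <- match.arg(re)
  q <- 1 + sum(!(names(design) %in% "cluster"))
  if (length(beta) != q || length(gamma) != q)
    stop("beta and gamma must have length ", q,
         " (intercept + covariate columns)")
  stopifnot(se > 0, se <= 1, sp > 0, sp <= 1)
  if (se + sp <= 1)
    warning("se + sp <= 1: the generating classifier is worse than random")
  if (re != "none" && is.null(design$cluster))
    stop("random-intercept truth requires a cluster column in the design")
  if (re == "common") stopifnot(sigma >= 0)
  if (re == "correlated") stopifnot(sigma1 >= 0, sigma2 >= 0,
                                    rho > -1, rho < 1)
  n <- nrow(design)
  t <- rep_len(t, n)
  stopifnot(all(t > 0))
  structure(list(beta = beta, gamma = gamma, se = se, sp = sp, re = re,
                 sigma = sigma, sigma1 = sigma1, sigma2 = sigma2, rho = rho,
                 t = t, design = design),
            class = "mcp_truth")
}

#' Simulate misclassified count data
#'
#' Generates data exactly by the assumed mechanism: cluster random
#' intercepts (when configured) are drawn first, the latent true counts
#' `y1 ~ Poisson(t lambda)`, `y2 ~ Poisson(t mu)` next, then the
#' cross-misclassified counts `u1 ~ Binomial(y1, 1 - se)` (true cases
#' labeled other) and `u2 ~ Binomial(y2, 1 - sp)`, giving observed `w1 = y1
#' - u1 + u2` and `w2 = y2 + u1 - u2`. Negative observed counts are
#' impossible by construction and the totals are conserved: `w1 + w2 = y1 +
#' y2`.
#'
#' @param truth an [truth_config] object.
#' @param seed integer seed; the output is fully determined by it.
#' @param latent if `TRUE`, attach the hidden latent record (y, u, random
#'   intercepts) as `attr(, "latent")` for testing; never written by
#'   [write_counts()].
#' @return An [mcp_data] object.
#' @export
simulate_counts <- function(truth, seed, latent = FALSE) {
  set.seed(seed)
  des <- truth$design
  n <- nrow(des)
  has_cl <- !is.null(des$cluster)
  K <- if (has_cl) max(des$cluster) else 0L
  eA <- eB <- rep(0, max(K, 1))
  if (truth$re == "common") {
    eA <- rnorm(K, 0, truth$sigma)
    eB <- rnorm(K, 0, truth$sigma)
  } else if (truth$re == "correlated") {
    z1 <- rnorm(K); z2 <- rnorm(K)
    eA <- truth$sigma1 * z1
    eB <- truth$sigma2 * (truth$rho * z1 + sqrt(1 - truth$rho^2) * z2)
  }
  zcols <- setdiff(names(des), c("x", "cluster"))
  X <- cbind(1, des$x, as.matrix(des[zcols]))
  eta_l <- drop(X %*% truth$beta)
  eta_m <- drop(X %*% truth$gamma)
  if (truth$re != "none") {
    eta_l <- eta_l + eA[des$cluster]
    eta_m <- eta_m + eB[des$cluster]
  }
  y1 <- rpois(n, truth$t * exp(eta_l))
  y2 <- rpois(n, truth$t * exp(eta_m))
  u1 <- rbinom(n, y1, 1 - truth$se)
  u2 <- rbinom(n, y2, 1 - truth$sp)
  w1 <- y1 - u1 + u2
  w2 <- y2 + u1 - u2
  stopifnot(all(w1 >= 0), all(w2 >= 0)) # guaranteed by construction
  out <- mcp_data(w1 = w1, w2 = w2, t = truth$t, x = des$x,
                  z = if (length(zcols)) des[zcols] else NULL,
                  cluster = if (has_cl) des$cluster else NULL)
  attr(out, "truth") <- truth
  if (latent)
    attr(out, "latent") <- list(y1 = y1, y2 = y2, u1 = u1, u2 = u2,
                                e_lambda = eA, e_mu = eB)
  out
}

#' Expected observed counts under the generating configuration
#'
#' Marginal means of the observed labeled counts with the random
#' intercepts integrated out analytically (a log-normal factor
#' `exp(sigma^2 / 2)` on each stream): `E[w1] = t (lambda se exp(sA^2/2) +
#' mu (1 - sp) exp(sB^2/2))` and the complementary expression for `E[w2]`.
#' Their sum is always the random-effect-inflated `t (lambda + mu)`:
#' relabeling moves events between streams but never creates or destroys
#' them.
#'
#' @param truth an [truth_config] object.
#' @return A list with vectors `w1` and `w2`.
#' @export
marginal_observed_means <- function(truth) {
  des <- truth$design
  zcols <- setdiff(names(des), c("x", "cluster"))
  X <- cbind(1, des$x, as.matrix(des[zcols]))
  lam <- exp(drop(X %*% truth$beta))
  mu <- exp(drop(X %*% truth$gamma))
  fA <- switch(truth$re, none = 1, common = exp(truth$sigma^2 / 2),
               correlated = exp(truth$sigma1^2 / 2))
  fB <- switch(truth$re, none = 1, common = exp(truth$sigma^2 / 2),
               correlated = exp(truth$sigma2^2 / 2))
  list(w1 = truth$t * (lam * truth$se * fA + mu * (1 - truth$sp) * fB),
       w2 = truth$t * (lam * (1 - truth$se) * fA + mu * truth$sp * fB))
}
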