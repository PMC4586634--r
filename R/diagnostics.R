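# Split-chain potential scale reduction factor. Each chain is split in
# half so that within-chain drift also registers as disagreement.
split_rhat <- function(x, chain) {
  pieces <- split_halves(x, chain)
  m <- length(pieces)
  n <- min(lengths(pieces))
  if (n < 2 || m < 2) return(NA_real_)
  pieces <- lapply(pieces, function(p) p[seq_len(n)])
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(ifelse(B == 0, 1, Inf))
  sqrt(((n - 1) / n * W + B / n) / W)
}

split_halves <- function(x, chain) {
  out <- list()
  for (ch in unique(chain)) {
    xc <- x[chain == ch]
    h <- floor(length(xc) / 2)
    out <- c(out, list(xc[seq_len(h)], xc[(h + 1):(2 * h)]))
  }
  out
}

# Effective sample size from chain-averaged autocorrelations with Geyer's
# initial monotone positive sequence truncation.
ess_basic <- function(x, chain) {
  chains <- split(x, chain)
  n <- min(lengths(chains))
  m <- length(chains)
  if (n < 4) return(NA_real_)
  chains <- lapply(chains, function(p) p[seq_len(n)])
  W <- mean(vapply(chains, var, 0))
  means <- vapply(chains, mean, 0)
  varplus <- W * (n - 1) / n + (if (m > 1) var(means) else 0)
  if (!is.finite(varplus) || varplus <= 0) return(NA_real_)
  lag_max <- min(n - 2, 500)
  acov <- sapply(chains, function(p)
    acf(p, lag.max = lag_max, type = "covariance", plot = FALSE,
        demean = TRUE)$acf[, 1, 1])
  acov <- if (is.matrix(acov)) rowMeans(acov) else acov
  rho <- 1 - (W - acov) / varplus # index 1 is lag 0
  # Geyer pairs (rho_0 + rho_1), (rho_2 + rho_3), ... kept while positive,
  # forced non-increasing
  P <- numeric(0); k <- 0; prev <- Inf
  while (2 * k + 2 <= length(rho)) {
    pair <- rho[2 * k + 1] + rho[2 * k + 2]
    if (pair < 0) break
    pair <- min(pair, prev)
    P <- c(P, pair); prev <- pair; k <- k + 1
  }
  tau <- max(-1 + 2 * sum(P), 1e-8)
  ess <- m * n / tau
  max(min(ess, m * n), 1)
}
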