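#' Construct a misclassified-count dataset
#'
#' Bundles the per-unit observed counts and design information into a
#' validated data frame. Each observational unit carries two observed event
#' counts: `w1`, events labeled as the cause of interest, and `w2`, events
#' labeled as any other cause. The labels may be wrong: a true cause-of-
#' interest event is labeled correctly with probability `se` (sensitivity)
#' and a true other-cause event with probability `sp` (specificity); those
#' parameters belong to the model, not the data.
#'
#' @param w1 non-negative integer vector, observed counts labeled as the
#'   cause of interest.
#' @param w2 non-negative integer vector, observed counts labeled as other
#'   causes.
#' @param t positive numeric vector, person-time opportunity size per unit.
#' @param x exposure indicator (or numeric exposure) per unit.
#' @param z optional data frame or matrix of additional covariates.
#' @param cluster optional integer cluster labels; must form a contiguous
#'   index set `1..K`. Required by random-intercept models.
#' @return A data frame of class `"mcp_data"` with columns `unit`,
#'   (`cluster`,) `t`, `w1`, `w2`, `x`, and any `z` columns.
#' @examples
#' d <- mcp_data(w1 = c(5, 3), w2 = c(10, 12), t = c(100, 100), x = c(0, 1))
#' @export
mcp_data <- function(w1, w2, t, x, z = NULL, cluster = NULL) {
  n <- length(w1)
  lens <- c(length(w2), length(t), length(x))
  if (any(lens != n))
    stop("w1, w2, t and x must have equal length")
  check_counts(w1, "w1")
  check_counts(w2, "w2")
  if (any(!is.finite(t)) || any(t <= 0))
    stop("person-time t must be positive and finite")
  out <- data.frame(unit = seq_len(n))
  if (!is.null(cluster)) {
    check_cluster(cluster, n)
    out$cluster <- as.integer(cluster)
  }
  out$t <- as.numeric(t)
  out$w1 <- as.integer(round(w1))
  out$w2 <- as.integer(round(w2))
  out$x <- as.numeric(x)
  if (!is.null(z)) {
    z <- as.data.frame(z)
    if (nrow(z) != n) stop("z must have one row per unit")
    if (is.null(names(z)) || any(!nzchar(names(z))))
      names(z) <- paste0("z", seq_len(ncol(z)))
    out <- cbind(out, z)
  }
  class(out) <- c("mcp_data", "data.frame")
  out
}

check_counts <- function(w, name) {
  if (any(!is.finite(w))) stop(name, " contains non-finite values")
  if (any(w < 0)) {
    bad <- which(w < 0)[1]
    stop(name, " must be non-negative (row ", bad, ")")
  }
  if (any(abs(w - round(w)) > 1e-8)) {
    bad <- which(abs(w - round(w)) > 1e-8)[1]
    stop(name, " must be integer counts (row ", bad, ")")
  }
  invisible(TRUE)
}

check_cluster <- function(cluster, n) {
  if (length(cluster) != n) stop("cluster must have one label per unit")
  cl <- as.integer(cluster)
  if (any(is.na(cl))) stop("cluster labels must be integers")
  K <- max(cl)
  if (min(cl) != 1L || !all(seq_len(K) %in% cl))
    stop("cluster labels must form a contiguous index set 1..K")
  invisible(TRUE)
}

#' Read a misclassified-count dataset from delimited text
#'
#' Expects a comma-separated file with a header row containing at least the
#' columns `unit`, `t`, `w1`, `w2`, `x`; a `cluster` column and covariate
#' columns `z1`, `z2`, ... are optional. Lines starting with `#` are
#' treated as comments.
#'
#' @param path file path.
#' @return An [mcp_data] object.
#' @export
read_counts <- function(path) {
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("unit", "t", "w1", "w2", "x")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (cc in c("w1", "w2")) {
    w <- raw[[cc]]
    if (any(!is.finite(w)) || any(w < 0) || any(w != round(w))) {
      bad <- which(!is.finite(w) | w < 0 | w != round(w))[1]
      stop("column ", cc, ", row ", bad, ": counts must be non-negative integers")
    }
  }
  if (any(raw$t <= 0)) {
    bad <- which(raw$t <= 0)[1]
    stop("column t, row ", bad, ": person-time must be positive")
  }
  zcols <- grep("^z[0-9]+$", names(raw), value = TRUE)
  mcp_data(w1 = raw$w1, w2 = raw$w2, t = raw$t, x = raw$x,
           z = if (length(zcols)) raw[zcols] else NULL,
           cluster = if ("cluster" %in% names(raw)) raw$cluster else NULL)
}

#' Write a misclassified-count dataset as delimited text
#'
#' Writes a CSV with `#`-prefixed comment headers recording the seed and a
#' configuration hash so output files are self-describing.
#'
#' @param data an [mcp_data] object (or compatible data frame).
#' @param path output file path.
#' @param seed optional integer recorded in the header.
#' @param config optional configuration list; its hash is recorded.
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comments(seed, config), con)
  write.csv(as.data.frame(data), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

header_comments <- function(seed = NULL, config = NULL) {
  c(sprintf("# mcpois %s", as.character(utils::packageVersion("mcpois"))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else as.character(seed)),
    sprintf("# config_hash: %s",
            if (is.null(config)) "NA" else config_hash(config)))
}

# design matrix with intercept first, exposure x second, z columns after;
# the exposure coefficient therefore always sits in position 2
design_matrix <- function(data) {
  zcols <- setdiff(names(data), c("unit", "cluster", "t", "w1", "w2", "x"))
  X <- cbind(1, data$x)
  cn <- c("(Intercept)", "x")
  for (zc in zcols) { X <- cbind(X, data[[zc]]); cn <- c(cn, zc) }
  colnames(X) <- cn
  X
}
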