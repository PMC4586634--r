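# Recognized configuration sections and keys. Unknown keys are rejected so
# a typo in a sweep config fails loudly instead of silently using defaults.
config_schema <- list(
  model = c("effects", "misclass", "se", "sp"),
  priors = c("coef_sd", "se", "sp", "sigma_upper", "sigma1_upper",
             "sigma2_upper"),
  mcmc = c("chains", "burn", "keep", "thin", "seed", "cut_se_sp"),
  study = c("R", "sigma2", "se_true", "sp_true", "track"),
  paths = c("data", "out"),
  seed = NULL
)

#' Read and validate a run configuration
#'
#' Run configurations are flat YAML files with the sections `model`,
#' `priors`, `mcmc`, `study`, `paths` and a top-level `seed`. Unknown keys
#' are rejected. The file format round-trips losslessly through
#' [write_run_config()].
#'
#' @param path YAML file path.
#' @return A named list of class `"mcp_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  class(cfg) <- "mcp_config"
  cfg
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(cfg), names(config_schema))) {
    if (is.null(config_schema[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a run configuration
#'
#' @param config a configuration list (validated against the schema).
#' @param path output YAML path.
#' @export
write_run_config <- function(config, path) {
  validate_config(config)
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Short content hash of a configuration
#'
#' A 32-bit FNV-1a hash of the canonical deparse, embedded in output file
#' headers so artifacts can be matched to the configuration that produced
#' them.
#'
#' @param config any R object.
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(txt) %% 256
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256 # b < 256, so the xor only touches the low byte
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # multiply by the FNV prime mod 2^32 without exceeding double precision
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
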