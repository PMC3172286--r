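#' Analysis run configuration
#'
#' Bundles the pipeline's cutoffs. Defaults mirror the thresholds the
#' analysis is designed around: per-timepoint differential call at p < 0.05,
#' profile significance at corrected p < 0.001, enrichment at p < 0.05, 50
#' model temporal profiles with maximum unit change 2, correlation-network
#' edges at |r| >= 0.8, and PPI hub degree > 10 (i.e. minimum 11).
#'
#' @param alpha_de Per-timepoint differential significance level.
#' @param alpha_profile Corrected significance level for model profiles.
#' @param alpha_enrich Significance level for term enrichment.
#' @param n_model_profiles Number of model temporal profiles to select.
#' @param max_unit_change Largest allowed per-step change of a model profile.
#' @param correlation_threshold Minimum |Pearson r| for a co-expression edge.
#' @param hub_min_degree Minimum within-subnetwork degree of a PPI hub.
#' @param seed Integer seed applied to any stochastic step.
#' @return A list of class `radhub_config`.
#' @export
run_config <- function(alpha_de = 0.05,
                       alpha_profile = 0.001,
                       alpha_enrich = 0.05,
                       n_model_profiles = 50L,
                       max_unit_change = 2L,
                       correlation_threshold = 0.8,
                       hub_min_degree = 11L,
                       seed = 0L) {
  cfg <- list(
    alpha_de = alpha_de,
    alpha_profile = alpha_profile,
    alpha_enrich = alpha_enrich,
    n_model_profiles = as.integer(n_model_profiles),
    max_unit_change = as.integer(max_unit_change),
    correlation_threshold = correlation_threshold,
    hub_min_degree = as.integer(hub_min_degree),
    seed = as.integer(seed)
  )
  for (a in c("alpha_de", "alpha_profile", "alpha_enrich")) {
    if (!is.numeric(cfg[[a]]) || cfg[[a]] <= 0 || cfg[[a]] >= 1) {
      stop(a, " must lie strictly in (0, 1)")
    }
  }
  if (cfg$n_model_profiles < 1L) stop("n_model_profiles must be positive")
  if (cfg$max_unit_change < 1L) stop("max_unit_change must be positive")
  if (cfg$correlation_threshold < 0 || cfg$correlation_threshold > 1) {
    stop("correlation_threshold must lie in [0, 1]")
  }
  if (cfg$hub_min_degree < 1L) stop("hub_min_degree must be positive")
  structure(cfg, class = "radhub_config")
}

#' Read a flat `key = value` configuration file
#'
#' Unknown keys are rejected; omitted keys take the [run_config()] defaults.
#'
#' @param path Path to the config file. Lines starting with `#` are ignored.
#' @return A `radhub_config` list.
#' @export
read_config <- function(path) {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, integer(1)) != 2L)
  if (length(bad) > 0L) stop("config line not of the form key = value: ", lines[bad[1L]])
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(as.numeric(vals)), keys)
  do.call(run_config, args)
}

#' Write a configuration to a flat `key = value` file
#'
#' @param cfg A `radhub_config` list.
#' @param path Output path.
#' @return `cfg`, invisibly.
#' @export
write_config <- function(cfg, path) {
  readr::write_lines(
    sprintf("%s = %s", names(cfg), vapply(cfg, format, character(1))),
    path
  )
  invisible(cfg)
}

#' @export
print.radhub_config <- function(x, ...) {
  cat("# radhub run configuration\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
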