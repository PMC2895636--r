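#' Run configuration
#'
#' Bundles every knob of a full analysis run — kinetics file, simulation
#' and classifier settings, partition schemes, correlation cutoffs,
#' correlation-based-population settings and the top-level RNG seed — so
#' that each output can record exactly how it was produced. The default
#' configuration locks all reference values (spike threshold -30 mV,
#' periodicity 1%, burst rule 30%, chi2 > 500, |rho| > 0.2, mask
#' threshold 3%).
#'
#' @param kinetics_path Kinetics YAML path.
#' @param sim A [sim_config()].
#' @param classifier A [classifier_config()].
#' @param schemes A scheme configuration ([default_schemes()]).
#' @param seed Top-level RNG seed; every stochastic stage derives from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(kinetics_path = default_kinetics_path(),
                       sim = sim_config(),
                       classifier = classifier_config(),
                       schemes = default_schemes(),
                       seed = 1L) {
  structure(
    list(kinetics_path = kinetics_path, sim = sim, classifier = classifier,
         schemes = schemes, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Configuration hash for provenance blocks
#'
#' A short deterministic digest of a run configuration (serialised to
#' YAML, then hashed with a simple polynomial rolling hash; no
#' cryptographic strength needed, only change detection).
#'
#' @param config A `run_config` (or any serialisable list).
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647   # fits in double exactly
  }
  sprintf("%08x", h)
}

provenance_block <- function(config) {
  list(config_hash = config_hash(config), seed = config$seed,
       package_version = as.character(utils::packageVersion("condcorr")))
}

#' Write the analysis report tables
#'
#' Emits the standard TSV outputs of a run into a directory:
#' `scan_results.tsv` (every pair x population test with statistics and
#' flags), `correlations.tsv` (the passing subset — the shape of the
#' per-activity-type correlation table), `sign_matrix.tsv` (pair x
#' population sign summary), `flagged.tsv` (edge-concentration review
#' list), optionally `success.tsv` (correlation-based population
#' enrichment reports), and `provenance.yaml` (config hash + seed).
#'
#' @param scan A `correlation_scan`.
#' @param dir Output directory (created if needed).
#' @param success Optional tibble of [success_report()] rows (with any
#'   identifying columns the caller added).
#' @param config A `run_config` for the provenance block.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(scan, dir, success = NULL, config = run_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- as_tibble(scan)
  readr::write_tsv(x, file.path(dir, "scan_results.tsv"))
  readr::write_tsv(dplyr::filter(x, .data$is_correlation),
                   file.path(dir, "correlations.tsv"))
  readr::write_tsv(correlation_sign_matrix(scan),
                   file.path(dir, "sign_matrix.tsv"))
  readr::write_tsv(dplyr::filter(x, .data$flagged_edge & .data$is_correlation),
                   file.path(dir, "flagged.tsv"))
  if (!is.null(success)) {
    readr::write_tsv(as_tibble(success), file.path(dir, "success.tsv"))
  }
  yaml::write_yaml(provenance_block(config),
                   file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Export a voltage trace as tidy TSV
#'
#' @param trace A `voltage_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_tsv(as_tibble(trace), path)
  invisible(path)
}
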