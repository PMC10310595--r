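#' Pipeline stage: simulate a dataset to files
#'
#' Wraps [generate_soil()] and [generate_bioaccess()] and writes three CSVs
#' into `out_dir`: `samples.csv` (wide, with `"<LOD"` marks),
#' `bioaccess.csv`, and `truth.csv` (latent values keyed by sample and
#' element). Deterministic for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_soil(config)
  bio <- generate_bioaccess(config, gen$samples)
  paths <- list(samples = file.path(out_dir, "samples.csv"),
                bioaccess = file.path(out_dir, "bioaccess.csv"),
                truth = file.path(out_dir, "truth.csv"))
  write_samples(gen$samples, paths$samples)
  write_bioaccess(bio, paths$bioaccess)
  write_results(gen$truth, paths$truth)
  log_stage("simulate", sprintf(
    "%d samples x %d elements, %d censored cells, seed %d",
    dplyr::n_distinct(gen$samples$sample_id), length(config$elements),
    sum(gen$samples$censored), config$seed))
  invisible(paths)
}

#' Pipeline stage: censored summaries and pairwise screen
#'
#' Kaplan-Meier summary statistics per element and site group plus the
#' pairwise Peto-Peto screen, written to `summary.csv` and `screen.csv`.
#'
#' @param samples Long sample tibble, or a path to a samples CSV.
#' @param out_dir Output directory.
#' @param alpha Screen significance level (BH-adjusted).
#' @return List with `summary` and `screen` tibbles, invisibly.
#' @export
run_summarize <- function(samples, out_dir, alpha = 0.05) {
  if (is.character(samples)) samples <- read_samples(samples)
  if (nrow(samples) == 0) abort_soilrisk("Empty dataset.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- summarize_elements(samples)
  scr <- if (dplyr::n_distinct(samples$site_group) >= 2) {
    pairwise_screen(samples, alpha = alpha)
  } else {
    NULL
  }
  write_results(summ, file.path(out_dir, "summary.csv"))
  if (!is.null(scr)) write_results(scr, file.path(out_dir, "screen.csv"))
  log_stage("summarize", sprintf(
    "%d element x group cells; %s", nrow(summ),
    if (is.null(scr)) "single group, screen skipped"
    else sprintf("%d pairwise tests, %d element(s) flagged no-difference",
                 nrow(scr), dplyr::n_distinct(scr$element[scr$no_group_difference]))))
  invisible(list(summary = summ, screen = scr))
}

#' Pipeline stage: indices, exceedance and risk tables
#'
#' Runs the pollution indices (when background means are configured), the
#' guideline exceedance screen, bioaccessibility processing, and the full
#' risk assessment, writing `indices.csv`, `exceedance.csv`, `rba.csv` and
#' `risk.csv`.
#'
#' @param samples Long sample tibble or path.
#' @param bioaccess Canonical extraction tibble, path, or `NULL` (falls back
#'   to packaged site-mean IVBA values; fixed-RBA elements are unaffected,
#'   direct-IVBA elements are flagged).
#' @param config Run configuration list ([read_run_config()]), or `NULL` for
#'   defaults.
#' @param out_dir Output directory.
#' @param registry Element registry.
#' @return List with `indices`, `exceedance`, `rba`, `risk` tibbles,
#'   invisibly.
#' @export
run_assess <- function(samples, bioaccess = NULL, config = NULL, out_dir,
                       registry = element_registry()) {
  if (is.character(samples)) samples <- read_samples(samples, registry)
  if (is.character(bioaccess)) bioaccess <- read_bioaccess(bioaccess)
  cfg <- config %||% read_run_config(NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$backgrounds)) {
    registry <- set_backgrounds(registry, cfg$backgrounds)
  }
  summ <- summarize_elements(samples)
  exceed <- guideline_screen(summ, registry)

  indices <- NULL
  if (any(is.finite(registry$background_mean))) {
    indices <- pollution_indices(samples, registry, by = "group",
                                 censoring = cfg$censoring)
    write_results(indices, file.path(out_dir, "indices.csv"))
  }

  rba <- if (is.null(bioaccess)) {
    rba_map(NULL, registry)
  } else {
    rba_map(process_bioaccess(bioaccess, registry), registry)
  }
  risk <- assess_dataset(samples, rba, receptors = cfg$receptors,
                         registry = registry, censoring = cfg$censoring,
                         hi_limit = cfg$thresholds$hi_limit,
                         cr_limit = cfg$thresholds$cr_limit)
  write_results(exceed, file.path(out_dir, "exceedance.csv"))
  write_results(rba, file.path(out_dir, "rba.csv"))
  write_results(tibble::as_tibble(risk), file.path(out_dir, "risk.csv"))
  defaulted <- rba$element[grepl("rba_defaulted", rba$flags)]
  log_stage("assess", sprintf(
    "%d risk rows; censoring=%s; RBA defaulted for: %s",
    nrow(risk), cfg$censoring,
    if (length(defaulted) == 0) "none" else paste(defaulted, collapse = ",")))
  invisible(list(indices = indices, exceedance = exceed, rba = rba, risk = risk))
}

log_stage <- function(stage, msg) {
  message(sprintf("[soilrisk:%s] %s", stage, msg))
}
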