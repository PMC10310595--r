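#' Read a soil-sample concentration table
#'
#' Reads a wide delimited file with one row per sample and one column per
#' element, returning the package's canonical long sample table. Two
#' censoring dialects are accepted:
#' \itemize{
#'   \item text marks: a cell `"<4"` means the result is below a reporting
#'     limit of 4 mg/kg (left-censored);
#'   \item paired columns: `Pb` holding the bound and a logical `Pb_cen`
#'     flag marking censored rows.
#' }
#'
#' @param path Path to a CSV file with header columns `sample_id`,
#'   `site_group`, optional `x`/`y` (local coordinates, m), and one column
#'   per element (mg/kg).
#' @param registry Element registry ([element_registry()]). Element columns
#'   absent from the registry are dropped with a warning.
#' @return Long tibble with columns `sample_id`, `site_group`, `x`, `y`,
#'   `element`, `conc` (mg/kg, `NA` when censored), `censored` (logical),
#'   `lod` (the reporting bound for censored cells, else the registry LOD).
#' @export
read_samples <- function(path, registry = element_registry()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("sample_id", "site_group")
  if (!all(required %in% names(raw))) {
    abort_soilrisk("Sample file must have `sample_id` and `site_group` columns.")
  }
  bad_group <- which(!raw$site_group %in% SITE_GROUPS)
  if (length(bad_group) > 0) {
    abort_soilrisk(paste0(
      "Unknown site_group '", raw$site_group[bad_group[1]], "' in data row ",
      bad_group[1], "; expected one of: ", paste(SITE_GROUPS, collapse = ", ")))
  }
  meta_cols <- intersect(c("sample_id", "site_group", "x", "y"), names(raw))
  flag_cols <- grep("_cen$", names(raw), value = TRUE)
  value_cols <- setdiff(names(raw), c(meta_cols, flag_cols))
  unknown <- setdiff(value_cols, registry$element)
  if (length(unknown) > 0) {
    rlang::warn(paste0("Ignoring unknown element column(s): ",
                       paste(unknown, collapse = ", ")))
    value_cols <- setdiff(value_cols, unknown)
  }
  if (length(value_cols) == 0) {
    abort_soilrisk("No recognised element columns in sample file.")
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(sample_id = character(), site_group = character(),
                          x = double(), y = double(), element = character(),
                          conc = double(), censored = logical(), lod = double()))
  }

  parse_cell <- function(cell, element, flag, row) {
    if (is.na(cell) || cell == "") {
      return(tibble::tibble(conc = NA_real_, censored = NA, lod = NA_real_))
    }
    cens_mark <- grepl("^\\s*<", cell)
    num <- suppressWarnings(as.numeric(sub("^\\s*<\\s*", "", cell)))
    if (is.na(num)) {
      abort_soilrisk(paste0("Cannot parse '", cell, "' for ", element,
                            " in data row ", row, "."))
    }
    if (num <= 0) {
      abort_soilrisk(paste0("Non-positive concentration ", num, " for ", element,
                            " in data row ", row, "."))
    }
    censored <- cens_mark || isTRUE(flag)
    lod_default <- registry$lod_xrf[match(element, registry$element)]
    tibble::tibble(
      conc = if (censored) NA_real_ else num,
      censored = censored,
      lod = if (censored) num else lod_default
    )
  }

  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    purrr::map_dfr(value_cols, function(el) {
      flag_col <- paste0(el, "_cen")
      flag <- if (flag_col %in% names(raw)) {
        tolower(raw[[flag_col]][i]) %in% c("true", "t", "1", "yes")
      } else {
        FALSE
      }
      parsed <- parse_cell(raw[[el]][i], el, flag, i)
      dplyr::mutate(parsed, element = el, .before = 1)
    })
  })
  meta <- tibble::tibble(
    sample_id = raw$sample_id,
    site_group = raw$site_group,
    x = if ("x" %in% names(raw)) as.numeric(raw$x) else NA_real_,
    y = if ("y" %in% names(raw)) as.numeric(raw$y) else NA_real_
  )
  if (anyDuplicated(meta$sample_id)) {
    abort_soilrisk("Duplicate sample_id values in sample file.")
  }
  out <- dplyr::bind_cols(
    meta[rep(seq_len(nrow(meta)), each = length(value_cols)), ],
    dplyr::bind_rows(rows)
  )
  dplyr::filter(out, !is.na(.data$censored))
}

#' Write a long sample table as a wide CSV with censoring marks
#'
#' Inverse of [read_samples()]: censored cells are rendered as `"<lod"`.
#'
#' @param samples Long sample tibble (see [read_samples()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  wide <- samples |>
    dplyr::mutate(cell = ifelse(.data$censored,
                                paste0("<", sprintf("%.15g", .data$lod)),
                                sprintf("%.15g", .data$conc))) |>
    dplyr::select("sample_id", "site_group", "x", "y", "element", "cell") |>
    tidyr::pivot_wider(names_from = "element", values_from = "cell")
  if (all(is.na(wide$x)) && all(is.na(wide$y))) {
    wide$x <- NULL
    wide$y <- NULL
  }
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a bioaccessibility-extraction table
#'
#' @param path CSV with columns `sample_id`, `element`, `extract_conc_ugL`
#'   (µg/L), `soil_mass_g` (g), `fluid_volume_mL` (mL), `total_mgkg` (mg/kg),
#'   and optionally `extract_lod_ugL`.
#' @return Tibble with canonical columns `sample_id`, `element`,
#'   `extract_conc` (µg/L), `soil_mass` (g), `fluid_volume` (L),
#'   `total_conc` (mg/kg), `extract_lod` (µg/L, `NA` if absent).
#' @export
read_bioaccess <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    element = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("sample_id", "element", "extract_conc_ugL", "soil_mass_g",
                "fluid_volume_mL", "total_mgkg")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_soilrisk(paste0("Bioaccessibility file missing column(s): ",
                          paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    sample_id = raw$sample_id,
    element = raw$element,
    extract_conc = raw$extract_conc_ugL,
    soil_mass = raw$soil_mass_g,
    fluid_volume = raw$fluid_volume_mL / 1000,
    total_conc = raw$total_mgkg,
    extract_lod = if ("extract_lod_ugL" %in% names(raw)) raw$extract_lod_ugL else NA_real_
  )
}

#' Write a bioaccessibility table in the CSV dialect read_bioaccess() reads
#'
#' @param bioaccess Tibble in the canonical layout of [read_bioaccess()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bioaccess <- function(bioaccess, path) {
  out <- tibble::tibble(
    sample_id = bioaccess$sample_id,
    element = bioaccess$element,
    extract_conc_ugL = bioaccess$extract_conc,
    soil_mass_g = bioaccess$soil_mass,
    fluid_volume_mL = bioaccess$fluid_volume * 1000,
    total_mgkg = bioaccess$total_conc
  )
  if (!all(is.na(bioaccess$extract_lod))) out$extract_lod_ugL <- bioaccess$extract_lod
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write any pipeline result table to CSV
#'
#' Columns keep their current order; numeric columns may be rounded to a
#' fixed number of significant digits for presentation copies. The default
#' (`digits = NA`) writes full precision so tables round-trip through
#' [readr::read_csv()] exactly.
#'
#' @param results A data frame / tibble.
#' @param path Output file path.
#' @param digits Significant digits for numeric columns, or `NA` for full
#'   precision.
#' @param allow_empty Permit writing a header-only file for zero-row input.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, digits = NA, allow_empty = FALSE) {
  if (nrow(results) == 0 && !allow_empty) {
    abort_soilrisk("Refusing to write an empty results table (set allow_empty = TRUE).")
  }
  out <- results
  if (!is.na(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            ~ signif(.x, digits)))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML with optional keys `seed`, `backgrounds` (element -> mg/kg),
#' `censoring` (one of `"half_lod"`, `"lod"`, `"zero"`), `thresholds`
#' (`hi_limit`, `cr_limit`, `alpha`), and `receptors` (list of receptor
#' parameter maps understood by [receptor_profile()]).
#'
#' @param path YAML file path.
#' @return A list with filled defaults: `seed`, `backgrounds`, `censoring`,
#'   `thresholds`, `receptors` (a receptor tibble).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  thresholds <- cfg$thresholds %||% list()
  thresholds$hi_limit <- thresholds$hi_limit %||% 1
  thresholds$cr_limit <- thresholds$cr_limit %||% 1e-5
  thresholds$alpha <- thresholds$alpha %||% 0.05
  if (any(unlist(thresholds) <= 0)) abort_soilrisk("Thresholds must be > 0.")
  receptors <- if (is.null(cfg$receptors)) {
    default_receptors()
  } else {
    purrr::map_dfr(cfg$receptors, ~ do.call(receptor_profile, .x))
  }
  censoring <- cfg$censoring %||% "half_lod"
  if (!censoring %in% c("half_lod", "lod", "zero")) {
    abort_soilrisk("`censoring` must be one of half_lod, lod, zero.")
  }
  list(
    seed = cfg$seed %||% 1L,
    backgrounds = cfg$backgrounds,
    censoring = censoring,
    thresholds = thresholds,
    receptors = receptors
  )
}
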