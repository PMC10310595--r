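#' In vitro bioaccessibility percentage
#'
#' Gastric-phase bioaccessibility from an extraction of `soil_mass` grams of
#' soil in `fluid_volume` litres of simulated gastric fluid (the standard
#' vessel is 1 g in 100 mL). The bioaccessible concentration is
#' `extract_conc * fluid_volume / soil_mass` (µg/g, i.e. mg/kg) and IVBA% is
#' that as a percentage of the total concentration. With the standard vessel
#' this reduces to `10 * extract_conc / total_conc`.
#'
#' @param extract_conc Element concentration in the extract, µg/L.
#' @param total_conc Total element concentration of the soil, mg/kg.
#' @param fluid_volume Extraction fluid volume, L.
#' @param soil_mass Extracted soil mass, g.
#' @return IVBA in percent (vectorized). May exceed 100 for heterogeneous
#'   or near-detection samples; downstream RBA resolution caps at 100.
#' @examples
#' ivba_percent(1000, 100)  # 100
#' @export
ivba_percent <- function(extract_conc, total_conc, fluid_volume = 0.1,
                         soil_mass = 1) {
  inputs <- c(extract_conc, total_conc, fluid_volume, soil_mass)
  if (any(!is.finite(inputs)) || any(inputs <= 0)) {
    abort_soilrisk("All ivba_percent inputs must be positive and finite.")
  }
  100 * (extract_conc * fluid_volume / soil_mass) / total_conc
}

#' Arsenic relative bioavailability from IVBA
#'
#' In vivo/in vitro regression for arsenic: `RBA% = 0.79 * IVBA% + 3`,
#' clamped to `[0, 100]`.
#'
#' @param ivba IVBA in percent, `>= 0`.
#' @return RBA in percent.
#' @examples
#' rba_arsenic(23.3)  # 21.407
#' @export
rba_arsenic <- function(ivba) {
  stopifnot(all(ivba >= 0))
  pmin(pmax(0.79 * ivba + 3, 0), 100)
}

#' Lead relative bioavailability from IVBA
#'
#' In vivo/in vitro regression for lead: `RBA% = 0.878 * IVBA% - 2.8`,
#' clamped to `[0, 100]` (the raw value is negative for IVBA below ~3.2%).
#'
#' @param ivba IVBA in percent, `>= 0`.
#' @return RBA in percent.
#' @examples
#' rba_lead(67.5)  # 56.465
#' @export
rba_lead <- function(ivba) {
  stopifnot(all(ivba >= 0))
  pmin(pmax(0.878 * ivba - 2.8, 0), 100)
}

#' Resolve an element's relative bioavailability fraction
#'
#' Applies the element's registry rule: the arsenic or lead regression
#' ([rba_arsenic()], [rba_lead()]), direct use of IVBA% capped at 100, or a
#' fixed RBA of 1. A `direct_ivba` element with no IVBA available falls back
#' to 1 with the flag `"rba_defaulted"`; IVBA above 100 is capped with the
#' flag `"ivba_gt_100"`.
#'
#' @param element Element symbol.
#' @param ivba IVBA in percent, or `NA` when unavailable.
#' @param registry Element registry.
#' @return One-row tibble: `element`, `ivba_pct`, `rba_fraction` (in
#'   `[0, 1]`), `rba_source`, `flags` (comma-separated, `""` if none).
#' @examples
#' resolve_rba("Cu", 58.9)  # 0.589, direct_ivba
#' resolve_rba("Sb", NA)    # 1.0, fixed_one
#' @export
resolve_rba <- function(element, ivba = NA_real_, registry = element_registry()) {
  i <- match(element, registry$element)
  if (is.na(i)) abort_soilrisk(paste0("Unknown element: ", element))
  rule <- registry$rba_rule[i]
  flags <- character(0)
  if (is.finite(ivba) && ivba > 100) flags <- c(flags, "ivba_gt_100")
  rba <- switch(rule,
    regression_as = {
      if (!is.finite(ivba)) { flags <- c(flags, "rba_defaulted"); 1 }
      else rba_arsenic(ivba) / 100
    },
    regression_pb = {
      if (!is.finite(ivba)) { flags <- c(flags, "rba_defaulted"); 1 }
      else rba_lead(ivba) / 100
    },
    direct_ivba = {
      if (!is.finite(ivba)) { flags <- c(flags, "rba_defaulted"); 1 }
      else min(ivba, 100) / 100
    },
    fixed_one = 1
  )
  tibble::tibble(element = element, ivba_pct = ivba, rba_fraction = rba,
                 rba_source = rule, flags = paste(flags, collapse = ","))
}

#' Process a bioaccessibility-extraction table
#'
#' Computes IVBA% and the resolved RBA fraction for every extraction record.
#' Records whose extract concentration is at or below the extract detection
#' limit get no IVBA (flag `"below_extract_lod"`); their RBA falls back per
#' the element rule.
#'
#' @param bioaccess Canonical extraction tibble (see [read_bioaccess()]).
#' @param registry Element registry.
#' @return The input with `ivba_pct`, `rba_fraction`, `rba_source`, `flags`
#'   columns appended.
#' @export
process_bioaccess <- function(bioaccess, registry = element_registry()) {
  purrr::map_dfr(seq_len(nrow(bioaccess)), function(i) {
    r <- bioaccess[i, ]
    below <- is.finite(r$extract_lod) && r$extract_conc <= r$extract_lod
    ivba <- if (below) NA_real_ else {
      ivba_percent(r$extract_conc, r$total_conc, r$fluid_volume, r$soil_mass)
    }
    res <- resolve_rba(r$element, ivba, registry)
    if (below) {
      res$flags <- paste(c("below_extract_lod",
                           setdiff(strsplit(res$flags, ",")[[1]], "")),
                         collapse = ",")
    }
    dplyr::bind_cols(dplyr::select(r, -"element"), dplyr::select(res, -"element"),
                     tibble::tibble(element = r$element)) |>
      dplyr::relocate("element", .after = "sample_id")
  })
}

#' Per-element RBA map from processed bioaccessibility records
#'
#' Aggregates processed records into one RBA fraction per element (mean of
#' per-sample fractions), then fills every registry element that lacks
#' records via [resolve_rba()] with `ivba = NA` (regression/direct elements
#' default to 1 and are flagged; `fixed_one` elements get 1 by rule). The
#' result feeds [assess_dataset()].
#'
#' @param processed Output of [process_bioaccess()], or `NULL` to use the
#'   packaged site-mean IVBA values ([ivba_reference_means()]).
#' @param registry Element registry.
#' @return Tibble: `element`, `ivba_pct`, `rba_fraction`, `rba_source`,
#'   `flags`.
#' @export
rba_map <- function(processed = NULL, registry = element_registry()) {
  if (is.null(processed)) {
    ref <- ivba_reference_means()
    return(purrr::map_dfr(registry$element, function(el) {
      resolve_rba(el, ifelse(el %in% names(ref), ref[[el]], NA_real_), registry)
    }))
  }
  by_el <- processed |>
    dplyr::filter(is.finite(.data$rba_fraction)) |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(ivba_pct = mean(.data$ivba_pct, na.rm = TRUE),
                     rba_fraction = mean(.data$rba_fraction),
                     rba_source = .data$rba_source[1],
                     flags = paste(unique(unlist(strsplit(.data$flags, ","))),
                                   collapse = ","))
  rest <- setdiff(registry$element, by_el$element)
  dplyr::bind_rows(
    by_el,
    purrr::map_dfr(rest, resolve_rba, ivba = NA_real_, registry = registry)
  ) |>
    dplyr::arrange(.data$element)
}
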