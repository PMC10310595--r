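#' Packaged element registry
#'
#' Constants for the 12 metals and metalloids retained for analysis at
#' informal e-waste recycling sites: XRF detection limits, oral tolerable
#' daily intakes, the arsenic cancer slope factor, CCME residential/parkland
#' soil quality guidelines, Dutch Intervention values, and the rule by which
#' each element's relative bioavailability (RBA) is resolved from in vitro
#' bioaccessibility (IVBA).
#'
#' RBA rules:
#' \describe{
#'   \item{`regression_as`}{arsenic in vivo/in vitro regression,
#'     RBA\% = 0.79 IVBA\% + 3.}
#'   \item{`regression_pb`}{lead regression, RBA\% = 0.878 IVBA\% − 2.8.}
#'   \item{`direct_ivba`}{IVBA\% used directly as the RBA surrogate
#'     (Ag, Cr, Cu, Ni, Zn).}
#'   \item{`fixed_one`}{RBA of 1 (Cd, Mo, Sb, Sn — extract concentrations
#'     typically below detection; also Au, which carries no TDI and therefore
#'     never enters the hazard index).}
#' }
#'
#' Background means (`background_mean`, the reference concentration used by
#' the pollution indices) are deliberately `NA`: they are site-specific and
#' must be supplied by the user, e.g. via [set_backgrounds()].
#'
#' @param elements Optional character vector restricting the registry to a
#'   subset of element symbols.
#' @return A tibble with one row per element and columns `element`,
#'   `lod_xrf` (mg/kg), `tdi` (mg/kg/day), `csf` ((mg/kg/day)^-1),
#'   `ccme_residential` (mg/kg), `dutch_intervention` (mg/kg),
#'   `background_mean` (mg/kg), `rba_rule`.
#' @examples
#' element_registry()
#' element_registry(c("As", "Pb"))
#' @export
element_registry <- function(elements = NULL) {
  reg <- tibble::tribble(
    ~element, ~lod_xrf, ~tdi,    ~csf, ~ccme_residential, ~dutch_intervention, ~rba_rule,
    "Ag",     4,        0.005,   NA,   NA,                NA,                  "direct_ivba",
    "As",     4,        0.0003,  1.8,  12,                55,                  "regression_as",
    "Au",     4,        NA,      NA,   NA,                NA,                  "fixed_one",
    "Cd",     6,        0.0005,  NA,   10,                12,                  "fixed_one",
    "Cr",     9,        0.003,   NA,   64,                380,                 "direct_ivba",
    "Cu",     15,       0.01,    NA,   63,                190,                 "direct_ivba",
    "Mo",     3,        0.005,   NA,   NA,                NA,                  "fixed_one",
    "Ni",     17,       0.02,    NA,   45,                210,                 "direct_ivba",
    "Pb",     4,        0.0036,  NA,   140,               210,                 "regression_pb",
    "Sb",     7,        0.0005,  NA,   20,                15,                  "fixed_one",
    "Sn",     5,        0.6,     NA,   50,                NA,                  "fixed_one",
    "Zn",     12,       0.3,     NA,   250,               720,                 "direct_ivba"
  )
  reg$background_mean <- NA_real_
  reg <- reg[, c("element", "lod_xrf", "tdi", "csf", "ccme_residential",
                 "dutch_intervention", "background_mean", "rba_rule")]
  if (!is.null(elements)) {
    missing <- setdiff(elements, reg$element)
    if (length(missing) > 0) {
      abort_soilrisk(paste0("Unknown element(s): ", paste(missing, collapse = ", ")))
    }
    reg <- reg[match(elements, reg$element), ]
  }
  reg
}

#' Elements contributing to the hazard index
#'
#' The hazard index sums hazard quotients over these 11 elements; Au is
#' analysed for concentration structure but has no tolerable daily intake.
#' @return Character vector of element symbols.
#' @export
hi_elements <- function() {
  c("Ag", "As", "Cd", "Cr", "Cu", "Mo", "Ni", "Pb", "Sb", "Sn", "Zn")
}

#' Attach site-specific background means to a registry
#'
#' @param registry Registry tibble from [element_registry()].
#' @param backgrounds Named numeric vector or list, element symbol ->
#'   background mean concentration (mg/kg). Values must be positive.
#' @return The registry with `background_mean` filled in for the named
#'   elements.
#' @examples
#' reg <- set_backgrounds(element_registry(), c(Pb = 25, Zn = 80))
#' @export
set_backgrounds <- function(registry, backgrounds) {
  backgrounds <- unlist(backgrounds)
  if (is.null(names(backgrounds)) || any(names(backgrounds) == "")) {
    abort_soilrisk("`backgrounds` must be a named vector (element -> mg/kg).")
  }
  if (any(!is.finite(backgrounds)) || any(backgrounds <= 0)) {
    abort_soilrisk("Background means must be positive and finite.")
  }
  unknown <- setdiff(names(backgrounds), registry$element)
  if (length(unknown) > 0) {
    abort_soilrisk(paste0("Unknown element(s) in backgrounds: ",
                          paste(unknown, collapse = ", ")))
  }
  idx <- match(names(backgrounds), registry$element)
  registry$background_mean[idx] <- unname(backgrounds)
  registry
}

#' Receptor exposure profile
#'
#' Bundles the parameters of the oral soil-ingestion exposure model: soil
#' ingestion rate, body weight, exposure frequency (days/week, weeks/year),
#' exposure duration and life expectancy. The exposure term used in intake
#' calculations is the dimensionless fraction
#' `(days_per_week / 7) * (weeks_per_year / 52)`; for carcinogens the intake
#' is additionally multiplied by `exposure_duration / life_expectancy`.
#'
#' @param name Receptor label, e.g. `"child"`.
#' @param ing_rate Soil ingestion rate, kg soil/day.
#' @param body_weight Body weight, kg.
#' @param days_per_week,weeks_per_year Exposure frequency; defaults give a
#'   continuous residential exposure term of 1.
#' @param exposure_duration Years of exposure; defaults to `life_expectancy`
#'   so the carcinogen year-fraction is 1.
#' @param life_expectancy Years; used for carcinogens only.
#' @return A one-row tibble of class `receptor_profile`.
#' @examples
#' receptor_profile("child", ing_rate = 4e-4, body_weight = 30)
#' @export
receptor_profile <- function(name, ing_rate, body_weight,
                             days_per_week = 7, weeks_per_year = 52,
                             exposure_duration = life_expectancy,
                             life_expectancy = 64) {
  stopifnot(is.character(name), length(name) == 1)
  if (ing_rate <= 0) abort_soilrisk("`ing_rate` must be > 0.")
  if (body_weight <= 0) abort_soilrisk("`body_weight` must be > 0.")
  if (days_per_week <= 0 || days_per_week > 7) {
    abort_soilrisk("`days_per_week` must be in (0, 7].")
  }
  if (weeks_per_year <= 0 || weeks_per_year > 52) {
    abort_soilrisk("`weeks_per_year` must be in (0, 52].")
  }
  if (exposure_duration <= 0 || exposure_duration > life_expectancy) {
    abort_soilrisk("`exposure_duration` must be in (0, life_expectancy].")
  }
  out <- tibble::tibble(
    receptor = name,
    ing_rate = ing_rate,
    body_weight = body_weight,
    days_per_week = days_per_week,
    weeks_per_year = weeks_per_year,
    exposure_duration = exposure_duration,
    life_expectancy = life_expectancy,
    et_fraction = (days_per_week / 7) * (weeks_per_year / 52),
    carcinogen_years_fraction = exposure_duration / life_expectancy
  )
  class(out) <- c("receptor_profile", class(out))
  out
}

#' Default child and adult receptors
#'
#' Child: 0.0004 kg soil/day, 30 kg body weight. Adult: 0.0001 kg soil/day,
#' 70 kg. Both assume continuous residential exposure (exposure-term fraction
#' 1) and a 64-year life expectancy with exposure duration equal to it.
#'
#' @return A two-row receptor tibble (child, adult).
#' @export
default_receptors <- function() {
  dplyr::bind_rows(
    receptor_profile("child", ing_rate = 0.0004, body_weight = 30),
    receptor_profile("adult", ing_rate = 0.0001, body_weight = 70)
  )
}

#' Site-mean in vitro bioaccessibility reference values
#'
#' Per-element arithmetic mean IVBA (%) measured on gastric-phase extractions
#' of e-waste site soils; used as the group-level fallback when per-sample
#' bioaccessibility is unavailable. Elements under the `fixed_one` RBA rule
#' are absent (their extracts were below detection).
#'
#' @return Named numeric vector, element -> mean IVBA (%).
#' @export
ivba_reference_means <- function() {
  c(Ag = 65.8, As = 23.3, Cr = 8.8, Cu = 58.9, Pb = 67.5, Ni = 38.3, Zn = 58.4)
}
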