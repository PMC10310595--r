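#' Chemical daily intake from incidental soil ingestion
#'
#' `CDI = Msoil * IngR * ET / BW`, in mg per kg body weight per day, where
#' `ET` is the dimensionless exposure-term fraction
#' `(days_per_week / 7) * (weeks_per_year / 52)`. For carcinogens the intake
#' is amortized over the lifetime by the additional factor
#' `exposure_duration / life_expectancy`.
#'
#' @param msoil Soil concentration, mg/kg (`>= 0`; censored values must be
#'   resolved upstream).
#' @param receptor One-row receptor tibble ([receptor_profile()]).
#' @param carcinogenic Apply the lifetime amortization factor?
#' @return CDI in mg/kg/day (vectorized over `msoil`).
#' @examples
#' child <- receptor_profile("child", 0.0004, 30)
#' chemical_daily_intake(6534, child)  # 0.08712
#' @export
chemical_daily_intake <- function(msoil, receptor, carcinogenic = FALSE) {
  stopifnot(all(msoil >= 0))
  if (receptor$body_weight <= 0) abort_soilrisk("`body_weight` must be > 0.")
  cdi <- msoil * receptor$ing_rate * receptor$et_fraction / receptor$body_weight
  if (carcinogenic) cdi <- cdi * receptor$carcinogen_years_fraction
  cdi
}

#' Hazard quotient
#'
#' `HQ = CDI * RBA / TDI`: the bioavailability-adjusted intake as a fraction
#' of the tolerable daily intake.
#'
#' @param cdi Chemical daily intake, mg/kg/day.
#' @param rba Relative bioavailability fraction in `[0, 1]`.
#' @param tdi Tolerable daily intake, mg/kg/day, `> 0`.
#' @return Dimensionless hazard quotient (vectorized).
#' @examples
#' hazard_quotient(0.08712, 0.56465, 0.0036)  # ~13.66
#' @export
hazard_quotient <- function(cdi, rba, tdi) {
  if (any(!is.finite(tdi)) || any(tdi <= 0)) {
    abort_soilrisk("`tdi` must be positive; elements without a TDI are skipped upstream.")
  }
  if (any(rba < 0 | rba > 1)) abort_soilrisk("`rba` must be in [0, 1].")
  cdi * rba / tdi
}

#' Hazard index
#'
#' Sum of hazard quotients over the elements present. `HI > 1` flags an
#' elevated probability of non-carcinogenic effects.
#'
#' @param hqs Named numeric vector of hazard quotients (element -> HQ).
#' @return List with `hi` (the sum) and `elements` (contributors).
#' @export
hazard_index <- function(hqs) {
  hqs <- hqs[is.finite(hqs)]
  if (length(hqs) == 0) abort_soilrisk("No hazard quotients supplied.")
  list(hi = sum(hqs), elements = names(hqs))
}

#' Carcinogenic risk
#'
#' `CR = CDI * CSF * RBA`: incremental lifetime cancer probability from the
#' lifetime-amortized intake and the oral cancer slope factor.
#'
#' @param cdi Carcinogenic chemical daily intake, mg/kg/day (computed with
#'   `carcinogenic = TRUE`).
#' @param csf Cancer slope factor, (mg/kg/day)^-1, `> 0`.
#' @param rba Relative bioavailability fraction.
#' @return Dimensionless risk (vectorized).
#' @export
cancer_risk <- function(cdi, csf, rba) {
  if (any(!is.finite(csf)) || any(csf <= 0)) {
    abort_soilrisk("`csf` must be positive; only carcinogens carry a slope factor.")
  }
  cdi * csf * rba
}

#' Full oral-ingestion risk assessment of a sample table
#'
#' For every sample x receptor: per-element CDIs and hazard quotients, the
#' hazard index over the elements with a TDI, and (for receptors named in
#' `cr_receptors`) the arsenic cancer risk, with threshold flags. Censored
#' concentrations enter through a stated substitution convention (default
#' LOD/2); elements lacking a TDI are skipped and listed in
#' `skipped_elements` rather than silently contributing zero.
#'
#' @param samples Long sample tibble (see [read_samples()]).
#' @param rba Per-element RBA tibble from [rba_map()] (columns `element`,
#'   `rba_fraction`).
#' @param receptors Receptor tibble; default [default_receptors()].
#' @param registry Element registry.
#' @param censoring `"half_lod"` (default), `"lod"` or `"zero"`.
#' @param hi_limit Hazard-index threshold (default 1).
#' @param cr_limit Cancer-risk acceptability threshold (default 1e-5, one
#'   excess cancer per 100,000 exposed).
#' @param cr_receptors Receptors for which the arsenic cancer risk is
#'   computed; default `"adult"`.
#' @return Tibble, one row per sample x receptor: `sample_id`, `site_group`,
#'   `receptor`, `hq_<element>` columns, `hi`, `hi_elements`,
#'   `skipped_elements`, `cr_as`, `hi_exceeds`, `cr_exceeds`. Attribute
#'   `"conventions"` records the censoring convention and thresholds.
#' @export
assess_dataset <- function(samples, rba, receptors = default_receptors(),
                           registry = element_registry(),
                           censoring = c("half_lod", "lod", "zero"),
                           hi_limit = 1, cr_limit = 1e-5,
                           cr_receptors = "adult") {
  censoring <- match.arg(censoring)
  if (nrow(receptors) == 0) abort_soilrisk("At least one receptor is required.")
  d <- samples |>
    dplyr::mutate(msoil = resolve_censored(.data$conc, .data$censored,
                                           .data$lod, censoring)) |>
    dplyr::inner_join(dplyr::select(registry, "element", "tdi", "csf"),
                      by = "element") |>
    dplyr::left_join(dplyr::select(rba, "element", "rba_fraction"), by = "element")
  if (any(is.na(d$rba_fraction))) {
    abort_soilrisk("RBA map does not cover every element in the dataset.")
  }

  out <- purrr::map_dfr(seq_len(nrow(receptors)), function(r) {
    rec <- receptors[r, ]
    d |>
      dplyr::group_by(.data$sample_id, .data$site_group) |>
      dplyr::group_modify(function(g, key) {
        has_tdi <- is.finite(g$tdi)
        hq <- rep(NA_real_, nrow(g))
        hq[has_tdi] <- hazard_quotient(
          chemical_daily_intake(g$msoil[has_tdi], rec),
          g$rba_fraction[has_tdi], g$tdi[has_tdi])
        hi_res <- hazard_index(setNames(hq[has_tdi], g$element[has_tdi]))
        cr <- NA_real_
        if (rec$receptor %in% cr_receptors && "As" %in% g$element) {
          i <- match("As", g$element)
          if (is.finite(g$csf[i])) {
            cr <- cancer_risk(
              chemical_daily_intake(g$msoil[i], rec, carcinogenic = TRUE),
              g$csf[i], g$rba_fraction[i])
          }
        }
        hq_row <- tibble::as_tibble(setNames(as.list(hq), paste0("hq_", g$element)))
        dplyr::bind_cols(
          tibble::tibble(receptor = rec$receptor),
          hq_row,
          tibble::tibble(
            hi = hi_res$hi,
            hi_elements = paste(hi_res$elements, collapse = ","),
            skipped_elements = paste(g$element[!has_tdi], collapse = ","),
            cr_as = cr,
            hi_exceeds = hi_res$hi > hi_limit,
            cr_exceeds = ifelse(is.na(cr), NA, cr > cr_limit)
          )
        )
      }) |>
      dplyr::ungroup()
  })
  attr(out, "conventions") <- list(censoring = censoring, hi_limit = hi_limit,
                                   cr_limit = cr_limit, et = "fraction")
  class(out) <- c("soilrisk_assessment", class(out))
  out
}

#' @export
print.soilrisk_assessment <- function(x, ...) {
  conv <- attr(x, "conventions")
  cat(sprintf(
    "Oral-ingestion risk assessment: %d sample x receptor rows\n", nrow(x)))
  cat(sprintf("  censoring: %s; HI limit %g; CR limit %g\n",
              conv$censoring, conv$hi_limit, conv$cr_limit))
  NextMethod()
}

#' @rdname assess_dataset
#' @param x A `soilrisk_assessment` object.
#' @param ... Unused.
#' @return `glance()`: one row per receptor with sample counts and
#'   exceedance counts.
#' @export
glance.soilrisk_assessment <- function(x, ...) {
  x |>
    dplyr::group_by(.data$receptor) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_hi_exceed = sum(.data$hi_exceeds),
      n_cr_exceed = sum(.data$cr_exceeds, na.rm = TRUE),
      max_hi = max(.data$hi),
      max_cr = ifelse(all(is.na(.data$cr_as)), NA_real_,
                      max(.data$cr_as, na.rm = TRUE))
    )
}

#' @rdname assess_dataset
#' @return `tidy()`: long tibble with one row per sample x receptor x
#'   element hazard quotient.
#' @export
tidy.soilrisk_assessment <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(dplyr::starts_with("hq_"), names_to = "element",
                        names_prefix = "hq_", values_to = "hq") |>
    dplyr::select("sample_id", "site_group", "receptor", "element", "hq",
                  "hi", "cr_as")
}
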