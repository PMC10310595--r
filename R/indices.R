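#' Enrichment factor
#'
#' Fe-normalized ratio of a sample's metal concentration to the local
#' background: `EF = (Ms * Fe_b) / (Mb * Fe_s)`, where `Ms`/`Fe_s` are the
#' metal and iron concentrations in the sample and `Mb`/`Fe_b` the
#' corresponding background means. Values near 1 indicate crustal levels;
#' large values indicate anthropogenic input. The ratio is invariant to any
#' common rescaling of the four inputs (mg/kg vs ppm).
#'
#' @param ms Metal concentration in the sample, mg/kg.
#' @param fes Iron concentration in the sample, mg/kg.
#' @param mb Background mean of the metal, mg/kg.
#' @param feb Background mean of iron, mg/kg.
#' @return Dimensionless enrichment factor (vectorized).
#' @examples
#' enrichment_factor(ms = 100, fes = 20000, mb = 10, feb = 20000)  # 10
#' @export
enrichment_factor <- function(ms, fes, mb, feb) {
  if (any(!is.finite(c(ms, fes, mb, feb))) || any(c(ms, fes, mb, feb) <= 0)) {
    abort_soilrisk("All enrichment-factor inputs must be positive and finite.")
  }
  (ms * feb) / (mb * fes)
}

#' Geoaccumulation index
#'
#' `Igeo = log2(Ms / (1.5 * Mb))`; the factor 1.5 absorbs natural variability
#' of the background. A sample at background therefore scores
#' `log2(1/1.5) < 0` ("unpolluted").
#'
#' @param ms Sample concentration, mg/kg.
#' @param mb Background mean, mg/kg.
#' @return Dimensionless index (vectorized).
#' @examples
#' geoaccumulation(12, 1)  # log2(8) = 3
#' @export
geoaccumulation <- function(ms, mb) {
  if (any(!is.finite(c(ms, mb))) || any(c(ms, mb) <= 0)) {
    abort_soilrisk("`ms` and `mb` must be positive and finite.")
  }
  log2(ms / (1.5 * mb))
}

EF_BREAKS <- c(-Inf, 2, 5, 20, 40, Inf)
EF_LABELS <- c("deficiency to minimal enrichment", "moderate enrichment",
               "significant enrichment", "very high enrichment",
               "extremely high enrichment")
IGEO_BREAKS <- c(-Inf, 0, 1, 2, 3, 4, 5, Inf)
IGEO_LABELS <- c("unpolluted", "unpolluted to moderately polluted",
                 "moderately polluted", "moderately to highly polluted",
                 "highly polluted", "highly to extremely high polluted",
                 "extremely high polluted")

#' Descriptive class for an enrichment factor or geoaccumulation index
#'
#' EF bins: `<2` deficiency to minimal, `2-5` moderate, `5-20` significant,
#' `20-40` very high, `>40` extremely high enrichment. Igeo bins: `<=0`
#' unpolluted through `5-6` extremely high polluted. Boundary values belong
#' to the lower bin (intervals closed on the right). Igeo above 6 keeps the
#' top label; use [classify_index_tbl()] to also see the out-of-scale flag.
#'
#' @param value Numeric vector of index values.
#' @param scheme `"ef"` or `"igeo"`.
#' @return Character vector of class labels.
#' @examples
#' classify_index(1, "ef")    # deficiency to minimal enrichment
#' classify_index(0, "igeo")  # unpolluted
#' @export
classify_index <- function(value, scheme = c("ef", "igeo")) {
  scheme <- match.arg(scheme)
  if (scheme == "ef") {
    as.character(cut(value, EF_BREAKS, EF_LABELS, right = TRUE))
  } else {
    as.character(cut(value, IGEO_BREAKS, IGEO_LABELS, right = TRUE))
  }
}

#' @rdname classify_index
#' @return `classify_index_tbl()`: tibble with `value`, `class`,
#'   `out_of_scale` (`TRUE` for Igeo > 6, beyond the published bins).
#' @export
classify_index_tbl <- function(value, scheme = c("ef", "igeo")) {
  scheme <- match.arg(scheme)
  tibble::tibble(
    value = value,
    class = classify_index(value, scheme),
    out_of_scale = if (scheme == "igeo") value > 6 else FALSE
  )
}

#' Per-sample or per-group pollution indices
#'
#' Computes EF and Igeo with their descriptive classes for every element with
#' a background mean in the registry. `by = "sample"` uses each sample's own
#' concentrations (censored cells resolved by `censoring`); `by = "group"`
#' first takes Kaplan-Meier means per element and site group via
#' [summarize_elements()] and indexes those, matching the usual "mean EF /
#' mean Igeo per area" presentation.
#'
#' The enrichment factor needs iron: supply the sample table with an `"Fe"`
#' element and `fe_background` (mg/kg). Without iron, EF columns are `NA` and
#' only Igeo is computed.
#'
#' @param samples Long sample tibble.
#' @param registry Registry with `background_mean` filled for the elements of
#'   interest (see [set_backgrounds()]).
#' @param by `"sample"` or `"group"`.
#' @param fe_background Background mean iron concentration, mg/kg.
#' @param censoring How censored cells enter per-sample indices:
#'   `"half_lod"`, `"lod"` or `"zero"` (zero-substituted cells get `NA`
#'   indices since the logs are undefined).
#' @return Tibble with `element`, id columns (`sample_id` or `site_group`),
#'   `ms`, `ef`, `ef_class`, `igeo`, `igeo_class`.
#' @export
pollution_indices <- function(samples, registry, by = c("sample", "group"),
                              fe_background = NULL,
                              censoring = c("half_lod", "lod", "zero")) {
  by <- match.arg(by)
  censoring <- match.arg(censoring)
  reg <- dplyr::filter(registry, is.finite(.data$background_mean))
  if (nrow(reg) == 0) {
    abort_soilrisk("No background means in registry; call set_backgrounds() first.")
  }
  has_fe <- "Fe" %in% samples$element && !is.null(fe_background)

  if (by == "sample") {
    d <- samples |>
      dplyr::mutate(ms = resolve_censored(.data$conc, .data$censored, .data$lod,
                                          censoring))
    fe <- d |>
      dplyr::filter(.data$element == "Fe") |>
      dplyr::select("sample_id", fes = "ms")
    d <- d |>
      dplyr::inner_join(dplyr::select(reg, "element", mb = "background_mean"),
                        by = "element")
    if (has_fe) d <- dplyr::left_join(d, fe, by = "sample_id")
    id_cols <- c("sample_id", "site_group")
  } else {
    d <- summarize_elements(samples) |>
      dplyr::select("element", "site_group", ms = "mean")
    fe <- d |>
      dplyr::filter(.data$element == "Fe") |>
      dplyr::select("site_group", fes = "ms")
    d <- dplyr::inner_join(d, dplyr::select(reg, "element", mb = "background_mean"),
                           by = "element")
    if (has_fe) d <- dplyr::left_join(d, fe, by = "site_group")
    id_cols <- "site_group"
  }
  if (!has_fe) d$fes <- NA_real_
  feb <- fe_background %||% NA_real_
  d |>
    dplyr::mutate(
      ef = ifelse(is.finite(.data$fes) & .data$ms > 0,
                  (.data$ms * feb) / (.data$mb * .data$fes),
                  NA_real_),
      ef_class = ifelse(is.na(.data$ef), NA_character_,
                        classify_index(.data$ef, "ef")),
      igeo = ifelse(.data$ms > 0, log2(.data$ms / (1.5 * .data$mb)), NA_real_),
      igeo_class = ifelse(is.na(.data$igeo), NA_character_,
                          classify_index(.data$igeo, "igeo"))
    ) |>
    dplyr::select(dplyr::all_of(c("element", id_cols)),
                  "ms", "ef", "ef_class", "igeo", "igeo_class")
}

#' Guideline exceedance screen
#'
#' Compares Kaplan-Meier mean concentrations per element and site group
#' against the packaged soil quality guidelines (CCME residential/parkland
#' and Dutch Intervention values). Exceedance is strict: a mean exactly at
#' the guideline does not exceed.
#'
#' @param summaries Output of [summarize_elements()] (needs `element`,
#'   `site_group`, `mean`).
#' @param registry Element registry carrying the guideline columns.
#' @return Long tibble: `element`, `site_group`, `mean`, `guideline_name`,
#'   `guideline_value`, `ratio`, `exceeds`. Elements with no guideline value
#'   are omitted.
#' @export
guideline_screen <- function(summaries, registry) {
  guides <- registry |>
    dplyr::select("element", ccme_residential = "ccme_residential",
                  dutch_intervention = "dutch_intervention") |>
    tidyr::pivot_longer(-"element", names_to = "guideline_name",
                        values_to = "guideline_value") |>
    dplyr::filter(is.finite(.data$guideline_value))
  summaries |>
    dplyr::select("element", "site_group", "mean") |>
    dplyr::inner_join(guides, by = "element",
                      relationship = "many-to-many") |>
    dplyr::mutate(ratio = .data$mean / .data$guideline_value,
                  exceeds = .data$ratio > 1) |>
    dplyr::arrange(.data$element, .data$site_group, .data$guideline_name)
}

# Substitute a value for censored cells when a point value is required
# (risk mode, per-sample indices). Convention exposed to the user; KM-based
# summaries never use this.
resolve_censored <- function(conc, censored, lod,
                             convention = c("half_lod", "lod", "zero")) {
  convention <- match.arg(convention)
  sub <- switch(convention, half_lod = lod / 2, lod = lod, zero = 0)
  ifelse(censored, sub, conc)
}
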