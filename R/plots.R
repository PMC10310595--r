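#' Bar chart of mean pollution indices by site group
#'
#' @param indices Output of [pollution_indices()] with `by = "group"`.
#' @param which `"igeo"` or `"ef"`.
#' @return A ggplot object.
#' @export
plot_indices <- function(indices, which = c("igeo", "ef")) {
  which <- match.arg(which)
  ylab <- if (which == "igeo") "Geoaccumulation index" else "Enrichment factor"
  ggplot2::ggplot(indices,
                  ggplot2::aes(x = .data$element, y = .data[[which]],
                               fill = .data$site_group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = ylab, fill = "Site group") +
    ggplot2::theme_minimal()
}

#' Hazard-index plot for a risk assessment
#'
#' One point per sample, faceted by receptor, log-scale y, with the
#' threshold drawn as a horizontal line; points above it carry unacceptable
#' non-carcinogenic risk.
#'
#' @param object A `soilrisk_assessment` from [assess_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.soilrisk_assessment <- function(object, ...) {
  conv <- attr(object, "conventions")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$site_group, y = .data$hi,
                               colour = .data$site_group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = conv$hi_limit, colour = "red",
                        linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~receptor) +
    ggplot2::labs(x = NULL, y = "Hazard index", colour = "Site group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Arsenic cancer-risk plot
#'
#' @param assessment A `soilrisk_assessment` with cancer risk computed.
#' @param cr_limit Acceptability threshold line.
#' @return A ggplot object.
#' @export
plot_cancer_risk <- function(assessment, cr_limit = 1e-5) {
  d <- dplyr::filter(tibble::as_tibble(assessment), !is.na(.data$cr_as))
  if (nrow(d) == 0) abort_soilrisk("No cancer-risk values in this assessment.")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site_group, y = .data$cr_as,
                                  colour = .data$site_group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = cr_limit, colour = "red", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Arsenic cancer risk", colour = "Site group") +
    ggplot2::theme_minimal()
}
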