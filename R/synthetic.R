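#' Configuration for the synthetic e-waste-site generator
#'
#' Defines a multi-element lognormal concentration field with two
#' anthropogenic point sources (a burning area and a dismantling area) and a
#' natural background. Each sample's log-concentration is
#' `log(gm_e) + sum_s log(loading_{s,e}) * exp(-d_s / decay_length) + eps`,
#' with `eps ~ N(0, log(gsd_e))` and `d_s` the distance to source `s`.
#' Burning and dismantling samples sit at their hotspots (full loading),
#' community samples on a grid around the sources (partial, spatially
#' decaying loading), background samples far away (no loading). Values below
#' the element's detection limit are emitted as left-censored.
#'
#' Defaults mirror the field design the package targets: group sizes
#' `burning 14, dismantling 11, community 64, background 12`, XRF detection
#' limits, burning-source loadings on Cu/Pb/Sb/Sn/Zn (plus As and Cd),
#' dismantling-source loadings on Ag/Au/Mo, and gastric IVBA distributions
#' per element. All parameters are overridable.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_per_group Named integer vector of group sizes.
#' @param background_gm,background_gsd Named per-element geometric mean
#'   (mg/kg) and geometric SD (`> 1`) of the background field.
#' @param burning_loadings,dismantling_loadings Named multiplicative factors
#'   (`>= 1`) applied at the respective hotspot; elements absent default to 1.
#' @param hotspots List with numeric `burning` and `dismantling` `(x, y)`
#'   coordinates in meters.
#' @param decay_length Exponential decay length of source influence, m.
#' @param lods Named detection limits (mg/kg); values `<= 0` disable
#'   censoring for that element.
#' @param ivba_params Named list, element -> `c(mean, sd)` of the truncated
#'   normal IVBA% distribution used by [generate_bioaccess()].
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_per_group = c(community = 64, burning = 14, dismantling = 11,
                    background = 12),
    background_gm = c(Ag = 2, As = 3, Au = 2, Cd = 3, Cr = 40, Cu = 30,
                      Mo = 2, Ni = 15, Pb = 25, Sb = 2, Sn = 4, Zn = 80),
    background_gsd = stats::setNames(rep(2.5, 12), names(background_gm)),
    burning_loadings = c(As = 50, Cd = 15, Cu = 500, Pb = 250, Sb = 250,
                         Sn = 200, Zn = 200),
    dismantling_loadings = c(Ag = 20, Au = 15, Mo = 10, Cr = 8),
    hotspots = list(burning = c(0, 0), dismantling = c(400, 0)),
    decay_length = 150,
    lods = c(Ag = 4, As = 4, Au = 4, Cd = 6, Cr = 9, Cu = 15, Mo = 3,
             Ni = 17, Pb = 4, Sb = 7, Sn = 5, Zn = 12),
    ivba_params = list(Ag = c(65.8, 29.7), As = c(23.3, 9.7), Cr = c(8.8, 4.8),
                       Cu = c(58.9, 12.2), Pb = c(67.5, 12.0),
                       Ni = c(38.3, 6.0), Zn = c(58.4, 20.2))) {
  elements <- names(background_gm)
  stopifnot(length(elements) > 0, !is.null(names(n_per_group)))
  if (!all(names(n_per_group) %in% SITE_GROUPS)) {
    abort_soilrisk("n_per_group names must be site groups.")
  }
  if (any(n_per_group < 1)) abort_soilrisk("n_per_group must be >= 1.")
  if (any(background_gm <= 0)) abort_soilrisk("background_gm must be > 0.")
  if (!setequal(names(background_gsd), elements) || any(background_gsd <= 1)) {
    abort_soilrisk("background_gsd must cover all elements and be > 1.")
  }
  for (nm in c("burning_loadings", "dismantling_loadings")) {
    ld <- get(nm)
    if (length(ld) > 0) {
      if (!all(names(ld) %in% elements)) {
        abort_soilrisk(paste0(nm, " names element(s) missing from background_gm."))
      }
      if (any(ld < 1)) abort_soilrisk(paste0(nm, " must be >= 1."))
    }
  }
  if (decay_length <= 0) abort_soilrisk("decay_length must be > 0.")
  full <- function(v) {
    out <- stats::setNames(rep(1, length(elements)), elements)
    out[names(v)] <- v
    out
  }
  lods_full <- stats::setNames(rep(0, length(elements)), elements)
  lods_full[names(lods)[names(lods) %in% elements]] <-
    lods[names(lods) %in% elements]
  structure(list(
    seed = as.integer(seed),
    n_per_group = n_per_group,
    elements = elements,
    background_gm = background_gm,
    background_gsd = background_gsd,
    loadings = list(burning = full(burning_loadings),
                    dismantling = full(dismantling_loadings)),
    hotspots = hotspots,
    decay_length = decay_length,
    lods = lods_full,
    ivba_params = ivba_params
  ), class = "synthetic_config")
}

# Fixed distance profiles per group: source members at their hotspot,
# community on a regular grid around both sources, background effectively
# at infinite distance.
synthetic_coords <- function(config) {
  n <- config$n_per_group
  place <- function(group, n_g) {
    if (n_g == 0) return(NULL)
    xy <- switch(group,
      burning = matrix(rep(config$hotspots$burning, n_g), ncol = 2, byrow = TRUE),
      dismantling = matrix(rep(config$hotspots$dismantling, n_g), ncol = 2,
                           byrow = TRUE),
      community = {
        side <- ceiling(sqrt(n_g))
        gx <- seq(-600, 1000, length.out = side)
        gy <- seq(-800, 800, length.out = side)
        grid <- expand.grid(x = gx, y = gy)
        as.matrix(grid[seq_len(n_g), ])
      },
      background = matrix(rep(c(2e4, 2e4), n_g), ncol = 2, byrow = TRUE)
    )
    tibble::tibble(site_group = group, x = unname(xy[, 1]), y = unname(xy[, 2]))
  }
  out <- purrr::map_dfr(names(n), ~ place(.x, n[[.x]]))
  out$sample_id <- sprintf("SYN%03d", seq_len(nrow(out)))
  out
}

#' Generate a synthetic soil-sample dataset with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `samples` (long sample tibble in the layout of
#'   [read_samples()], censored below the configured LODs) and `truth` (a
#'   tibble of every latent uncensored concentration plus the per-sample,
#'   per-source decay weights; attribute `"config"` carries the full
#'   configuration).
#' @export
generate_soil <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  coords <- synthetic_coords(config)
  n <- nrow(coords)
  els <- config$elements

  dist_to <- function(h) sqrt((coords$x - h[1])^2 + (coords$y - h[2])^2)
  w_burn <- exp(-dist_to(config$hotspots$burning) / config$decay_length)
  w_dism <- exp(-dist_to(config$hotspots$dismantling) / config$decay_length)

  truth <- purrr::map_dfr(els, function(el) {
    mu <- log(config$background_gm[[el]]) +
      log(config$loadings$burning[[el]]) * w_burn +
      log(config$loadings$dismantling[[el]]) * w_dism
    latent <- exp(mu + rnorm(n, 0, log(config$background_gsd[[el]])))
    tibble::tibble(
      sample_id = coords$sample_id, site_group = coords$site_group,
      x = coords$x, y = coords$y, element = el,
      latent = latent, w_burning = w_burn, w_dismantling = w_dism,
      lod = config$lods[[el]]
    )
  })
  samples <- truth |>
    dplyr::mutate(
      censored = .data$lod > 0 & .data$latent < .data$lod,
      conc = ifelse(.data$censored, NA_real_, .data$latent),
      lod = ifelse(.data$lod > 0, .data$lod, NA_real_)
    ) |>
    dplyr::select("sample_id", "site_group", "x", "y", "element",
                  "conc", "censored", "lod")
  attr(truth, "config") <- config
  list(samples = samples, truth = truth)
}

#' Generate synthetic bioaccessibility extractions for a sample set
#'
#' Draws per-sample IVBA% from the configured truncated-at-zero normal for
#' each element with `ivba_params`, then back-computes the extract
#' concentration for the standard 1 g / 100 mL vessel so that
#' [ivba_percent()] recovers the drawn value exactly:
#' `extract_conc (µg/L) = ivba_pct * total_conc / 10`. Only uncensored
#' totals yield records.
#'
#' @param config A [synthetic_config()].
#' @param samples Long sample tibble from [generate_soil()].
#' @return Canonical extraction tibble (see [read_bioaccess()]) with the
#'   drawn `ivba_true` attached.
#' @export
generate_bioaccess <- function(config, samples) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  els <- names(config$ivba_params)
  d <- samples |>
    dplyr::filter(.data$element %in% els, !.data$censored)
  if (nrow(d) == 0) return(tibble::tibble())
  draw <- function(el, k) {
    p <- config$ivba_params[[el]]
    if (p[2] == 0) return(rep(p[1], k))
    # inverse-CDF draw from N(mean, sd) truncated at 0
    lo <- stats::pnorm(0, p[1], p[2])
    stats::qnorm(runif(k, lo, 1), p[1], p[2])
  }
  d |>
    dplyr::group_by(.data$element) |>
    dplyr::group_modify(function(g, key) {
      iv <- draw(key$element, nrow(g))
      tibble::tibble(
        sample_id = g$sample_id,
        extract_conc = iv * g$conc / 10,
        soil_mass = 1,
        fluid_volume = 0.1,
        total_conc = g$conc,
        extract_lod = NA_real_,
        ivba_true = iv
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("sample_id") |>
    dplyr::arrange(.data$sample_id, .data$element)
}
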