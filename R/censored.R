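#' Kaplan-Meier summary statistics for left-censored concentrations
#'
#' Left-censored data ("<LOD" nondetects) are flipped about a constant
#' `M > max(x)` so that a value known only to be *below* its bound becomes a
#' right-censored survival time, the product-limit estimator is fitted to the
#' flipped data, and the mean, SD and quantiles are read off the estimated
#' distribution and flipped back. With no censoring the results equal the
#' ordinary arithmetic statistics (mean, sample SD, type-1 quantiles)
#' exactly, and the estimates do not depend on the choice of `M`.
#'
#' When the smallest value in the data is censored, the product-limit curve
#' does not reach zero; the leftover probability mass is assigned to that
#' smallest reporting bound (the restricted-mean convention used in nondetect
#' practice) and `mass_carried` is set.
#'
#' @param x Numeric vector: observed concentrations for uncensored entries,
#'   reporting bounds (LODs) for censored entries. mg/kg.
#' @param censored Logical vector, `TRUE` where `x` is a bound.
#' @param flip_constant Flip point `M`; default `max(x) + 1`. Any constant
#'   greater than `max(x)` gives identical results.
#' @return One-row tibble: `n`, `n_censored`, `pct_censored`, `mean`, `sd`,
#'   `median`, `p95`, `maximum`, `flip_constant`, `mass_carried`,
#'   `all_censored`. When every value is censored the location statistics are
#'   upper bounds at the smallest LOD and `all_censored` is `TRUE`.
#' @examples
#' km_summary(c(1, 2, 3), c(TRUE, FALSE, FALSE))  # mean 2.0
#' @export
km_summary <- function(x, censored = rep(FALSE, length(x)), flip_constant = NULL) {
  stopifnot(length(x) >= 1, length(x) == length(censored))
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort_soilrisk("Concentrations and bounds must be positive and finite.")
  }
  censored <- as.logical(censored)
  n <- length(x)
  pct_cens <- 100 * mean(censored)

  if (all(censored)) {
    return(tibble::tibble(
      n = n, n_censored = n, pct_censored = 100,
      mean = min(x), sd = NA_real_, median = min(x), p95 = min(x),
      maximum = max(x), flip_constant = NA_real_,
      mass_carried = TRUE, all_censored = TRUE
    ))
  }

  M <- flip_constant %||% (max(x) + 1)
  if (M <= max(x)) abort_soilrisk("`flip_constant` must exceed max(x).")

  fit <- survival::survfit(survival::Surv(M - x, !censored) ~ 1)
  est <- km_distribution(fit, M)

  q_km <- function(p) {
    # generalized inverse of the estimated CDF (type-1 style)
    est$value[match(TRUE, est$cdf >= p - 1e-12)]
  }
  mu <- sum(est$mass * est$value)
  var_pop <- max(sum(est$mass * est$value^2) - mu^2, 0)
  sdev <- if (n > 1) sqrt(var_pop * n / (n - 1)) else NA_real_

  tibble::tibble(
    n = n, n_censored = sum(censored), pct_censored = pct_cens,
    mean = mu, sd = sdev, median = q_km(0.5), p95 = q_km(0.95),
    maximum = max(x[!censored]),
    flip_constant = M,
    mass_carried = est$leftover > 1e-12,
    all_censored = FALSE
  )
}

# Probability masses of the flipped-back product-limit distribution:
# one atom per event time, plus any leftover survival mass carried to the
# smallest observed point (largest flipped time). Returns atoms sorted by
# ascending concentration with the cumulative distribution attached.
km_distribution <- function(fit, M) {
  times <- fit$time
  surv <- fit$surv
  n_event <- fit$n.event
  prev_s <- c(1, head(surv, -1))
  is_event <- n_event > 0
  value <- M - times[is_event]
  mass <- (prev_s - surv)[is_event]
  leftover <- surv[length(surv)]
  if (leftover > 1e-12) {
    carry_point <- M - max(times)
    hit <- which(abs(value - carry_point) < 1e-12)
    if (length(hit) == 1) {
      mass[hit] <- mass[hit] + leftover
    } else {
      value <- c(value, carry_point)
      mass <- c(mass, leftover)
    }
  }
  ord <- order(value)
  value <- value[ord]
  mass <- mass[ord]
  list(value = value, mass = mass, cdf = cumsum(mass), leftover = leftover)
}

#' Table-1-style censored summaries per element and site group
#'
#' Applies [km_summary()] to every element x site-group cell of a long
#' sample table.
#'
#' @param samples Long sample tibble (see [read_samples()]).
#' @param elements Optional character vector restricting the elements.
#' @return Tibble with `element`, `site_group` and the [km_summary()]
#'   columns, one row per cell.
#' @export
summarize_elements <- function(samples, elements = NULL) {
  if (!is.null(elements)) {
    samples <- dplyr::filter(samples, .data$element %in% elements)
  }
  if (nrow(samples) == 0) abort_soilrisk("No matching measurements to summarise.")
  samples |>
    dplyr::group_by(.data$element, .data$site_group) |>
    dplyr::group_modify(function(d, key) {
      xs <- ifelse(d$censored, d$lod, d$conc)
      km_summary(xs, d$censored)
    }) |>
    dplyr::ungroup()
}

# Peto-Peto (Prentice-Wilcoxon) scores on the flipped scale, computed from
# the pooled product-limit estimate. Events score S(t-) + S(t) - 1, censored
# observations score S(t) - 1; the scores sum to zero over the pooled sample.
peto_peto_scores <- function(t, event) {
  fit <- survival::survfit(survival::Surv(t, event) ~ 1)
  times <- fit$time
  surv <- fit$surv
  prev_s <- c(1, head(surv, -1))
  s_at <- function(ti) surv[match(ti, times)]
  s_before <- function(ti) prev_s[match(ti, times)]
  ifelse(event,
         s_before(t) + s_at(t) - 1,
         s_at(t) - 1)
}

#' Peto-Peto generalized Wilcoxon test for two censored groups
#'
#' Compares the concentration distributions of two groups of possibly
#' left-censored measurements. Data are flipped about a common constant so
#' the left-censored values become right-censored survival times; the
#' Peto-Peto modification of the Gehan-Wilcoxon test is then applied.
#'
#' Two inference paths are available: the chi-square approximation
#' (`survival::survdiff` with `rho = 1`), and a small-sample permutation test
#' of the Peto-Peto score statistic (sum of the pooled Prentice-Wilcoxon
#' scores in group A), exhaustive when the number of group-label
#' arrangements is at most `max_exhaustive` and Monte-Carlo otherwise.
#'
#' @param x_a,x_b Numeric vectors of values/bounds for the two groups.
#' @param cens_a,cens_b Logical censoring indicators.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param max_exhaustive Largest number of label arrangements enumerated
#'   exhaustively.
#' @param n_mc Monte-Carlo permutations when enumeration is infeasible.
#' @return One-row tibble: `statistic` (chi-square for the asymptotic path,
#'   the absolute score sum for the permutation path), `p_value`, `method`,
#'   `skipped` (`TRUE` when a group carries no usable information, e.g. all
#'   values censored at one bound in both groups).
#' @examples
#' peto_peto(c(1, 2, 3), c(100, 200, 300))
#' @export
peto_peto <- function(x_a, x_b, cens_a = rep(FALSE, length(x_a)),
                      cens_b = rep(FALSE, length(x_b)),
                      method = c("asymptotic", "permutation"),
                      max_exhaustive = 20000, n_mc = 4999) {
  method <- match.arg(method)
  stopifnot(length(x_a) >= 2, length(x_b) >= 2)
  x <- c(x_a, x_b)
  cens <- c(as.logical(cens_a), as.logical(cens_b))
  grp <- rep(c("a", "b"), c(length(x_a), length(x_b)))
  skip_result <- function() tibble::tibble(
    statistic = NA_real_, p_value = NA_real_, method = method, skipped = TRUE)
  if (all(cens) || length(unique(ifelse(cens, -x, x))) == 1) {
    return(skip_result())
  }
  M <- max(x) + 1
  t <- M - x
  event <- !cens

  if (method == "asymptotic") {
    sd1 <- tryCatch(
      survival::survdiff(survival::Surv(t, event) ~ grp, rho = 1),
      error = function(e) NULL)
    if (is.null(sd1) || !is.finite(sd1$chisq)) return(skip_result())
    return(tibble::tibble(
      statistic = unname(sd1$chisq),
      p_value = pchisq(unname(sd1$chisq), df = 1, lower.tail = FALSE),
      method = "asymptotic", skipped = FALSE))
  }

  scores <- peto_peto_scores(t, event)
  n_a <- length(x_a)
  obs <- abs(sum(scores[grp == "a"]))
  n_arrangements <- choose(length(x), n_a)
  if (n_arrangements <= max_exhaustive) {
    idx <- combn(length(x), n_a)
    stats <- abs(colSums(matrix(scores[idx], nrow = n_a)))
    p <- mean(stats >= obs - 1e-12)
    meth <- "permutation_exhaustive"
  } else {
    stats <- vapply(seq_len(n_mc), function(i) {
      abs(sum(scores[sample.int(length(x), n_a)]))
    }, numeric(1))
    p <- (1 + sum(stats >= obs - 1e-12)) / (n_mc + 1)
    meth <- "permutation_mc"
  }
  tibble::tibble(statistic = obs, p_value = p, method = meth, skipped = FALSE)
}

#' Pairwise Peto-Peto screen across elements and site groups
#'
#' Runs [peto_peto()] for every pair of site groups, for every element, and
#' attaches Benjamini-Hochberg adjusted p-values over the whole family of
#' tests. Elements for which no pairwise comparison reaches `alpha` on the
#' adjusted scale are flagged as showing no group difference (the criterion
#' used to drop elements from further analysis).
#'
#' @param samples Long sample tibble.
#' @param elements Elements to screen; defaults to all present.
#' @param alpha Significance level for the screen (adjusted p-values).
#' @param method Passed to [peto_peto()].
#' @return Tibble: `element`, `group_a`, `group_b`, `statistic`, `p_value`,
#'   `p_adjusted`, `method`, `skipped`, `no_group_difference` (per-element
#'   flag, repeated on each of its rows).
#' @export
pairwise_screen <- function(samples, elements = NULL, alpha = 0.05,
                            method = c("asymptotic", "permutation")) {
  method <- match.arg(method)
  groups <- sort(unique(samples$site_group))
  if (length(groups) < 2) {
    abort_soilrisk(">= 2 site groups required for the pairwise screen.")
  }
  present <- unique(samples$element)
  if (is.null(elements)) {
    elements <- sort(present)
  } else {
    absent <- setdiff(elements, present)
    if (length(absent) > 0) {
      rlang::warn(paste0("Element(s) absent from dataset, skipped: ",
                         paste(absent, collapse = ", ")))
      elements <- intersect(elements, present)
    }
  }
  pairs <- combn(groups, 2)
  res <- purrr::map_dfr(elements, function(el) {
    d <- dplyr::filter(samples, .data$element == el)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      ga <- pairs[1, k]; gb <- pairs[2, k]
      da <- dplyr::filter(d, .data$site_group == ga)
      db <- dplyr::filter(d, .data$site_group == gb)
      if (nrow(da) < 2 || nrow(db) < 2) {
        return(tibble::tibble(element = el, group_a = ga, group_b = gb,
                              statistic = NA_real_, p_value = NA_real_,
                              method = method, skipped = TRUE))
      }
      out <- peto_peto(ifelse(da$censored, da$lod, da$conc),
                       ifelse(db$censored, db$lod, db$conc),
                       da$censored, db$censored, method = method)
      dplyr::bind_cols(tibble::tibble(element = el, group_a = ga, group_b = gb), out)
    })
  })
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  flag <- res |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(no_group_difference =
                       all(is.na(.data$p_adjusted) | .data$p_adjusted >= alpha))
  dplyr::left_join(res, flag, by = "element")
}

#' Ordinary least-squares comparability regression between two methods
#'
#' Fits `y ~ x` for paired measurements of the same samples by two analytical
#' methods (e.g. field XRF vs ICP-MS after acid digestion) and reports slope,
#' intercept, R-squared and the slope p-value.
#'
#' @param x,y Paired uncensored concentrations (mg/kg), `length >= 3`.
#' @return Object of class `comparability_fit`; use [tidy()] / [glance()]
#'   for tabular views.
#' @examples
#' fit <- comparability_regression(c(1, 2, 3, 4), c(1.1, 2.0, 2.9, 4.2))
#' glance(fit)
#' @export
comparability_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort_soilrisk("At least 3 complete pairs required.")
  if (stats::var(x) == 0) abort_soilrisk("Zero variance in x; regression undefined.")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = sm$r.squared,
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    n = length(x),
    model = fit
  ), class = "comparability_fit")
}

#' @export
print.comparability_fit <- function(x, ...) {
  cat(sprintf("Method-comparability OLS (n = %d)\n", x$n))
  cat(sprintf("  slope %.4g, intercept %.4g, R^2 %.3f, slope p %.3g\n",
              x$slope, x$intercept, x$r2, x$p_value))
  invisible(x)
}

#' @rdname comparability_regression
#' @param x A `comparability_fit` object.
#' @param ... Unused.
#' @export
tidy.comparability_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname comparability_regression
#' @export
glance.comparability_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, slope = x$slope, intercept = x$intercept,
                 p.value = x$p_value, n = x$n)
}

#' Standard reference material recovery
#'
#' @param measured Measured concentration(s), mg/kg.
#' @param certified Certified value(s), mg/kg, `> 0`.
#' @return Recovery in percent, `100 * measured / certified`.
#' @examples
#' srm_recovery(95, 100)  # 95
#' @export
srm_recovery <- function(measured, certified) {
  if (any(!is.finite(certified)) || any(certified <= 0)) {
    abort_soilrisk("`certified` must be positive.")
  }
  100 * measured / certified
}
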