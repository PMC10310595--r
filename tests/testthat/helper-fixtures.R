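# Shared fixture builders; everything is generated in code.

# Long sample tibble from a named concentration vector (one sample).
one_sample_tbl <- function(conc, site_group = "burning", sample_id = "S1") {
  tibble::tibble(
    sample_id = sample_id, site_group = site_group,
    x = NA_real_, y = NA_real_,
    element = names(conc), conc = unname(conc),
    censored = FALSE, lod = NA_real_
  )
}

# Long sample tibble for one element across groups, from per-group value lists.
element_groups_tbl <- function(element, values_by_group, censored_by_group = NULL) {
  purrr::imap_dfr(values_by_group, function(v, grp) {
    cen <- if (is.null(censored_by_group)) rep(FALSE, length(v)) else censored_by_group[[grp]]
    tibble::tibble(
      sample_id = paste0(grp, "_", seq_along(v)), site_group = grp,
      x = NA_real_, y = NA_real_, element = element,
      conc = ifelse(cen, NA_real_, v), censored = cen,
      lod = ifelse(cen, v, NA_real_)
    )
  })
}

# Mean concentrations used by the deterministic risk checks.
burning_means <- c(Ag = 162, As = 191, Cd = 56, Cr = 139, Cu = 16700, Mo = 18,
                   Ni = 138, Pb = 6534, Sb = 554, Sn = 1005, Zn = 15470)
dismantling_means <- c(Ag = 38, As = 19, Cd = 38, Cr = 337, Cu = 3257, Mo = 24,
                       Ni = 96, Pb = 645, Sb = 105, Sn = 130, Zn = 1530)

# Independent Peto-Peto oracle: Prentice-Wilcoxon scores computed from first
# principles (pooled KM by explicit risk-set arithmetic, no survfit), then
# exhaustive enumeration of group-label arrangements.
oracle_peto_perm <- function(x_a, x_b, cens_a, cens_b) {
  x <- c(x_a, x_b); cens <- c(cens_a, cens_b)
  M <- max(x) + 1
  t <- M - x; event <- !cens
  ut <- sort(unique(t[event]))
  n <- length(t)
  s <- 1
  surv_at <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(t >= ut[k])
    d <- sum(event & t == ut[k])
    s <- s * (1 - d / at_risk)
    surv_at[k] <- s
  }
  S <- function(ti) { # right-continuous KM at ti
    k <- sum(ut <= ti)
    if (k == 0) 1 else surv_at[k]
  }
  S_minus <- function(ti) {
    k <- sum(ut < ti)
    if (k == 0) 1 else surv_at[k]
  }
  scores <- ifelse(event,
                   vapply(t, function(ti) S_minus(ti) + S(ti) - 1, 0),
                   vapply(t, function(ti) S(ti) - 1, 0))
  n_a <- length(x_a)
  obs <- abs(sum(scores[seq_len(n_a)]))
  idx <- utils::combn(n, n_a)
  stats <- abs(colSums(matrix(scores[idx], nrow = n_a)))
  list(p = mean(stats >= obs - 1e-12), statistic = obs)
}
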