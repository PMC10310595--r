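test_that("km_summary reproduces the hand-computed product-limit mean", {
  # {<1, 2, 3}: flip about M = 4; survival steps 2/3 after flipped time 1,
  # 1/3 after flipped time 2; restricted-mean area 1 + 2/3 + 1/3 = 2 on the
  # flipped scale; mean = 4 - 2 = 2.0.
  s <- km_summary(c(1, 2, 3), c(TRUE, FALSE, FALSE))
  expect_equal(s$mean, 2.0, tolerance = 1e-12)
  expect_equal(s$pct_censored, 100 / 3)
  expect_true(s$mass_carried)  # smallest point is a censored bound
  expect_equal(s$median, 2)
})

test_that("with zero censoring KM summaries equal arithmetic statistics", {
  set.seed(11)
  for (n in c(1, 2, 5, 30)) {
    x <- rlnorm(n, 2, 1)
    s <- km_summary(x)
    expect_equal(s$mean, mean(x), tolerance = 1e-12)
    if (n > 1) expect_equal(s$sd, sd(x), tolerance = 1e-12)
    expect_equal(s$median, quantile(x, 0.5, type = 1, names = FALSE),
                 tolerance = 1e-12)
    expect_equal(s$p95, quantile(x, 0.95, type = 1, names = FALSE),
                 tolerance = 1e-12)
    expect_equal(s$maximum, max(x))
  }
})

test_that("KM mean lies within the substitution bounds and ignores the flip constant", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- rlnorm(n, 1, 1)
    lod <- quantile(x, runif(1, 0.1, 0.6))
    cens <- x < lod
    if (all(cens) || !any(cens)) next
    xs <- ifelse(cens, lod, x)
    s <- km_summary(xs, cens)
    lo <- mean(ifelse(cens, 0, x))
    hi <- mean(xs)
    expect_gte(s$mean, lo - 1e-12)
    expect_lte(s$mean, hi + 1e-12)
    expect_lte(s$median, s$p95)
    expect_lte(s$p95, s$maximum)
    # flip-invariance: any valid M gives identical estimates
    s2 <- km_summary(xs, cens, flip_constant = max(xs) * 7 + 3)
    expect_equal(s2$mean, s$mean, tolerance = 1e-12)
    expect_equal(s2$sd, s$sd, tolerance = 1e-12)
    expect_equal(s2$median, s$median, tolerance = 1e-12)
  }
})

test_that("fully censored input yields a flagged upper-bound summary", {
  s <- km_summary(c(4, 6, 4), c(TRUE, TRUE, TRUE))
  expect_true(s$all_censored)
  expect_equal(s$mean, 4)   # smallest reporting bound, as an upper bound
  expect_equal(s$median, 4)
  expect_true(is.na(s$sd))
})

test_that("peto_peto is null on identical groups and detects separation", {
  x <- c(1, 2, 3)
  r <- peto_peto(x, x)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  r2 <- peto_peto(c(1, 2, 3), c(100, 200, 300))
  expect_lt(r2$p_value, 0.05)
  # permutation path on the same data: identical groups give p = 1
  rp <- peto_peto(x, x, method = "permutation")
  expect_equal(rp$p_value, 1)
})

test_that("permutation p-values agree with an independent exhaustive oracle", {
  set.seed(5)
  cases <- list(
    list(a = c(1, 2, 3, 4), b = c(2.5, 3.5, 9, 11),
         ca = rep(FALSE, 4), cb = rep(FALSE, 4)),
    list(a = c(1, 1, 2, 5, 7), b = c(3, 4, 6, 8),
         ca = c(TRUE, FALSE, FALSE, FALSE, FALSE), cb = c(TRUE, FALSE, FALSE, FALSE)),
    list(a = rlnorm(7), b = rlnorm(8, 1), ca = rep(FALSE, 7), cb = rep(FALSE, 8)),
    list(a = c(2, 2, 3, 3, 10, 12), b = c(2, 4, 4, 9, 9, 15),
         ca = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
         cb = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  )
  for (cs in cases) {
    got <- peto_peto(cs$a, cs$b, cs$ca, cs$cb, method = "permutation")
    want <- oracle_peto_perm(cs$a, cs$b, cs$ca, cs$cb)
    expect_equal(got$method, "permutation_exhaustive")
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("degenerate groups are skipped with an explicit flag", {
  r <- peto_peto(c(4, 4, 4), c(4, 4, 4), rep(TRUE, 3), rep(TRUE, 3))
  expect_true(r$skipped)
  expect_true(is.na(r$p_value))
})

test_that("pairwise screen flags null elements, detects shifts, needs >= 2 groups", {
  set.seed(31)
  base <- rlnorm(30, 3, 0.5)
  d <- dplyr::bind_rows(
    element_groups_tbl("Ni", list(community = base[1:10], burning = base[11:20],
                                  dismantling = base[21:30])),
    element_groups_tbl("Pb", list(community = rlnorm(10, 3, 0.3),
                                  burning = rlnorm(10, 3, 0.3) * 10,
                                  dismantling = rlnorm(10, 3, 0.3)))
  )
  scr <- pairwise_screen(d)
  expect_true(all(scr$p_adjusted >= scr$p_value - 1e-15, na.rm = TRUE))
  ni <- scr[scr$element == "Ni", ]
  expect_true(all(ni$no_group_difference))
  pb <- scr[scr$element == "Pb", ]
  expect_false(any(pb$no_group_difference))
  burning_pairs <- pb[pb$group_a == "burning" | pb$group_b == "burning", ]
  expect_true(all(burning_pairs$p_adjusted < 0.05))

  single <- element_groups_tbl("Pb", list(community = rlnorm(5)))
  expect_error(pairwise_screen(single), ">= 2 site groups")
  expect_warning(pairwise_screen(d, elements = c("Pb", "Cu")), "Cu")
})

test_that("comparability regression matches exact lines and the normal equations", {
  x <- c(1, 5, 9, 13)
  # exact fits trigger lm's "essentially perfect fit" warning by design
  g <- suppressWarnings(glance(comparability_regression(x, x)))
  expect_equal(g$slope, 1, tolerance = 1e-12)
  expect_equal(g$intercept, 0, tolerance = 1e-12)
  expect_equal(g$r.squared, 1, tolerance = 1e-12)
  g2 <- suppressWarnings(glance(comparability_regression(x, 2 * x + 1)))
  expect_equal(g2$slope, 2, tolerance = 1e-12)
  expect_equal(g2$intercept, 1, tolerance = 1e-12)

  set.seed(17)
  xr <- runif(25, 1, 100)
  yr <- 3 + 0.8 * xr + rnorm(25, 0, 5)
  fit <- comparability_regression(xr, yr)
  # closed-form normal equations, computed independently
  b <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  a <- mean(yr) - b * mean(xr)
  expect_equal(fit$slope, b, tolerance = 1e-10)
  expect_equal(fit$intercept, a, tolerance = 1e-10)
  expect_error(comparability_regression(rep(2, 5), 1:5), "variance")
  td <- tidy(fit)
  expect_equal(td$estimate, c(a, b), tolerance = 1e-10)
})

test_that("SRM recovery is plain percentage arithmetic", {
  expect_equal(srm_recovery(100, 100), 100)
  expect_equal(srm_recovery(0, 100), 0)
  expect_equal(srm_recovery(95, 100), 95)
  expect_equal(srm_recovery(c(95, 96), c(100, 100)), c(95, 96))
  expect_error(srm_recovery(5, 0), "positive")
})
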