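child <- receptor_profile("child", ing_rate = 0.0004, body_weight = 30)
adult <- receptor_profile("adult", ing_rate = 0.0001, body_weight = 70)

test_that("chemical daily intake follows the exposure model", {
  expect_equal(chemical_daily_intake(6534, child), 6534 * 0.0004 / 30,
               tolerance = 1e-12)  # 0.08712
  expect_equal(chemical_daily_intake(0, child), 0)
  # child/adult intake ratio is fixed by the exposure constants: 4 * 70/30
  ms <- 1234
  expect_equal(chemical_daily_intake(ms, child) / chemical_daily_intake(ms, adult),
               4 * 70 / 30, tolerance = 1e-12)
  # carcinogenic amortization: duration/LE, defaulting to 1
  expect_equal(chemical_daily_intake(ms, adult, carcinogenic = TRUE),
               chemical_daily_intake(ms, adult), tolerance = 1e-12)
  part <- receptor_profile("part", 1e-4, 70, exposure_duration = 16,
                           life_expectancy = 64)
  expect_equal(chemical_daily_intake(ms, part, carcinogenic = TRUE),
               chemical_daily_intake(ms, part) * 16 / 64, tolerance = 1e-12)
  # exposure-term fraction
  wk <- receptor_profile("wk", 1e-4, 70, days_per_week = 3.5, weeks_per_year = 26)
  expect_equal(chemical_daily_intake(ms, wk), ms * 1e-4 * 0.25 / 70,
               tolerance = 1e-12)
})

test_that("hazard quotient, index and cancer risk are the stated products", {
  expect_equal(hazard_quotient(0.08712, 0.56465, 0.0036),
               0.08712 * 0.56465 / 0.0036, tolerance = 1e-12)  # ~13.66
  expect_equal(hazard_quotient(0.5, 0, 0.1), 0)
  expect_equal(hazard_quotient(0.02, 1, 0.02), 1)
  expect_error(hazard_quotient(1, 1, 0), "positive")
  expect_error(hazard_quotient(1, 1.2, 1), "\\[0, 1\\]")

  hqs <- c(Pb = 13.66, Cu = 13.11, Sb = 14.77)
  expect_equal(hazard_index(hqs)$hi, sum(hqs))
  expect_equal(hazard_index(rev(hqs))$hi, hazard_index(hqs)$hi)
  expect_equal(hazard_index(c(Pb = 13.66))$hi, 13.66)
  expect_equal(hazard_index(c(a = 0, b = 0))$hi, 0)
  expect_error(hazard_index(numeric(0)), "No hazard")

  cdi <- 191 * 0.0001 / 70
  expect_equal(cancer_risk(cdi, 1.8, 0.21407), cdi * 1.8 * 0.21407,
               tolerance = 1e-12)  # 1.05e-4
  expect_equal(cancer_risk(0, 1.8, 0.2), 0)
  expect_equal(cancer_risk(2 * cdi, 1.8, 0.21407),
               2 * cancer_risk(cdi, 1.8, 0.21407), tolerance = 1e-12)
  expect_error(cancer_risk(1, NA, 1), "positive")
})

test_that("assess_dataset bundles HQ/HI/CR with flags and conventions", {
  d <- one_sample_tbl(burning_means, "burning")
  res <- assess_dataset(d, rba_map(NULL))
  expect_equal(nrow(res), 2)
  ch <- res[res$receptor == "child", ]
  ad <- res[res$receptor == "adult", ]
  expect_true(ch$hi_exceeds)
  expect_true(ad$cr_exceeds)
  expect_true(is.na(ch$cr_as))  # cancer risk is adult-only by default
  # HI equals the sum of the per-element HQ columns
  hq_cols <- grep("^hq_", names(ch), value = TRUE)
  expect_equal(ch$hi, sum(unlist(ch[hq_cols])), tolerance = 1e-12)
  # child/adult HI ratio fixed by the exposure constants
  expect_equal(ch$hi / ad$hi, 4 * 70 / 30, tolerance = 1e-12)
  expect_equal(attr(res, "conventions")$censoring, "half_lod")
  # broom-style views
  g <- glance(res)
  expect_equal(g$n_samples, c(1, 1))
  long <- tidy(res)
  expect_equal(nrow(long), 2 * length(burning_means))
})

test_that("zero-ish concentrations produce zero risk and no flags", {
  d <- one_sample_tbl(burning_means, "community")
  d$conc <- 1e-12
  res <- assess_dataset(d, rba_map(NULL))
  expect_true(all(res$hi < 1e-6))
  expect_false(any(res$hi_exceeds))
  expect_false(any(res$cr_exceeds, na.rm = TRUE))
})

test_that("elements without a TDI are skipped loudly, never zeroed", {
  d <- one_sample_tbl(c(burning_means, Au = 30), "burning")
  res <- assess_dataset(d, rba_map(NULL))
  expect_match(res$skipped_elements[1], "Au")
  expect_false(grepl("Au", res$hi_elements[1]))
  expect_true(is.na(res$hq_Au[1]))
  # Au contributes nothing: identical HI without it
  res2 <- assess_dataset(one_sample_tbl(burning_means, "burning"), rba_map(NULL))
  expect_equal(res$hi, res2$hi, tolerance = 1e-12)
})

test_that("risk is monotone in every single concentration", {
  rba <- rba_map(NULL)
  base <- assess_dataset(one_sample_tbl(dismantling_means, "dismantling"), rba)
  for (el in c("As", "Pb", "Zn")) {
    bumped <- dismantling_means
    bumped[el] <- bumped[el] * 2
    res <- assess_dataset(one_sample_tbl(bumped, "dismantling"), rba)
    expect_gt(res$hi[1], base$hi[1])
    expect_gte(res$cr_as[res$receptor == "adult"],
               base$cr_as[base$receptor == "adult"])
  }
})

test_that("censoring conventions bracket the risk", {
  d <- one_sample_tbl(dismantling_means, "dismantling")
  d$censored[d$element == "Pb"] <- TRUE
  d$conc[d$element == "Pb"] <- NA
  d$lod[d$element == "Pb"] <- 4
  rba <- rba_map(NULL)
  hz <- function(conv) assess_dataset(d, rba, censoring = conv)$hi[1]
  expect_lt(hz("zero"), hz("half_lod"))
  expect_lt(hz("half_lod"), hz("lod"))
})
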