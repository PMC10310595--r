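test_that("packaged registry carries the constants the analysis relies on", {
  reg <- element_registry()
  expect_setequal(reg$element, c("Ag", "As", "Au", "Cd", "Cr", "Cu", "Mo",
                                 "Ni", "Pb", "Sb", "Sn", "Zn"))
  as_row <- reg[reg$element == "As", ]
  expect_equal(as_row$ccme_residential, 12)
  expect_equal(as_row$tdi, 0.0003)
  expect_equal(as_row$csf, 1.8)
  expect_equal(reg$rba_rule[reg$element == "Sb"], "fixed_one")
  expect_equal(reg$rba_rule[reg$element == "As"], "regression_as")
  expect_equal(reg$rba_rule[reg$element == "Pb"], "regression_pb")
  expect_setequal(reg$element[reg$rba_rule == "direct_ivba"],
                  c("Ag", "Cr", "Cu", "Ni", "Zn"))
  expect_setequal(reg$element[reg$rba_rule == "fixed_one" & reg$element != "Au"],
                  c("Cd", "Mo", "Sb", "Sn"))
  # only the carcinogen carries a slope factor
  expect_true(all(is.na(reg$csf[reg$element != "As"])))
  # hazard-index family excludes Au, which has no TDI
  expect_setequal(hi_elements(), setdiff(reg$element, "Au"))
  expect_true(all(is.finite(reg$tdi[match(hi_elements(), reg$element)])))
  # backgrounds are user-supplied, not packaged
  expect_true(all(is.na(reg$background_mean)))
})

test_that("set_backgrounds validates and fills, receptors validate bounds", {
  reg <- set_backgrounds(element_registry(), c(Pb = 25, Zn = 80))
  expect_equal(reg$background_mean[reg$element == "Pb"], 25)
  expect_error(set_backgrounds(element_registry(), c(Pb = -1)), "positive")
  expect_error(set_backgrounds(element_registry(), c(Xx = 5)), "Unknown")
  expect_error(receptor_profile("r", ing_rate = 0, body_weight = 30))
  expect_error(receptor_profile("r", 1e-4, 70, days_per_week = 9))
  rec <- default_receptors()
  expect_equal(rec$et_fraction, c(1, 1))
  expect_equal(rec$ing_rate, c(4e-4, 1e-4))
  expect_equal(rec$body_weight, c(30, 70))
})

test_that("read_samples parses numeric cells, censoring marks and both dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,site_group,Pb,As",
               "S1,burning,6534,12",
               "S2,community,44,<4"), f)
  d <- read_samples(f)
  pb1 <- d[d$sample_id == "S1" & d$element == "Pb", ]
  expect_equal(pb1$conc, 6534)
  expect_false(pb1$censored)
  as2 <- d[d$sample_id == "S2" & d$element == "As", ]
  expect_true(as2$censored)
  expect_equal(as2$lod, 4)
  expect_true(is.na(as2$conc))

  # paired value/flag dialect
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,site_group,As,As_cen",
               "S1,community,4,TRUE",
               "S2,community,9,FALSE"), f2)
  d2 <- read_samples(f2)
  expect_equal(d2$censored, c(TRUE, FALSE))
  expect_equal(d2$lod[1], 4)

  # header-only file -> empty table
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,site_group,Pb", f3)
  expect_equal(nrow(read_samples(f3)), 0)
})

test_that("read_samples rejects bad groups and values, warns on unknown columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,site_group,Pb", "S1,lagoon,5"), f)
  expect_error(read_samples(f), "lagoon")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,site_group,Pb", "S1,burning,-3"), f2)
  expect_error(read_samples(f2), "Non-positive")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,site_group,Pb,Kryptonite", "S1,burning,5,1"), f3)
  expect_warning(d <- read_samples(f3), "Kryptonite")
  expect_setequal(unique(d$element), "Pb")
})

test_that("sample tables round-trip through write_samples, censoring marks intact", {
  cfg <- synthetic_config(seed = 7, n_per_group = c(community = 6, burning = 3))
  samples <- generate_soil(cfg)$samples
  f <- withr::local_tempfile(fileext = ".csv")
  write_samples(samples, f)
  back <- read_samples(f)
  key <- function(d) dplyr::arrange(d, sample_id, element)
  a <- key(samples); b <- key(back)
  expect_equal(b$censored, a$censored)
  expect_equal(b$conc, a$conc, tolerance = 1e-12)
  expect_equal(b$lod[b$censored], a$lod[a$censored], tolerance = 1e-12)
})

test_that("write_results keeps schema, honours allow_empty, and round-trips", {
  tbl <- tibble::tibble(sample_id = c("a", "b"), hi = c(1.234567890123, 2),
                        flag = c(TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(tbl, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(names(back), names(tbl))
  expect_equal(back$hi, tbl$hi, tolerance = 1e-12)
  expect_error(write_results(tbl[0, ], f), "empty")
  write_results(tbl[0, ], f, allow_empty = TRUE)
  expect_equal(nrow(readr::read_csv(f, show_col_types = FALSE)), 0)
})

test_that("run configuration defaults are sane and overridable", {
  cfg <- read_run_config(NULL)
  expect_equal(cfg$thresholds$hi_limit, 1)
  expect_equal(cfg$thresholds$cr_limit, 1e-5)
  expect_equal(cfg$censoring, "half_lod")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 99", "censoring: lod",
               "thresholds:", "  hi_limit: 2",
               "backgrounds:", "  Pb: 25"), f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$seed, 99)
  expect_equal(cfg2$censoring, "lod")
  expect_equal(cfg2$thresholds$hi_limit, 2)
  expect_equal(cfg2$backgrounds$Pb, 25)
})
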