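# Synthetic cohort generator and delimited-text round trips.

test_that("generator is deterministic and respects the configured strata", {
  cfg <- cohort_config(n_patients = 300, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  grp <- classify_lifespan(a$rbc_lifespan_days)
  for (g in c("SHORT", "MID", "NORMAL")) {
    r <- cfg$lifespan_ranges[[g]]
    v <- a$rbc_lifespan_days[grp == g]
    expect_true(all(v >= r[1] & v <= r[2]))
  }
  expect_true(all(a$hba1c_pct > 4 & a$hba1c_pct < 14))
  # byte-identical file output for identical configs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("group shares and CVD odds land in the stated bands at n=10000", {
  met <- make_metric_cohort(n = 10000, seed = 2024)
  p <- group_proportions(met$group)
  expect_lt(abs(p$pct[p$group == "SHORT"] - 19.23), 1.5)
  expect_lt(abs(p$pct[p$group == "MID"] - 33.17), 2)
  or <- complication_odds(met)
  cvd <- or$odds_ratio[or$flag == "cvd_flag"]
  expect_gt(cvd, 1.224)
  expect_lt(cvd, 2.833)
})

test_that("zero-noise SHORT-only cohort satisfies the generating model exactly", {
  cfg <- cohort_config(n_patients = 50, seed = 9, hgi_noise_sd = 0,
                       group_proportions = c(SHORT = 1, MID = 0, NORMAL = 0))
  met <- glycemia_metrics(simulate_cohort(cfg))
  m <- published_models()$SHORT
  expect_equal(met$ehba1c_pct,
               m$beta_lifespan * met$rbc_lifespan_days +
                 m$beta_hba1c * met$hba1c_pct + m$intercept,
               tolerance = 1e-12)
})

test_that("group HGI medians track the reference values under defaults", {
  met <- make_metric_cohort(n = 10000, seed = 31)
  med <- tapply(met$hgi, met$group, median)
  expect_lt(abs(med[["SHORT"]] - (-0.855)), 0.15)
  expect_lt(abs(med[["MID"]] - (-0.415)), 0.15)
  expect_lt(abs(med[["NORMAL"]] - (-0.020)), 0.15)
  # monotone structure: mean HGI non-decreasing SHORT -> MID -> NORMAL
  mu <- tapply(met$hgi, met$group, mean)
  expect_true(mu[["SHORT"]] <= mu[["MID"]] &&
                mu[["MID"]] <= mu[["NORMAL"]])
})

test_that("infeasible configs are rejected", {
  expect_error(cohort_config(n_patients = 5), ">= 10")
  expect_error(cohort_config(group_proportions = c(SHORT = 0.5, MID = 0.5,
                                                   NORMAL = 0.5)), "sum to 1")
  expect_error(cohort_config(baseline_complication_rate = 1), "\\(0, 1\\)")
  expect_error(cohort_config(complication_or_targets = c(cvd = -1,
                                                         neuropathy = 1,
                                                         fundus = 1)),
               "odds ratios")
})

test_that("cohort files round-trip including the empty cohort", {
  coh <- simulate_cohort(cohort_config(n_patients = 25, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$patient_id, coh$patient_id)
  expect_equal(back$hba1c_pct, coh$hba1c_pct, tolerance = 1e-5)
  expect_equal(back$cvd_flag, coh$cvd_flag)
  expect_identical(names(back), names(coh))

  write_cohort(coh[0, ], path)
  expect_equal(nrow(read_cohort(path)), 0)
})

test_that("read_cohort reports invalid rows with file line numbers", {
  df <- data.frame(patient_id = c("a", "b", "c"),
                   hba1c_pct = c(7, 25, 8),
                   ag_mmol_L = c(8, 9, 10),
                   rbc_lifespan_days = c(80, 90, 210),
                   cvd_flag = c(0, 1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(df, path)
  expect_warning(back <- read_cohort(path), "line 3.*line 4")
  expect_equal(nrow(back), 1)
  rej <- attr(back, "rejected")
  expect_equal(rej$line, c(3L, 4L))
  expect_match(rej$reason[1], "hba1c_pct")
  expect_match(rej$reason[2], "rbc_lifespan_days.*cvd_flag")
})

test_that("header violations are named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,hba1c_pct", "a,7"), path)
  expect_error(read_cohort(path), "missing column")
  writeLines(c("patient_id,hba1c_pct,ag_mmol_L,rbc_lifespan_days,shoe_size",
               "a,7,8,80,42"), path)
  expect_error(read_cohort(path), "unknown column.*shoe_size")
})
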