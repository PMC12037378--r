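# Inflection detection and subgroup OLS correction-model fitting.

# noiseless two-segment HGI profile with a known break
hinge_data <- function(break_day = 66, n = 120, slope_pre = 0.06,
                       slope_post = 0.002, seed = 10, noise_sd = 0) {
  set.seed(seed)
  x <- runif(n, 45, 110)
  y <- slope_pre * pmin(x - break_day, 0) + slope_post * pmax(x - break_day, 0) +
    rnorm(n, 0, max(noise_sd, 0)) - 0.1
  list(x = x, y = y)
}

test_that("detect_inflection recovers a noiseless 66-day break exactly", {
  d <- hinge_data(66)
  res <- detect_inflection(d$x, d$y, grid = 50:100)
  expect_equal(res$inflection_days, 66)
  expect_equal(res$segment_slopes[["pre"]], 0.06, tolerance = 1e-8)
  expect_equal(res$segment_slopes[["post"]], 0.002, tolerance = 1e-8)
  expect_true(res$material)
  expect_true(all(res$sse <= res$candidate_profile$sse + 1e-9))
})

test_that("globally linear data is flagged as no material inflection", {
  set.seed(12)
  x <- runif(60, 45, 110)
  y <- 0.01 * x - 1
  res <- detect_inflection(x, y, grid = 50:100)
  expect_false(res$material)
  expect_lt(diff(range(res$candidate_profile$sse)), 1e-18)
})

test_that("detect_inflection is shift-equivariant on noiseless data", {
  d <- hinge_data(70, seed = 14)
  r0 <- detect_inflection(d$x, d$y, grid = 50:100)
  r5 <- detect_inflection(d$x + 5, d$y, grid = 55:105)
  expect_equal(r5$inflection_days, r0$inflection_days + 5)
})

test_that("grid and size preconditions are enforced", {
  d <- hinge_data(66, n = 30)
  expect_error(detect_inflection(d$x, d$y, grid = 20:120), "outside")
  expect_error(detect_inflection(d$x[1:10], d$y[1:10], grid = 50:60),
               ">= 20")
})

test_that("default-cohort inflection lands near the generating 66-day break", {
  met <- make_metric_cohort(n = 5000, seed = 77)
  grid <- seq(ceiling(min(met$rbc_lifespan_days)),
              floor(max(met$rbc_lifespan_days)))
  res <- detect_inflection(met$rbc_lifespan_days, met$hgi, grid = grid)
  expect_lt(abs(res$inflection_days - 66), 3 + 1e-9)
})

test_that("fit_correction_model recovers published coefficients exactly", {
  for (g in c("SHORT", "MID")) {
    m <- fit_correction_model(make_exact_cohort(g), g)
    ref <- published_models()[[g]]
    expect_equal(m$beta_lifespan, ref$beta_lifespan, tolerance = 1e-6)
    expect_equal(m$beta_hba1c, ref$beta_hba1c, tolerance = 1e-6)
    expect_equal(m$intercept, ref$intercept, tolerance = 1e-6)
    expect_equal(m$multiple_R, 1, tolerance = 1e-6)
    expect_lt(m$f_pvalue, 0.05)
  }
})

test_that("a 10-point system matches the normal-equations solve", {
  set.seed(33)
  df <- data.frame(
    hba1c_pct = runif(10, 5, 10),
    rbc_lifespan_days = runif(10, 40, 66),
    ag_mmol_L = runif(10, 5, 15))
  m <- fit_correction_model(df, "SHORT")
  X <- cbind(1, df$rbc_lifespan_days, df$hba1c_pct)
  beta <- solve(t(X) %*% X, t(X) %*% estimated_hba1c(df$ag_mmol_L))
  expect_equal(c(m$intercept, m$beta_lifespan, m$beta_hba1c), c(beta),
               tolerance = 1e-10)
  # residual orthogonality to each design column
  r <- estimated_hba1c(df$ag_mmol_L) - X %*% beta
  expect_true(all(abs(t(X) %*% r) < 1e-8 * nrow(df)))
})

test_that("degenerate fits are rejected", {
  df <- make_exact_cohort("SHORT", n = 20)
  df$rbc_lifespan_days <- 60
  expect_error(fit_correction_model(df, "SHORT"), "singular")
  expect_error(fit_correction_model(make_exact_cohort("SHORT", n = 5), "SHORT"),
               ">= 10")
})

test_that("coefficient RMSE shrinks with sample size at fixed noise", {
  rmse_at <- function(n) {
    errs <- vapply(1:8, function(s) {
      cfg <- cohort_config(n_patients = n, seed = 1000 + s,
                           group_proportions = c(SHORT = 1, MID = 0,
                                                 NORMAL = 0))
      m <- fit_correction_model(glycemia_metrics(simulate_cohort(cfg)),
                                "SHORT")
      ref <- published_models()$SHORT
      sqrt(mean((c(m$beta_lifespan, m$beta_hba1c, m$intercept) -
                   c(ref$beta_lifespan, ref$beta_hba1c, ref$intercept))^2))
    }, numeric(1))
    mean(errs)
  }
  r <- c(rmse_at(200), rmse_at(2000), rmse_at(20000))
  expect_true(all(diff(r) < 0))
})
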