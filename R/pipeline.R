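# End-to-end study replica: simulate or load cohorts, split construction vs
# internal, derive metrics, detect the inflection, fit and apply correction
# models, validate each cohort, and write a reproducible output tree.

#' Split a cohort into construction and internal subsets
#'
#' Simple random allocation without stratification. By default the
#' construction size is `round(n * a / (a + b))` for ratio `a:b`, so the
#' sizes differ from the exact ratio by less than one record (516 at 4:1
#' gives 413/103). Fixed sizes can be requested instead (e.g. the reference
#' study's 416/100).
#'
#' @param records Patient-record data frame (>= 5 rows).
#' @param ratio Two positive numbers, construction:internal (default 4:1).
#' @param seed RNG seed for the allocation.
#' @param sizes Optional `c(n_construction, n_internal)` overriding the
#'   ratio; must sum to `nrow(records)`.
#' @return List with `construction` and `internal` data frames; disjoint and
#'   exhaustive, `cohort_label` relabelled accordingly.
#' @export
split_cohort <- function(records, ratio = c(4, 1), seed = 1L, sizes = NULL) {
  n <- nrow(records)
  if (n < 5) stop("split_cohort: need at least 5 records")
  if (is.null(sizes)) {
    if (length(ratio) != 2 || any(ratio <= 0))
      stop("split_cohort: ratio must be two positive parts")
    n_con <- round(n * ratio[1] / sum(ratio))
    n_con <- min(max(n_con, 1L), n - 1L)
  } else {
    if (length(sizes) != 2 || any(sizes <= 0) || sum(sizes) != n)
      stop("split_cohort: sizes must be two positive counts summing to nrow")
    n_con <- sizes[1]
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  idx <- sample.int(n, n_con)
  con <- records[sort(idx), , drop = FALSE]
  int <- records[-sort(idx), , drop = FALSE]
  if ("cohort_label" %in% names(records)) {
    con$cohort_label <- "construction"
    int$cohort_label <- "internal"
  }
  rownames(con) <- rownames(int) <- NULL
  list(construction = con, internal = int)
}

#' Pipeline configuration
#'
#' @param mode `"simulate"` (default) or `"load"`.
#' @param cohort_config A [cohort_config()] for the pooled hospital cohort
#'   (simulate mode). Its seed drives all simulation randomness.
#' @param independent_config Optional [cohort_config()] for the external
#'   cohort; by default derived from `cohort_config` with a distinct seed and
#'   an older age range, emulating external validation.
#' @param paths Named character vector (load mode): `pooled` (split into
#'   construction/internal) or `construction`/`internal`, plus optional
#'   `independent`.
#' @param split_ratio Construction:internal allocation ratio (default 4:1).
#' @param split_sizes Optional fixed `c(construction, internal)` sizes; the
#'   default for a 516-record pooled cohort is 416/100 (the reference sizes,
#'   not an exact 4:1); set to NULL to force exact-ratio rounding.
#' @param split_seed Seed for the random allocation.
#' @param grid Breakpoint candidate grid (days).
#' @param threshold_pct Validation decision threshold on corrected HbA1c.
#' @param out_dir Output directory, or NULL to skip writing.
#' @param verbose Print stage progress.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"),
                            cohort_config = glycorr::cohort_config(n_patients = 516),
                            independent_config = NULL,
                            paths = NULL,
                            split_ratio = c(4, 1),
                            split_sizes = if (cohort_config$n_patients == 516)
                              c(416, 100) else NULL,
                            split_seed = cohort_config$seed + 1L,
                            grid = 45:110,
                            threshold_pct = 7.0,
                            out_dir = NULL,
                            verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "load") {
    if (is.null(paths)) stop("pipeline_config: load mode requires paths")
    missing_paths <- paths[!file.exists(paths)]
    if (length(missing_paths))
      stop("pipeline_config: path(s) not found: ",
           paste(missing_paths, collapse = ", "))
  }
  if (is.null(independent_config) && mode == "simulate") {
    cov <- cohort_config$covariate_ranges
    cov$age_years <- c(55, 80)  # older external cohort
    independent_config <- glycorr::cohort_config(
      n_patients = 165,
      seed = (cohort_config$seed + 104729L) %% .Machine$integer.max,
      group_proportions = cohort_config$group_proportions,
      lifespan_ranges = cohort_config$lifespan_ranges,
      hba1c_mean = cohort_config$hba1c_mean,
      hba1c_sd = cohort_config$hba1c_sd,
      hba1c_bounds = cohort_config$hba1c_bounds,
      hgi_noise_sd = cohort_config$hgi_noise_sd,
      generating_models = cohort_config$generating_models,
      complication_or_targets = cohort_config$complication_or_targets,
      baseline_complication_rate = cohort_config$baseline_complication_rate,
      covariate_ranges = cov,
      cohort_label = "independent")
  }
  structure(
    list(mode = mode, cohort_config = cohort_config,
         independent_config = independent_config, paths = paths,
         split_ratio = split_ratio, split_sizes = split_sizes,
         split_seed = as.integer(split_seed), grid = grid,
         threshold_pct = threshold_pct, out_dir = out_dir,
         verbose = verbose),
    class = "pipeline_config"
  )
}

#' Run the full correction-modelling pipeline
#'
#' Stages, in order: obtain cohorts (simulate or load); split the pooled
#' cohort into construction and internal; derive per-patient metrics; detect
#' the HGI-lifespan inflection on the construction cohort; fit SHORT and MID
#' correction models on the construction cohort; apply them to every cohort;
#' validate each cohort (outcome eHbA1c > 7%, predictor corrected HbA1c).
#' Re-running with an identical config reproduces the outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @return List with `cohorts` (metric-augmented data frames), `inflection`
#'   (a `changepoint_result`), `fitted_models` (a [correction_model_set()]),
#'   `reports` (named `validation_report`s), `summary` (one row per cohort),
#'   `proportions` (construction-group shares), `audit` (stage log).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  audit <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    audit <<- c(audit, msg)
    if (config$verbose) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohorts <- stage("acquire", {
    if (config$mode == "simulate") {
      pooled <- simulate_cohort(config$cohort_config)
      note("simulated pooled cohort: n=%d seed=%d", nrow(pooled),
           config$cohort_config$seed)
      sp <- split_cohort(pooled, ratio = config$split_ratio,
                         seed = config$split_seed,
                         sizes = config$split_sizes)
      indep <- simulate_cohort(config$independent_config)
      note("split %d -> %d/%d; simulated independent n=%d",
           nrow(pooled), nrow(sp$construction), nrow(sp$internal),
           nrow(indep))
      list(construction = sp$construction, internal = sp$internal,
           independent = indep)
    } else {
      p <- config$paths
      if ("pooled" %in% names(p)) {
        pooled <- read_cohort(p[["pooled"]])
        sp <- split_cohort(pooled, ratio = config$split_ratio,
                           seed = config$split_seed,
                           sizes = config$split_sizes)
        out <- list(construction = sp$construction, internal = sp$internal)
      } else {
        out <- list(construction = read_cohort(p[["construction"]]),
                    internal = read_cohort(p[["internal"]]))
      }
      if ("independent" %in% names(p))
        out$independent <- read_cohort(p[["independent"]])
      note("loaded cohorts: %s",
           paste(sprintf("%s=%d", names(out), vapply(out, nrow, 1L)),
                 collapse = " "))
      out
    }
  })

  cohorts <- stage("metrics", {
    lapply(cohorts, glycemia_metrics)
  })
  note("derived metrics for %d cohort(s)", length(cohorts))

  con <- cohorts$construction
  inflection <- stage("inflection", {
    grid <- config$grid[config$grid >= min(con$rbc_lifespan_days) &
                          config$grid <= max(con$rbc_lifespan_days)]
    if (!length(grid))
      stop("no breakpoint candidates inside the lifespan range")
    detect_inflection(con$rbc_lifespan_days, con$hgi, grid = grid)
  })
  note("inflection at %g days (material: %s)", inflection$inflection_days,
       inflection$material)

  fitted <- stage("fit", {
    correction_model_set(fit_correction_model(con, "SHORT"),
                         fit_correction_model(con, "MID"))
  })
  note("fitted SHORT (n=%d, R=%.4f) and MID (n=%d, R=%.4f)",
       fitted$SHORT$n, fitted$SHORT$multiple_R,
       fitted$MID$n, fitted$MID$multiple_R)

  cohorts <- stage("apply", {
    lapply(cohorts, function(df) {
      df$hba1c_corrected_pct <- correct_hba1c(df$hba1c_pct,
                                              df$rbc_lifespan_days, fitted)
      df
    })
  })
  # boundary discontinuity of the fitted piecewise model, for the log
  jump66 <- correct_hba1c(7, 66, fitted) - correct_hba1c(7, 66 + 1e-9, fitted)
  jump90 <- correct_hba1c(7, 90 - 1e-9, fitted) - correct_hba1c(7, 90, fitted)
  note("piecewise jumps at 66/90 days (HbA1c 7%%): %+.4f / %+.4f",
       jump66, jump90)

  reports <- stage("validate", {
    lapply(cohorts, validate_cohort, models = fitted,
           threshold_pct = config$threshold_pct)
  })
  for (r in reports)
    note("validated %s: AUC=%.4f (%.4f-%.4f)", r$cohort_label, r$auc,
         r$auc_ci_low, r$auc_ci_high)

  props <- group_proportions(con$group)
  note("construction group shares: %s; <90d pooled %.2f%%",
       paste(sprintf("%s %.2f%%", props$group, props$pct), collapse = ", "),
       attr(props, "below_90_pct"))

  result <- list(cohorts = cohorts, inflection = inflection,
                 fitted_models = fitted, reports = reports,
                 summary = do.call(rbind, lapply(reports, report_row)),
                 proportions = props, audit = audit)

  if (!is.null(config$out_dir)) {
    stage("write", write_pipeline_outputs(result, config))
    note("outputs written to %s", config$out_dir)
    result$audit <- audit
  }
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(config$out_dir, ...)
  for (nm in names(result$cohorts))
    write_cohort(result$cohorts[[nm]], f(paste0(nm, ".csv")))
  write_models(result$fitted_models, f("fitted_models.txt"))
  utils::write.csv(result$summary, f("validation_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$inflection$candidate_profile,
                   f("inflection_profile.csv"), row.names = FALSE)
  report_json <- list(
    seed = config$cohort_config$seed,
    split_seed = config$split_seed,
    inflection_days = result$inflection$inflection_days,
    material_inflection = result$inflection$material,
    proportions = result$proportions,
    below_90_pct = attr(result$proportions, "below_90_pct"),
    reports = lapply(result$reports, function(r)
      r[c("cohort_label", "n", "auc", "auc_ci_low", "auc_ci_high",
          "accuracy", "sensitivity", "specificity", "threshold_pct")])
  )
  jsonlite::write_json(report_json, f("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(result$audit, f("audit.log"))
  invisible(NULL)
}
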