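# HGI-lifespan inflection detection and subgroup correction-model fitting.

#' Detect the inflection of the HGI-lifespan relation
#'
#' Grid search for the breakpoint of a continuous two-segment linear model:
#' for each candidate day c the hinge basis (1, x, max(0, x - c)) is fit by
#' least squares, and the SSE-minimising candidate is returned. Ties (within
#' 1e-9 relative) go to the smallest candidate. When the best two-segment fit
#' improves on a single straight line by less than 1% of its SSE, the result
#' is flagged as showing no material inflection.
#'
#' A restricted cubic spline fit (4 knots at the 0.05/0.35/0.65/0.95
#' quantiles) is returned alongside for plotting; the reported breakpoint
#' always comes from the hinge search, which defines a single reportable day.
#'
#' @param lifespan,hgi Numeric vectors (>= 20 points) of RBC lifespan (days)
#'   and the hemoglobin glycation index (%).
#' @param grid Candidate breakpoints (days); default integer days 45-110.
#'   Must lie inside the lifespan range.
#' @return Object of class `changepoint_result`: `inflection_days`,
#'   `segment_slopes` (pre/post), `sse`, `candidate_profile` (data frame of
#'   candidate vs SSE), `single_line_sse`, `material` (logical), `spline_fit`
#'   (data frame `lifespan`, `fitted` from the RCS).
#' @export
detect_inflection <- function(lifespan, hgi, grid = 45:110) {
  if (length(lifespan) != length(hgi))
    stop("detect_inflection: unequal lengths")
  if (length(lifespan) < 20) stop("detect_inflection: need >= 20 points")
  if (any(!is.finite(lifespan)) || any(!is.finite(hgi)))
    stop("detect_inflection: inputs must be finite")
  grid <- sort(unique(grid))
  if (min(grid) < min(lifespan) || max(grid) > max(lifespan))
    stop("detect_inflection: candidate grid extends outside the data range")

  sse_for <- function(X) {
    fit <- stats::lm.fit(X, hgi)
    sum(fit$residuals^2)
  }
  single_sse <- sse_for(cbind(1, lifespan))
  prof <- vapply(grid, function(c_) {
    sse_for(cbind(1, lifespan, pmax(0, lifespan - c_)))
  }, numeric(1))
  best_sse <- min(prof)
  tol <- 1e-9 * max(best_sse, .Machine$double.eps)
  best <- grid[which(prof <= best_sse + tol)[1]]  # smallest candidate wins

  fit <- stats::lm.fit(cbind(1, lifespan, pmax(0, lifespan - best)), hgi)
  slope_pre <- fit$coefficients[2]
  slope_post <- fit$coefficients[2] + fit$coefficients[3]
  # a single line that already fits to numerical noise leaves no material
  # inflection, whatever the relative SSE ratio says
  tss <- sum((hgi - mean(hgi))^2)
  material <- single_sse > 1e-10 * max(tss, .Machine$double.eps) &&
    (single_sse - best_sse) >= 0.01 * single_sse

  knots <- stats::quantile(lifespan, c(0.05, 0.35, 0.65, 0.95), names = FALSE)
  spline_fitted <- tryCatch({
    B <- rcs_basis(lifespan, knots)
    sfit <- stats::lm.fit(cbind(1, B), hgi)
    as.numeric(cbind(1, B) %*% sfit$coefficients)
  }, error = function(e) rep(NA_real_, length(lifespan)))

  structure(
    list(inflection_days = best,
         segment_slopes = c(pre = unname(slope_pre),
                            post = unname(slope_post)),
         sse = best_sse,
         candidate_profile = data.frame(candidate = grid, sse = prof),
         single_line_sse = single_sse,
         material = material,
         spline_fit = data.frame(lifespan = lifespan,
                                 fitted = spline_fitted)),
    class = "changepoint_result"
  )
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf(
    "<changepoint_result> inflection at %g days (slopes %.4g / %.4g)%s\n",
    x$inflection_days, x$segment_slopes[1], x$segment_slopes[2],
    if (!x$material) " [no material inflection]" else ""))
  invisible(x)
}

# Restricted cubic spline basis (Harrell's parameterisation): k knots give
# k - 1 columns (x plus k - 2 nonlinear terms), linear beyond the end knots.
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("rcs_basis: need at least 3 knots")
  if (any(diff(knots) <= 0)) stop("rcs_basis: knots must be strictly increasing")
  tk <- knots[k]
  tk1 <- knots[k - 1]
  scale2 <- (tk - knots[1])^2
  cub <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (cub(x - tj) - cub(x - tk1) * (tk - tj) / (tk - tk1) +
       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  })
  cbind(x, do.call(cbind, cols))
}

#' Fit a subgroup HbA1c correction model
#'
#' Ordinary least squares of the estimated HbA1c (from AG through the ADAG
#' relation) on RBC lifespan and measured HbA1c with intercept, restricted to
#' the records of one lifespan group. Returns the fitted coefficients, the
#' multiple correlation R = sqrt(R^2), and the overall F test.
#'
#' @param records Patient-record data frame with `hba1c_pct`, `ag_mmol_L`,
#'   `rbc_lifespan_days` (a precomputed `ehba1c_pct` column is used if
#'   present).
#' @param group `"SHORT"` or `"MID"`; records are filtered by
#'   [classify_lifespan()] before fitting. Needs >= 10 records in the group.
#' @return A [correction_model()] with fit diagnostics.
#' @export
fit_correction_model <- function(records, group = c("SHORT", "MID")) {
  group <- match.arg(group)
  grp <- classify_lifespan(records$rbc_lifespan_days)
  sub <- records[grp == group, , drop = FALSE]
  n <- nrow(sub)
  if (n < 10)
    stop("fit_correction_model: need >= 10 records in group ", group,
         " (have ", n, ")")
  y <- if ("ehba1c_pct" %in% names(sub)) sub$ehba1c_pct else
    estimated_hba1c(sub$ag_mmol_L)
  X <- cbind(intercept = 1, lifespan = sub$rbc_lifespan_days,
             hba1c = sub$hba1c_pct)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("fit_correction_model: singular design (constant lifespan or HbA1c)")
  coefs <- qr.coef(qrX, y)
  fitted <- as.numeric(X %*% coefs)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  p <- ncol(X) - 1
  f_stat <- if (rss > 0) (tss - rss) / p / (rss / (n - p - 1)) else Inf
  f_p <- if (is.finite(f_stat))
    stats::pf(f_stat, p, n - p - 1, lower.tail = FALSE) else 0
  correction_model(group,
                   beta_lifespan = coefs[["lifespan"]],
                   beta_hba1c = coefs[["hba1c"]],
                   intercept = coefs[["intercept"]],
                   multiple_R = if (is.na(r2)) NA_real_ else
                     sqrt(max(0, min(1, r2))),
                   f_stat = f_stat, f_pvalue = f_p, n = n)
}
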