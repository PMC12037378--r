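# Rank-based group statistics and 2x2 association measures.
#
# These are authored from the defining formulas (not delegated to stats::)
# so that tests can check them against independent oracles; stats::cor.test,
# stats::kruskal.test and stats::chisq.test appear only in the test suite.

#' Spearman rank correlation with large-sample p-value
#'
#' Average ranks for ties; rho is the Pearson correlation of the ranks; the
#' p-value uses the t approximation `t = rho * sqrt((n-2) / (1-rho^2))` on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_correlation: unequal lengths")
  n <- length(x)
  if (n < 3) stop("spearman_correlation: need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("spearman_correlation: inputs must be finite")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("spearman_correlation: constant input, rho undefined")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Kruskal-Wallis rank-sum test
#'
#' H with tie correction:
#' `H = [12 / (N(N+1)) * sum(R_j^2 / n_j) - 3(N+1)] / [1 - sum(t^3-t)/(N^3-N)]`
#' where `R_j` are group rank sums and `t` runs over tie-group sizes. The
#' p-value is chi-square on k - 1 degrees of freedom. All-identical input
#' returns H = 0, p = 1.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis: need a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("kruskal_wallis: empty group")
  all_x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(all_x))) stop("kruskal_wallis: inputs must be finite")
  N <- length(all_x)
  k <- length(groups)
  if (length(unique(all_x)) == 1)
    return(list(H = 0, p_value = 1, df = k - 1))
  r <- rank(all_x)
  idx <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)
  ties <- table(all_x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / correction
  list(H = H, p_value = stats::pchisq(H, df = k - 1, lower.tail = FALSE),
       df = k - 1)
}

#' Pearson chi-square test of association
#'
#' Chi-square on an r x c count matrix from observed vs expected cell counts
#' under independence, without continuity correction by default; the Yates
#' correction is available for 2x2 tables.
#'
#' @param table Matrix of non-negative counts (at least 2 x 2), or a
#'   [contingency_2x2()].
#' @param yates Apply the Yates continuity correction (2x2 only).
#' @return List with `chi2`, `p_value`, `df`.
#' @export
chi_square_association <- function(table, yates = FALSE) {
  if (inherits(table, "contingency_2x2")) table <- as.matrix(table)
  if (!is.matrix(table) || nrow(table) < 2 || ncol(table) < 2)
    stop("chi_square_association: need an r x c count matrix, r, c >= 2")
  if (any(table < 0) || any(!is.finite(table)))
    stop("chi_square_association: counts must be finite and >= 0")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0))
    stop("chi_square_association: zero marginal in row ",
         paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0))
    stop("chi_square_association: zero marginal in column ",
         paste(which(cs == 0), collapse = ", "))
  expected <- outer(rs, cs) / sum(table)
  dev <- abs(table - expected)
  if (yates) {
    if (!all(dim(table) == c(2, 2)))
      stop("chi_square_association: Yates correction is 2x2 only")
    dev <- pmax(dev - 0.5, 0)
  }
  chi2 <- sum(dev^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       df = df)
}

#' 2x2 contingency table
#'
#' Exposure x outcome counts for odds-ratio and chi-square computations
#' (e.g. exposure = RBC lifespan < 90 days, outcome = complication).
#'
#' @param exposed_cases,exposed_noncases,unexposed_cases,unexposed_noncases
#'   Non-negative counts.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(exposed_cases, exposed_noncases,
                            unexposed_cases, unexposed_noncases) {
  cells <- c(exposed_cases, exposed_noncases, unexposed_cases,
             unexposed_noncases)
  if (any(cells < 0) || any(!is.finite(cells)))
    stop("contingency_2x2: counts must be finite and >= 0")
  if (sum(cells) == 0) stop("contingency_2x2: empty table")
  structure(
    list(exposed_cases = exposed_cases, exposed_noncases = exposed_noncases,
         unexposed_cases = unexposed_cases,
         unexposed_noncases = unexposed_noncases),
    class = "contingency_2x2"
  )
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$exposed_cases, x$unexposed_cases,
           x$exposed_noncases, x$unexposed_noncases),
         nrow = 2,
         dimnames = list(exposure = c("exposed", "unexposed"),
                         outcome = c("case", "noncase")))
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (a*d) / (b*c)` with the log-scale interval
#' `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero
#' the Haldane-Anscombe correction (+0.5 to all cells) is applied and
#' flagged; two zero cells on the same diagonal leave the OR undefined.
#'
#' @param table A [contingency_2x2()].
#' @return List with `odds_ratio`, `ci_low`, `ci_high`,
#'   `haldane_corrected`.
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$exposed_cases
  b <- table$exposed_noncases
  c_ <- table$unexposed_cases
  d <- table$unexposed_noncases
  if ((a == 0 && d == 0) || (b == 0 && c_ == 0))
    stop("odds_ratio: two zero cells on a diagonal, OR undefined")
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(0.975)
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       haldane_corrected = corrected)
}

#' Complication odds ratios for shortened lifespan
#'
#' Convenience wrapper: builds the 2x2 table (exposure = lifespan < 90 days)
#' for each complication flag present in the records and returns the
#' unadjusted odds ratios with Woolf intervals.
#'
#' @param records Patient-record data frame with `rbc_lifespan_days` and at
#'   least one of `cvd_flag`, `neuropathy_flag`, `fundus_flag`.
#' @return Data frame with one row per flag: `flag`, `odds_ratio`,
#'   `ci_low`, `ci_high`.
#' @export
complication_odds <- function(records) {
  flags <- intersect(COHORT_FLAG_COLS, names(records))
  if (!length(flags)) stop("complication_odds: no complication flags present")
  exposed <- records$rbc_lifespan_days < LIFESPAN_NORMAL_MIN
  rows <- lapply(flags, function(f) {
    y <- records[[f]]
    keep <- !is.na(y)
    tab <- contingency_2x2(sum(y[keep] == 1 & exposed[keep]),
                           sum(y[keep] == 0 & exposed[keep]),
                           sum(y[keep] == 1 & !exposed[keep]),
                           sum(y[keep] == 0 & !exposed[keep]))
    o <- odds_ratio(tab)
    data.frame(flag = f, odds_ratio = o$odds_ratio, ci_low = o$ci_low,
               ci_high = o$ci_high, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
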