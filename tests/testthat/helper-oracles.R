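# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Spearman rho as Pearson correlation of average ranks.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Kruskal-Wallis H from the raw definition: normalised variance of group
# mean ranks, with explicit tie correction.
oracle_kw <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  N <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  t <- table(x)
  H / (1 - sum(t^3 - t) / (N^3 - N))
}

# Pearson chi-square by explicit expected-count loops.
oracle_chi2 <- function(tab) {
  total <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / total
    out <- out + (tab[i, j] - e)^2 / e
  }
  out
}

# Woolf CI bounds from the log-variance definition.
oracle_or_ci <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
}

# AUC by exhaustive pairwise comparison with half-credit for ties.
oracle_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Cohort with the derived-metric columns, small and seeded.
make_metric_cohort <- function(n = 500, seed = 99, ...) {
  glycemia_metrics(simulate_cohort(cohort_config(n_patients = n,
                                                 seed = seed, ...)))
}

# Zero-noise cohort on one lifespan stratum: the dependent variable is the
# exact generating model, so OLS must recover it to machine precision.
make_exact_cohort <- function(group = "SHORT", n = 200, seed = 1) {
  set.seed(seed)
  range <- if (group == "SHORT") c(40, 66) else c(67, 89)
  lifespan <- runif(n, range[1], range[2])
  hba1c <- runif(n, 5, 12)
  m <- published_models()[[group]]
  ehba1c <- m$beta_lifespan * lifespan + m$beta_hba1c * hba1c + m$intercept
  data.frame(patient_id = sprintf("X-%04d", seq_len(n)),
             hba1c_pct = hba1c,
             ag_mmol_L = ag_from_ehba1c(ehba1c),
             rbc_lifespan_days = lifespan,
             stringsAsFactors = FALSE)
}
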