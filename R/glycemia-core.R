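# Pure-formula layer: RBC lifespan from CO breath measurements, the ADAG
# average-glucose conversion, the hemoglobin glycation index, lifespan-group
# classification, and the piecewise linear HbA1c correction.

# ADAG regression constants relating average glucose (mmol/L) to HbA1c (%):
# eHbA1c = (AG + 2.5944) / 1.5944.
ADAG_SLOPE <- 1.5944
ADAG_OFFSET <- 2.5944

# mg/dL per mmol/L of glucose
MGDL_PER_MMOL <- 18.016

# Lifespan-group boundaries (days). Groups partition (0, Inf):
# SHORT = (0, 66], MID = (66, 90), NORMAL = [90, Inf). On integer days this
# coincides with the clinical labels <=66 / 67-89 / >=90.
LIFESPAN_SHORT_MAX <- 66
LIFESPAN_NORMAL_MIN <- 90

LIFESPAN_GROUPS <- c("SHORT", "MID", "NORMAL")

#' CO breath sample for RBC lifespan estimation
#'
#' Bundles the measurements of an end-expiratory (alveolar) breath sample used
#' to estimate mean red-blood-cell lifespan from endogenous carbon monoxide.
#' Heme catabolism releases one CO molecule per heme, so the alveolar CO
#' concentration in excess of the atmospheric background, normalised by the
#' circulating hemoglobin mass, is inversely proportional to the RBC turnover
#' rate. All physical constants and volume ratios of the underlying formula
#' are folded into a single calibration constant `k_cal`.
#'
#' @param alveolar_co_ppm CO concentration in end-expiratory breath (ppm).
#' @param ambient_co_ppm Atmospheric background CO (ppm).
#' @param hb_g_per_L Blood hemoglobin concentration (g/L).
#' @param k_cal Calibration constant (days.ppm.L/g). The default 1 is chosen
#'   so that a typical subject (Hb 140 g/L, net alveolar CO 1.4 ppm) has a
#'   lifespan of 100 days.
#' @return An object of class `co_breath_sample`.
#' @examples
#' s <- co_breath_sample(alveolar_co_ppm = 3.0, ambient_co_ppm = 1.6,
#'                       hb_g_per_L = 140)
#' estimate_rbc_lifespan(s)
#' @export
co_breath_sample <- function(alveolar_co_ppm, ambient_co_ppm, hb_g_per_L,
                             k_cal = 1) {
  stopifnot(is.numeric(alveolar_co_ppm), is.numeric(ambient_co_ppm),
            is.numeric(hb_g_per_L), is.numeric(k_cal))
  if (any(!is.finite(c(alveolar_co_ppm, ambient_co_ppm, hb_g_per_L, k_cal))))
    stop("co_breath_sample: all fields must be finite")
  if (any(ambient_co_ppm < 0))
    stop("co_breath_sample: ambient_co_ppm must be >= 0")
  if (any(hb_g_per_L <= 0))
    stop("co_breath_sample: hb_g_per_L must be > 0")
  if (any(k_cal <= 0))
    stop("co_breath_sample: k_cal must be > 0")
  structure(
    list(alveolar_co_ppm = alveolar_co_ppm,
         ambient_co_ppm = ambient_co_ppm,
         hb_g_per_L = hb_g_per_L,
         k_cal = k_cal),
    class = "co_breath_sample"
  )
}

#' Estimate RBC lifespan from a CO breath sample
#'
#' Computes `lifespan = k_cal * [Hb] / (alveolar CO - ambient CO)`. The
#' result is homogeneous of degree +1 in hemoglobin and -1 in net CO: doubling
#' hemoglobin doubles the estimate, doubling net CO halves it.
#'
#' @param sample A [co_breath_sample()].
#' @return Estimated mean RBC lifespan in days (strictly positive).
#' @export
estimate_rbc_lifespan <- function(sample) {
  if (!inherits(sample, "co_breath_sample"))
    stop("estimate_rbc_lifespan: expected a co_breath_sample")
  net_co <- sample$alveolar_co_ppm - sample$ambient_co_ppm
  if (any(net_co <= 0))
    stop("degenerate breath sample: alveolar CO must exceed ambient CO")
  sample$k_cal * sample$hb_g_per_L / net_co
}

#' Estimated HbA1c from average glucose (ADAG relation)
#'
#' Converts average glucose to the estimated HbA1c via the ADAG linear
#' regression, `eHbA1c = (AG + 2.5944) / 1.5944` with AG in mmol/L.
#'
#' @param ag Average glucose over the monitoring window.
#' @param units Either `"mmol/L"` (default, the scale of the ADAG constants)
#'   or `"mg/dL"` (divided by 18.016 before conversion).
#' @return Estimated HbA1c (NGSP %). Strictly increasing in `ag`.
#' @examples
#' estimated_hba1c(8.5664)   # 7.0
#' @export
estimated_hba1c <- function(ag, units = c("mmol/L", "mg/dL")) {
  units <- match.arg(units)
  if (!is.numeric(ag) || any(!is.finite(ag)))
    stop("estimated_hba1c: ag must be finite numeric")
  if (units == "mg/dL") ag <- ag / MGDL_PER_MMOL
  (ag + ADAG_OFFSET) / ADAG_SLOPE
}

#' Average glucose implied by an estimated HbA1c
#'
#' Inverse of [estimated_hba1c()]: `AG = 1.5944 * eHbA1c - 2.5944` (mmol/L).
#' Used by the cohort generator to back-solve AG from a generated eHbA1c.
#'
#' @param ehba1c Estimated HbA1c (%).
#' @return Average glucose (mmol/L).
#' @export
ag_from_ehba1c <- function(ehba1c) {
  if (!is.numeric(ehba1c) || any(!is.finite(ehba1c)))
    stop("ag_from_ehba1c: ehba1c must be finite numeric")
  ADAG_SLOPE * ehba1c - ADAG_OFFSET
}

#' Hemoglobin glycation index
#'
#' `HGI = measured HbA1c - estimated HbA1c`. Negative values indicate that the
#' HbA1c assay underestimates glycemia relative to measured glucose, the
#' signature of a shortened RBC lifespan.
#'
#' @param hba1c_pct Measured HbA1c (%).
#' @param ehba1c_pct Estimated HbA1c (%).
#' @return HGI (%, signed).
#' @export
hgi <- function(hba1c_pct, ehba1c_pct) {
  if (!is.numeric(hba1c_pct) || !is.numeric(ehba1c_pct) ||
      any(!is.finite(hba1c_pct)) || any(!is.finite(ehba1c_pct)))
    stop("hgi: inputs must be finite numeric")
  hba1c_pct - ehba1c_pct
}

#' Classify RBC lifespan into clinical groups
#'
#' SHORT for lifespan <= 66 days, MID for (66, 90), NORMAL for >= 90 days.
#' Fractional lifespans fall in the half-open intervals; on integer days this
#' matches the <=66 / 67-89 / >=90 convention.
#'
#' @param lifespan_days RBC lifespan (days, may be fractional). Vectorised.
#' @return Factor with levels `SHORT`, `MID`, `NORMAL`.
#' @examples
#' classify_lifespan(c(66, 66.5, 89, 90))
#' @export
classify_lifespan <- function(lifespan_days) {
  if (!is.numeric(lifespan_days) || any(!is.finite(lifespan_days)))
    stop("classify_lifespan: lifespan must be finite numeric")
  if (any(lifespan_days <= 0))
    stop("classify_lifespan: lifespan must be > 0")
  lab <- ifelse(lifespan_days <= LIFESPAN_SHORT_MAX, "SHORT",
                ifelse(lifespan_days < LIFESPAN_NORMAL_MIN, "MID", "NORMAL"))
  factor(lab, levels = LIFESPAN_GROUPS)
}

#' Piecewise linear HbA1c correction
#'
#' Applies the lifespan-specific linear correction
#' `HbA1c(c) = beta_lifespan * lifespan + beta_hba1c * HbA1c + intercept`
#' using the SHORT model for lifespans <= 66 days and the MID model for
#' (66, 90) days; measurements with a normal lifespan (>= 90 days) are
#' returned unchanged. The two published equations are discontinuous at the
#' group boundaries; no smoothing is applied.
#'
#' Corrected values are not clamped; results outside the physiological (3,
#' 20)% range raise a warning, not an error.
#'
#' @param hba1c_pct Measured HbA1c (%). Vectorised.
#' @param lifespan_days RBC lifespan (days), same length (or scalar).
#' @param models A [correction_model_set()]; defaults to the published
#'   coefficients ([published_models()]).
#' @return Corrected HbA1c (%).
#' @examples
#' correct_hba1c(7, 60)   # SHORT model
#' correct_hba1c(7, 100)  # unchanged
#' @export
correct_hba1c <- function(hba1c_pct, lifespan_days,
                          models = published_models()) {
  models <- as_correction_model_set(models)
  n <- max(length(hba1c_pct), length(lifespan_days))
  hba1c_pct <- rep_len(hba1c_pct, n)
  lifespan_days <- rep_len(lifespan_days, n)
  grp <- classify_lifespan(lifespan_days)
  out <- hba1c_pct
  for (g in c("SHORT", "MID")) {
    idx <- which(grp == g)
    if (!length(idx)) next
    m <- models[[g]]
    out[idx] <- m$beta_lifespan * lifespan_days[idx] +
      m$beta_hba1c * hba1c_pct[idx] + m$intercept
  }
  oob <- out <= 3 | out >= 20
  if (any(oob))
    warning(sprintf("correct_hba1c: %d corrected value(s) outside (3, 20)%%",
                    sum(oob)))
  out
}

#' Per-patient glycemia metrics
#'
#' Derives estimated HbA1c, HGI, lifespan group and corrected HbA1c for each
#' patient record.
#'
#' @param records A patient-record data frame (see [read_cohort()] for the
#'   column contract): needs `hba1c_pct`, `ag_mmol_L`, `rbc_lifespan_days`.
#' @param models Correction models, default [published_models()].
#' @return `records` with columns `ehba1c_pct`, `hgi`, `group`,
#'   `hba1c_corrected_pct` appended.
#' @export
glycemia_metrics <- function(records, models = published_models()) {
  need <- c("hba1c_pct", "ag_mmol_L", "rbc_lifespan_days")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("glycemia_metrics: missing column(s): ", paste(miss, collapse = ", "))
  records$ehba1c_pct <- estimated_hba1c(records$ag_mmol_L)
  records$hgi <- hgi(records$hba1c_pct, records$ehba1c_pct)
  records$group <- classify_lifespan(records$rbc_lifespan_days)
  records$hba1c_corrected_pct <-
    correct_hba1c(records$hba1c_pct, records$rbc_lifespan_days, models)
  records
}

#' Lifespan-group proportion report
#'
#' Tabulates the share of patients in each lifespan group, plus the pooled
#' fraction with a shortened lifespan (< 90 days).
#'
#' @param group A factor from [classify_lifespan()], or a named count vector
#'   with entries `SHORT`, `MID`, `NORMAL`.
#' @return Data frame with columns `group`, `n`, `pct` (percent, 2 dp) and an
#'   attached attribute `below_90_pct`.
#' @examples
#' group_proportions(c(SHORT = 80, MID = 138, NORMAL = 198))
#' @export
group_proportions <- function(group) {
  if (is.numeric(group)) {
    if (!all(LIFESPAN_GROUPS %in% names(group)))
      stop("group_proportions: counts must be named SHORT, MID, NORMAL")
    counts <- group[LIFESPAN_GROUPS]
  } else {
    counts <- table(factor(group, levels = LIFESPAN_GROUPS))
  }
  n <- sum(counts)
  if (n == 0) stop("group_proportions: empty input")
  pct <- round(100 * as.numeric(counts) / n, 2)
  out <- data.frame(group = LIFESPAN_GROUPS, n = as.numeric(counts),
                    pct = pct, stringsAsFactors = FALSE)
  attr(out, "below_90_pct") <- round(100 * sum(counts[c("SHORT", "MID")]) / n, 2)
  out
}
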