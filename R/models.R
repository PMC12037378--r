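# Correction-model objects and their plain-text serialization.

#' Construct a lifespan correction model
#'
#' A linear model `HbA1c(c) = beta_lifespan * lifespan + beta_hba1c * HbA1c +
#' intercept` valid on one lifespan group.
#'
#' @param group `"SHORT"` (lifespan <= 66 d) or `"MID"` (67-89 d).
#' @param beta_lifespan Lifespan coefficient (% per day).
#' @param beta_hba1c Measured-HbA1c coefficient (dimensionless).
#' @param intercept Intercept (%).
#' @param multiple_R Multiple correlation coefficient in [0, 1], or NA.
#' @param f_stat,f_pvalue Overall regression F test, or NA.
#' @param n Number of records used in the fit, or NA.
#' @return Object of class `correction_model`.
#' @export
correction_model <- function(group, beta_lifespan, beta_hba1c, intercept,
                             multiple_R = NA_real_, f_stat = NA_real_,
                             f_pvalue = NA_real_, n = NA_integer_) {
  group <- match.arg(group, c("SHORT", "MID"))
  stopifnot(is.numeric(beta_lifespan), is.numeric(beta_hba1c),
            is.numeric(intercept))
  if (!is.na(multiple_R) && (multiple_R < 0 || multiple_R > 1))
    stop("correction_model: multiple_R must be in [0, 1]")
  structure(
    list(group = group,
         beta_lifespan = as.numeric(beta_lifespan),
         beta_hba1c = as.numeric(beta_hba1c),
         intercept = as.numeric(intercept),
         multiple_R = as.numeric(multiple_R),
         f_stat = as.numeric(f_stat),
         f_pvalue = as.numeric(f_pvalue),
         n = n),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model %s> HbA1c(c) = %+g*lifespan %+g*HbA1c %+g  (R = %s)\n",
    x$group, x$beta_lifespan, x$beta_hba1c, x$intercept,
    ifelse(is.na(x$multiple_R), "NA", format(x$multiple_R, digits = 4))))
  invisible(x)
}

#' Bundle SHORT and MID correction models
#'
#' @param short,mid [correction_model()] objects for the respective groups.
#' @return A named list of class `correction_model_set`.
#' @export
correction_model_set <- function(short, mid) {
  if (!inherits(short, "correction_model") || short$group != "SHORT")
    stop("correction_model_set: 'short' must be a SHORT correction_model")
  if (!inherits(mid, "correction_model") || mid$group != "MID")
    stop("correction_model_set: 'mid' must be a MID correction_model")
  structure(list(SHORT = short, MID = mid), class = "correction_model_set")
}

as_correction_model_set <- function(models) {
  if (inherits(models, "correction_model_set")) return(models)
  if (is.list(models) && all(c("SHORT", "MID") %in% names(models)))
    return(correction_model_set(models$SHORT, models$MID))
  stop("correct_hba1c: need one correction model per SHORT and MID group")
}

#' Published correction coefficients
#'
#' The reference piecewise correction: for lifespan <= 66 days
#' `HbA1c(c) = -0.05629*lifespan + 1.127*HbA1c + 3.178` (R = 0.7360), and for
#' 67-89 days `HbA1c(c) = -0.004772*lifespan + 0.7569*HbA1c + 2.394`
#' (R = 0.7344).
#'
#' @return A [correction_model_set()].
#' @export
published_models <- function() {
  correction_model_set(
    correction_model("SHORT", -0.05629, 1.127, 3.178, multiple_R = 0.7360),
    correction_model("MID", -0.004772, 0.7569, 2.394, multiple_R = 0.7344)
  )
}

#' Write correction models to a plain-text key-value file
#'
#' Versioned `key = value` format, one coefficient per line, so alternative
#' coefficient sets can be swapped in without code changes.
#'
#' @param models A [correction_model_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  models <- as_correction_model_set(models)
  lines <- c("format_version = 1")
  for (g in c("SHORT", "MID")) {
    m <- models[[g]]
    p <- tolower(g)
    lines <- c(lines,
      sprintf("%s.beta_lifespan = %.17g", p, m$beta_lifespan),
      sprintf("%s.beta_hba1c = %.17g", p, m$beta_hba1c),
      sprintf("%s.intercept = %.17g", p, m$intercept),
      sprintf("%s.multiple_R = %.17g", p, m$multiple_R))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read correction models from a key-value file
#'
#' @param path File written by [write_models()] (or hand-edited in the same
#'   format; `#` starts a comment).
#' @return A [correction_model_set()].
#' @export
read_models <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("read_models: malformed line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  get_num <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("read_models: missing key '", key, "'")
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v) && vals[i] != "NA")
      stop("read_models: non-numeric value for '", key, "'")
    v
  }
  mk <- function(g) {
    p <- tolower(g)
    correction_model(g,
      beta_lifespan = get_num(paste0(p, ".beta_lifespan")),
      beta_hba1c = get_num(paste0(p, ".beta_hba1c")),
      intercept = get_num(paste0(p, ".intercept")),
      multiple_R = get_num(paste0(p, ".multiple_R")))
  }
  correction_model_set(mk("SHORT"), mk("MID"))
}
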