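# MetS risk-factor screening.
#
# Boundary semantics follow the clinical rule set exactly: >= for waist,
# triglycerides and blood pressure; strict < for HDL; strict > for glucose.

#' Default MetS risk-factor thresholds
#'
#' The screening thresholds used for risk flagging, fully configurable:
#' excessive waist circumference >= 88 cm (women) / >= 102 cm (men);
#' elevated fasting triglycerides >= 1.7 mmol/L; reduced HDL < 1.03 mmol/L
#' (men) / < 1.29 mmol/L (women); high blood pressure, systolic >= 130 or
#' diastolic >= 85 mm Hg; elevated fasting glucose > 5.6 mmol/L. At-risk
#' status requires the waist criterion plus at least `at_risk_min_secondary`
#' secondary factors; MetS (IDF-style central obesity rule) requires waist
#' plus at least `mets_min_secondary`.
#'
#' @return A named list of thresholds.
#' @export
default_risk_rules <- function() {
  list(
    waist = c(F = 88, M = 102),
    triglycerides = 1.7,
    hdl = c(M = 1.03, F = 1.29),
    sbp = 130,
    dbp = 85,
    glucose = 5.6,
    at_risk_min_secondary = 1L,
    mets_min_secondary = 2L
  )
}

secondary_flags <- c("tg_high", "hdl_low", "bp_high", "glucose_high")

#' Flag MetS risk factors
#'
#' Evaluates the five risk-factor indicators for each participant-visit
#' row. Screening requires complete panels: any missing value needed by a
#' rule is an error, never silently skipped.
#'
#' @param visits Data frame with columns `sex` (`"M"`/`"F"`), `waist`,
#'   `triglycerides`, `hdl`, `sbp`, `dbp`, `glucose`; `participant_id` and
#'   `week` are carried through when present.
#' @param rules Threshold list, see [default_risk_rules()].
#' @return Tibble with logical columns `waist_excessive`, `tg_high`,
#'   `hdl_low`, `bp_high`, `glucose_high` and integer `n_secondary`
#'   (count of true secondary flags, 0-4).
#' @export
#' @examples
#' flag_risk_factors(data.frame(sex = "F", waist = 88, triglycerides = 1.69,
#'                              hdl = 1.29, sbp = 129, dbp = 84, glucose = 5.6))
flag_risk_factors <- function(visits, rules = default_risk_rules()) {
  visits <- tibble::as_tibble(visits)
  need <- c("sex", "waist", "triglycerides", "hdl", "sbp", "dbp", "glucose")
  miss <- setdiff(need, names(visits))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(visits$sex %in% c("M", "F"))) abort("sex must be 'M' or 'F'")
  vals <- visits[setdiff(need, "sex")]
  if (anyNA(vals)) abort("screening requires complete panels; missing values found")

  flags <- tibble::tibble(
    waist_excessive = visits$waist >= unname(rules$waist[visits$sex]),
    tg_high = visits$triglycerides >= rules$triglycerides,
    hdl_low = visits$hdl < unname(rules$hdl[visits$sex]),
    bp_high = visits$sbp >= rules$sbp | visits$dbp >= rules$dbp,
    glucose_high = visits$glucose > rules$glucose
  )
  flags$n_secondary <- as.integer(rowSums(flags[secondary_flags]))
  id_cols <- intersect(c("participant_id", "week"), names(visits))
  dplyr::bind_cols(visits[id_cols], flags)
}

validate_flags <- function(flags) {
  need <- c("waist_excessive", secondary_flags, "n_secondary")
  miss <- setdiff(need, names(flags))
  if (length(miss)) abort(paste("missing flag columns:", paste(miss, collapse = ", ")))
  if (!all(flags$n_secondary ==
           rowSums(flags[secondary_flags]))) {
    abort("n_secondary inconsistent with secondary flags")
  }
  invisible(flags)
}

#' Classify at-risk-of-MetS status
#'
#' At risk of MetS: excessive waist circumference combined with at least one
#' secondary risk factor (the study inclusion rule).
#'
#' @param flags Tibble from [flag_risk_factors()].
#' @param rules Threshold list, see [default_risk_rules()].
#' @return Logical vector.
#' @export
classify_at_risk <- function(flags, rules = default_risk_rules()) {
  validate_flags(flags)
  flags$waist_excessive & flags$n_secondary >= rules$at_risk_min_secondary
}

#' Classify manifest MetS (IDF-style rule)
#'
#' MetS: central obesity (excessive waist) plus at least two secondary risk
#' factors, evaluated with this package's threshold table. Used to select
#' the MetS reference group for the health-space model.
#'
#' @inheritParams classify_at_risk
#' @return Logical vector.
#' @export
classify_mets <- function(flags, rules = default_risk_rules()) {
  validate_flags(flags)
  flags$waist_excessive & flags$n_secondary >= rules$mets_min_secondary
}

#' Average duplicate readings
#'
#' Glucose and blood pressure are measured twice per visit; the arithmetic
#' mean of the two readings is the value of record.
#'
#' @param x1,x2 Paired numeric readings (no missing values).
#' @return Element-wise mean.
#' @export
#' @examples
#' average_duplicates(130, 134)  # 132
average_duplicates <- function(x1, x2) {
  if (anyNA(x1) || anyNA(x2)) abort("both duplicate readings must be present")
  if (any(x1 < 0) || any(x2 < 0)) abort("readings must be >= 0")
  (x1 + x2) / 2
}

#' HOMA-IR configuration
#'
#' The insulin-resistance index here is computed from fasting glucose and
#' C-peptide. The default closed form is
#' `glucose * (c_peptide * cpep_to_insulin) / denominator`, i.e. the
#' classical HOMA1-IR expression with C-peptide converted to an
#' insulin-equivalent concentration. The conversion factor is an explicit,
#' configurable assumption (C-peptide-based HOMA variants are not uniquely
#' standardized); pass `fun` to substitute any other closed form.
#'
#' @param cpep_to_insulin Insulin-equivalent (uU/mL) per nmol/L C-peptide.
#' @param denominator HOMA normalization constant (default 22.5).
#' @param fun Optional `function(glucose, c_peptide)` overriding the default
#'   form entirely.
#' @return A config list for [homa_ir()].
#' @export
homa_config <- function(cpep_to_insulin = 20, denominator = 22.5, fun = NULL) {
  list(cpep_to_insulin = cpep_to_insulin, denominator = denominator, fun = fun)
}

#' HOMA-IR from glucose and C-peptide
#'
#' @param glucose Fasting glucose, mmol/L (> 0).
#' @param c_peptide Fasting C-peptide, nmol/L (> 0).
#' @param config See [homa_config()].
#' @return Numeric HOMA-IR values.
#' @export
#' @examples
#' homa_ir(5.6, 0.5)
homa_ir <- function(glucose, c_peptide, config = homa_config()) {
  if (any(!is.finite(glucose)) || any(!is.finite(c_peptide)) ||
      any(glucose <= 0) || any(c_peptide <= 0)) {
    abort("glucose and C-peptide must be positive")
  }
  if (!is.null(config$fun)) return(config$fun(glucose, c_peptide))
  glucose * (c_peptide * config$cpep_to_insulin) / config$denominator
}

#' Motivation-to-change check
#'
#' Mean of the three 7-point intention-to-change items; a mean of at least
#' `cutoff` counts as motivated (screening inclusion rule).
#'
#' @param items Numeric vector (or matrix, items in columns) of Likert
#'   scores 1-7.
#' @param cutoff Minimum mean (default 5).
#' @return Logical.
#' @export
is_motivated <- function(items, cutoff = 5) {
  if (is.matrix(items)) rowMeans(items) >= cutoff else mean(items) >= cutoff
}
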