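#' Published cohort summary tables
#'
#' Summary statistics (means and SDs) of a 16-week one-group pretest-posttest
#' personalized-nutrition intervention in adults at risk of metabolic
#' syndrome, together with the two NHANES-derived reference groups used to
#' anchor the health-space score. These printed cohort-level values are the
#' package's canonical description of the study conditions: the synthetic
#' cohort generator draws its default specifications from them, and the
#' week-16 change scores of record are plain arithmetic on them.
#'
#' @details Four tables are returned:
#' \describe{
#'   \item{cohorts}{Per-group demographics and metabolic panel: columns
#'     `group` (`"intervention"`, `"healthy-reference"`, `"mets-reference"`),
#'     `feature`, `mean`, `sd`. Units: age years, BMI kg/m2, waist cm,
#'     lipids/glucose mmol/L, C-peptide nmol/L, blood pressure mm Hg.}
#'   \item{cohort_info}{Per-group sample size and male proportion.}
#'   \item{diet}{DHDI category scores (1-10), total DHDI (8-80) and blood
#'     carotenoids (umol/L) at weeks 0/8/16, with the number of participants
#'     whose behavior-change strategy included the category
#'     (`n_strategy`, of 34; `NA` for outcomes measured in everyone).}
#'   \item{metabolic}{Metabolic outcomes and the health score at weeks
#'     0/8/16.}
#'   \item{likert}{Self-perceived health items (7-point Likert) at weeks 0
#'     and 16.}
#' }
#'
#' @return A named list of tibbles (see Details).
#' @export
#' @examples
#' tabs <- study_summary_tables()
#' summary_change(tabs$diet, "dhdi_total")   # +4.3
study_summary_tables <- function() {
  cohorts <- tibble::tribble(
    ~feature,            ~intervention_mean, ~intervention_sd, ~healthy_mean, ~healthy_sd, ~mets_mean, ~mets_sd,
    "age",               61,    8.2,   57.6,  16.2,  54,    21.0,
    "bmi",               29.9,  4.18,  21.3,  1.88,  31.1,  5.68,
    "waist",             102,   11.4,  83.2,  4.68,  105,   10.8,
    "total_cholesterol", 6.23,  0.78,  5.32,  1.10,  4.77,  1.02,
    "hdl",               1.14,  0.27,  1.49,  0.37,  1.01,  0.13,
    "ldl",               4.34,  0.74,  3.12,  1.02,  2.73,  0.99,
    "triglycerides",     1.67,  0.85,  1.57,  0.52,  2.25,  0.95,
    "glucose",           5.61,  0.65,  5.33,  0.70,  7.07,  3.08,
    "c_peptide",         0.52,  0.33,  0.75,  0.40,  1.46,  0.90,
    "sbp",               135,   18.0,  138,   18.5,  128,   21.5,
    "dbp",               78.6,  9.54,  77.7,  14.0,  67.4,  18.6
  )
  cohorts <- tidyr::pivot_longer(
    cohorts, -"feature",
    names_to = c("group", ".value"), names_pattern = "(.*)_(mean|sd)"
  )
  cohorts$group <- c(
    intervention = "intervention",
    healthy = "healthy-reference",
    mets = "mets-reference"
  )[cohorts$group]

  cohort_info <- tibble::tibble(
    group = c("intervention", "healthy-reference", "mets-reference"),
    n = c(34L, 10L, 41L),
    male_prop = c(9 / 34, 5 / 10, 19 / 41)
  )

  diet <- tibble::tribble(
    ~outcome,          ~n_strategy, ~mean_wk0, ~sd_wk0, ~mean_wk8, ~sd_wk8, ~mean_wk16, ~sd_wk16,
    "vegetables",      31L,  6.6,  2.9,  7.5,  3.0,  7.1,  3.3,
    "fruit",           9L,   5.8,  3.3,  8.2,  2.0,  8.4,  2.0,
    "oils_and_fats",   21L,  3.7,  3.9,  3.6,  4.1,  3.5,  3.8,
    "fish",            12L,  6.6,  3.2,  7.5,  2.6,  8.6,  1.9,
    "wholegrain",      19L,  6.3,  2.5,  7.7,  2.8,  7.9,  2.8,
    "dairy",           14L,  3.1,  2.6,  3.8,  3.1,  4.1,  2.7,
    "nuts",            20L,  6.2,  3.3,  7.0,  2.6,  8.4,  2.5,
    "sugar_beverages", 3L,   1.9,  1.8,  5.5,  5.0,  6.6,  2.8,
    "dhdi_total",      NA,   52.9, 13.1, 56.5, 11.3, 57.2, 11.5,
    "carotenoids",     NA,   1.21, 0.43, 1.39, 0.46, 1.42, 0.56
  )

  metabolic <- tibble::tribble(
    ~outcome,            ~mean_wk0, ~sd_wk0, ~mean_wk8, ~sd_wk8, ~mean_wk16, ~sd_wk16,
    "glucose",           5.61, 0.67, 5.63, 0.64, 5.84, 0.63,
    "c_peptide",         0.52, 0.32, 0.52, 0.23, 0.43, 0.16,
    "triglycerides",     1.67, 0.86, 1.43, 0.60, 1.39, 0.55,
    "total_cholesterol", 6.23, 0.78, 5.91, 0.84, 5.90, 0.86,
    "hdl",               1.14, 0.28, 1.09, 0.28, 1.44, 0.36,
    "ldl",               4.34, 0.74, 4.18, 0.79, 3.87, 0.78,
    "sbp",               135,  18.2, 133,  13.7, 132,  17.1,
    "dbp",               78.6, 9.60, 80.3, 8.93, 79.6, 9.77,
    "bmi",               29.9, 3.94, 29.4, 3.60, 29.2, 3.66,
    "waist",             102,  11.5, 100,  9.43, 99.4, 8.86,
    "health_score",      1.30, 0.31, 1.23, 0.30, 1.57, 0.32
  )

  likert <- tibble::tribble(
    ~outcome,                ~mean_wk0, ~sd_wk0, ~mean_wk16, ~sd_wk16,
    "sp_health",             4.68, 1.07, 5.35, 1.10,
    "sp_diet_healthiness",   4.50, 1.05, 5.56, 0.96,
    "sp_diet_satisfaction",  4.35, 1.39, 5.29, 1.14
  )

  list(
    cohorts = cohorts, cohort_info = cohort_info,
    diet = diet, metabolic = metabolic, likert = likert
  )
}

#' Change score from a summary table
#'
#' Week-to-week difference of printed means for one outcome in a summary
#' table as returned by [study_summary_tables()].
#'
#' @param table A tibble with an `outcome` column and `mean_wk<w>` columns.
#' @param outcome Outcome name (one row of `table`).
#' @param from,to Visit weeks (default 0 to 16).
#' @return The signed mean change `to` minus `from` (a length-1 numeric).
#' @export
#' @examples
#' summary_change(study_summary_tables()$metabolic, "glucose")  # +0.23
summary_change <- function(table, outcome, from = 0, to = 16) {
  row <- table[table$outcome == outcome, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(paste0("outcome '", outcome, "' not found in summary table"))
  }
  cols <- paste0("mean_wk", c(from, to))
  if (!all(cols %in% names(row))) {
    abort(paste0("weeks ", from, "/", to, " not present in summary table"))
  }
  as.numeric(row[[cols[2]]] - row[[cols[1]]])
}
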