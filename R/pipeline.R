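# End-to-end study orchestration on synthetic data:
# simulate -> screen -> diet scores -> health space -> advice -> strategies
# -> longitudinal evaluation, on the week 0/8/16 schedule (advice at weeks
# 0 and 8, health score at weeks 0 and 16).

#' Study run configuration
#'
#' Bundles every tunable of the pipeline: the seed, cohort sizes, visit
#' schedule, threshold tables and synthetic specifications. All stage
#' outputs are pure functions of this configuration, so two runs with the
#' same configuration are identical.
#'
#' @param seed Master seed; per-stage seeds are small fixed offsets of it.
#' @param n_participants Intervention cohort size (default 34).
#' @param n_reference_pool Named sizes of the raw reference pools to draw
#'   before selection.
#' @param n_top_healthy Healthy-reference size after rank aggregation
#'   (default 10).
#' @param weeks Measurement weeks.
#' @param advice_weeks Weeks at which stage-1 advice is generated.
#' @param health_score_weeks Weeks at which the health score is computed.
#' @param likert_weeks Weeks of the self-perceived-health items.
#' @param min_category_n Minimum per-category strategy subset size for the
#'   mixed-model analysis; smaller categories are reported without
#'   statistics (as the study does for sugar-containing beverages).
#' @param dropout_n Complete-record dropouts after week 0.
#' @param risk_rules,advice_rules Threshold tables (see
#'   [default_risk_rules()], [default_advice_rules()]).
#' @param hs_random Random-effect structure of the health-space model.
#' @param cohort_specs Optional list overriding the three
#'   [default_cohort_spec()]s (`intervention`, `healthy`, `mets`).
#' @param trajectory Optional [trajectory_spec()] override.
#' @return A list of class `run_config`.
#' @export
study_config <- function(seed = 1,
                         n_participants = 34,
                         n_reference_pool = c(healthy = 1200, mets = 400),
                         n_top_healthy = 10,
                         weeks = c(0, 8, 16),
                         advice_weeks = c(0, 8),
                         health_score_weeks = c(0, 16),
                         likert_weeks = c(0, 16),
                         min_category_n = 5,
                         dropout_n = 0,
                         risk_rules = default_risk_rules(),
                         advice_rules = default_advice_rules(),
                         hs_random = "slopes",
                         cohort_specs = NULL,
                         trajectory = NULL) {
  if (is.null(cohort_specs)) {
    cohort_specs <- list(
      intervention = default_cohort_spec("intervention"),
      healthy = default_cohort_spec("healthy-reference"),
      mets = default_cohort_spec("mets-reference")
    )
  }
  if (is.null(trajectory)) {
    trajectory <- default_trajectory_spec(dropout_n = dropout_n)
  }
  structure(
    list(seed = as.integer(seed), n_participants = n_participants,
         n_reference_pool = n_reference_pool, n_top_healthy = n_top_healthy,
         weeks = weeks, advice_weeks = advice_weeks,
         health_score_weeks = health_score_weeks,
         likert_weeks = likert_weeks, min_category_n = min_category_n,
         risk_rules = risk_rules, advice_rules = advice_rules,
         hs_random = hs_random, cohort_specs = cohort_specs,
         trajectory = trajectory),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

profile_from_visit <- function(visit_row) {
  pr <- unlist(visit_row[dhdi_categories])
  if (!is.na(visit_row[["carotenoids"]])) {
    pr <- c(pr, carotenoids = visit_row[["carotenoids"]])
  }
  pr
}

summarize_weeks <- function(visits, outcome, weeks) {
  purrr::map_dfr(weeks, function(w) {
    v <- visits[[outcome]][visits$week == w]
    v <- v[!is.na(v)]
    tibble::tibble(week = w, n = length(v), mean = mean(v), sd = sd(v))
  })
}

#' Run the full study pipeline on synthetic data
#'
#' Executes the complete workflow: generates the reference pools and the
#' longitudinal intervention cohort, screens week-0 panels for risk flags,
#' selects the two reference groups (rank aggregation for healthy, MetS
#' rule for the other), fits the health-space model and scores the cohort
#' at weeks 0 and 16, produces stage-1 advice plans at weeks 0 and 8,
#' attaches the generated behavior-change strategies, and evaluates every
#' outcome with the study's statistics (per-category strategy subsetting,
#' linear mixed models with outlier rule and BH post hoc contrasts, ordinal
#' mixed models for the Likert items).
#'
#' @param config A [study_config()].
#' @return Object of class `study_report`: per-stage outputs plus a
#'   provenance block (seed, config hash, package version). Identical
#'   configurations produce identical reports.
#' @export
run_study <- function(config = study_config()) {
  seed <- config$seed

  healthy_pool <- stage("simulate-healthy-pool",
    generate_reference_pool(config$cohort_specs$healthy,
                            config$n_reference_pool[["healthy"]], seed + 1L))
  mets_pool <- stage("simulate-mets-pool",
    generate_reference_pool(config$cohort_specs$mets,
                            config$n_reference_pool[["mets"]], seed + 2L))
  cohort <- stage("simulate-cohort",
    generate_intervention_cohort(config$cohort_specs$intervention,
                                 config$trajectory,
                                 config$n_participants, seed + 3L))
  visits <- cohort$visits

  wk0 <- visits[visits$week == 0, ]
  flags <- stage("screen", flag_risk_factors(wk0, config$risk_rules))
  screening <- dplyr::mutate(
    flags,
    at_risk = classify_at_risk(flags, config$risk_rules),
    mets = classify_mets(flags, config$risk_rules)
  )

  healthy_ref <- stage("select-healthy-reference",
    select_healthy_reference(healthy_pool, config$n_top_healthy,
                             rules = config$risk_rules))
  mets_ref <- stage("select-mets-reference",
    select_mets_reference(mets_pool, config$risk_rules))
  hs_model <- stage("fit-health-space",
    fit_health_space(healthy_ref, mets_ref, random = config$hs_random))

  score_rows <- visits[visits$week %in% config$health_score_weeks, ]
  scores <- stage("predict-health-score", predict_score(hs_model, score_rows))
  visits <- dplyr::left_join(
    visits, dplyr::rename(scores, health_score = "score"),
    by = c("participant_id", "week")
  )

  advice <- stage("advise", {
    purrr::map_dfr(config$advice_weeks, function(w) {
      rows <- visits[visits$week == w, ]
      wflags <- flag_risk_factors(rows, config$risk_rules)
      purrr::map_dfr(seq_len(nrow(rows)), function(i) {
        plan <- advise(profile_from_visit(rows[i, ]), wflags[i, ],
                       config$advice_rules)
        if (nrow(plan) == 0) return(NULL)
        dplyr::bind_cols(
          tibble::tibble(participant_id = rows$participant_id[i],
                         advice_week = w),
          tibble::as_tibble(plan)
        )
      })
    })
  })

  strategies <- cohort$strategies

  evaluation <- stage("evaluate", {
    diet_res <- purrr::map(setNames(nm = dhdi_categories), function(cat) {
      long <- visits[c("participant_id", "week")]
      long$value <- visits[[cat]]
      long <- subset_by_strategy(long, strategies, cat)
      n_cat <- attr(long, "n_strategy")
      if (n_cat < config$min_category_n) {
        return(list(n_strategy = n_cat, result = NULL))
      }
      list(n_strategy = n_cat, result = fit_time_mixed_model(long))
    })
    whole <- function(outcome) {
      long <- visits[c("participant_id", "week")]
      long$value <- visits[[outcome]]
      fit_time_mixed_model(long)
    }
    metab_outcomes <- c("glucose", "c_peptide", "triglycerides",
                        "total_cholesterol", "hdl", "ldl", "sbp", "dbp",
                        "bmi", "waist", "health_score")
    likert_outcomes <- c("sp_health", "sp_diet_healthiness",
                         "sp_diet_satisfaction")
    list(
      diet_categories = diet_res,
      dhdi_total = whole("dhdi_total"),
      carotenoids = whole("carotenoids"),
      metabolic = purrr::map(setNames(nm = metab_outcomes), whole),
      likert = purrr::map(setNames(nm = likert_outcomes), function(o) {
        long <- visits[c("participant_id", "week")]
        long$value <- visits[[o]]
        fit_ordinal_mixed(long[!is.na(long$value), ])
      })
    )
  })

  tables <- stage("report-tables", {
    diet_tbl <- purrr::map_dfr(c(dhdi_categories, "dhdi_total", "carotenoids"),
      function(o) {
        s <- summarize_weeks(visits, o, config$weeks)
        res <- if (o %in% dhdi_categories) evaluation$diet_categories[[o]]$result
               else evaluation[[o]]
        tibble::tibble(
          outcome = o,
          n_strategy = if (o %in% dhdi_categories)
            evaluation$diet_categories[[o]]$n_strategy else NA_integer_,
          mean_wk0 = s$mean[s$week == 0], mean_wk8 = s$mean[s$week == 8],
          mean_wk16 = s$mean[s$week == 16],
          p_time = if (is.null(res)) NA_real_ else res$p_overall
        )
      })
    metab_tbl <- purrr::map_dfr(names(evaluation$metabolic), function(o) {
      s <- summarize_weeks(visits, o, config$weeks)
      tibble::tibble(
        outcome = o,
        mean_wk0 = s$mean[s$week == 0], mean_wk8 = s$mean[s$week == 8],
        mean_wk16 = s$mean[s$week == 16],
        p_time = evaluation$metabolic[[o]]$p_overall
      )
    })
    likert_tbl <- purrr::map_dfr(names(evaluation$likert), function(o) {
      s <- summarize_weeks(visits, o, config$likert_weeks)
      tibble::tibble(
        outcome = o,
        mean_wk0 = s$mean[s$week == 0],
        mean_wk16 = s$mean[s$week == 16],
        p_time = evaluation$likert[[o]]$p_overall
      )
    })
    list(diet = diet_tbl, metabolic = metab_tbl, likert = likert_tbl)
  })

  structure(
    list(
      visits = visits, strategies = strategies, screening = screening,
      healthy_reference = healthy_ref, mets_reference = mets_ref,
      health_space = hs_model, health_scores = scores, advice = advice,
      evaluation = evaluation, tables = tables,
      provenance = list(
        seed = seed,
        config_hash = rlang::hash(config),
        package = as.character(utils::packageVersion("metspace"))
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed ", x$provenance$seed, ", ",
      dplyr::n_distinct(x$visits$participant_id), " participants\n", sep = "")
  cat("\nDiet quality (means by week, overall time-effect P):\n")
  print(x$tables$diet, n = Inf)
  cat("\nMetabolic health:\n")
  print(x$tables$metabolic, n = Inf)
  cat("\nSelf-perceived health:\n")
  print(x$tables$likert, n = Inf)
  invisible(x)
}
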