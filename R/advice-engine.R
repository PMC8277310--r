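# Stage-1 automated dietary advice.
#
# Two passes: (1) per food category, is diet quality / nutrient status
# sufficient? (2) do present metabolic abnormalities call for emphasis on
# particular categories? Every advised category carries machine-checkable
# reason provenance, so a plan can be audited and regenerated from its own
# triggers.

#' Default advice rule set
#'
#' The configurable rules driving the stage-1 advice algorithm. The
#' published system's exact cut-off levels and abnormality-to-category
#' mapping are not disclosed, so these defaults are explicit, editable
#' assumptions: a DHDI category is "sufficient" at a score of
#' `dhdi_cutoff` (default 8 of 10, approximate guideline adherence) or
#' more; blood carotenoids below `carotenoid_cutoff` (default 1.0 umol/L,
#' near the cohort baseline mean of 1.21) mark fruit and vegetable status
#' insufficient; each risk flag maps to the food categories with reported
#' evidence for the corresponding abnormality (fish/oils for lipids, nuts
#' for HDL, wholegrain and sugary-drink moderation for glycemia,
#' vegetables/dairy for blood pressure, energy-dense categories for central
#' obesity). Results that depend on these rules are config-dependent.
#'
#' @param dhdi_cutoffs Named numeric (per category) or single score in
#'   `[1, 10]`; scores strictly below the cut-off trigger advice.
#' @param carotenoid_cutoff umol/L below which fruit/vegetable status is
#'   insufficient.
#' @param flag_map Named list: risk flag -> character vector of categories.
#' @param max_categories Optional cap on plan size (keeps the first
#'   categories in canonical order).
#' @return A list of class `advice_rules`.
#' @export
default_advice_rules <- function(dhdi_cutoffs = 8,
                                 carotenoid_cutoff = 1.0,
                                 flag_map = list(
                                   tg_high = c("fish", "sugar_beverages", "oils_and_fats"),
                                   hdl_low = c("fish", "nuts", "oils_and_fats"),
                                   glucose_high = c("wholegrain", "sugar_beverages"),
                                   bp_high = c("vegetables", "dairy"),
                                   waist_excessive = c("sugar_beverages", "oils_and_fats", "nuts")
                                 ),
                                 max_categories = NULL) {
  if (length(dhdi_cutoffs) == 1 && is.null(names(dhdi_cutoffs))) {
    dhdi_cutoffs <- setNames(rep(dhdi_cutoffs, 8), dhdi_categories)
  }
  if (!setequal(names(dhdi_cutoffs), dhdi_categories)) {
    abort("dhdi_cutoffs must cover exactly the 8 DHDI categories")
  }
  if (any(dhdi_cutoffs < 1 | dhdi_cutoffs > 10)) {
    abort("cut-offs must lie in the score range [1, 10]")
  }
  bad <- setdiff(unlist(flag_map), dhdi_categories)
  if (length(bad)) abort(paste("unknown categories in flag_map:",
                               paste(bad, collapse = ", ")))
  structure(
    list(dhdi_cutoffs = dhdi_cutoffs[dhdi_categories],
         carotenoid_cutoff = carotenoid_cutoff,
         flag_map = flag_map, max_categories = max_categories),
    class = "advice_rules"
  )
}

empty_triggers <- function() {
  tibble::tibble(category = character(), reason = character(),
                 trigger = character(), value = numeric())
}

#' Evaluate diet sufficiency per food category
#'
#' Pass 1 of the advice algorithm: a category is insufficient when its DHDI
#' score is below its cut-off, and fruit/vegetables are additionally
#' insufficient when blood carotenoids (if measured) fall below the
#' biomarker cut-off.
#'
#' @param profile Named numeric with the 8 category scores, optionally a
#'   `carotenoids` element (umol/L).
#' @param rules An [default_advice_rules()] rule set.
#' @return Tibble `category`, `reason` (`"insufficient-diet-score"` /
#'   `"insufficient-biomarker"`), `trigger` (the rule that fired), `value`
#'   (the observed value).
#' @export
evaluate_diet_sufficiency <- function(profile, rules = default_advice_rules()) {
  scores <- profile[intersect(names(profile), dhdi_categories)]
  check_category_scores(scores)
  low <- scores < rules$dhdi_cutoffs[names(scores)]
  out <- tibble::tibble(
    category = names(scores)[low],
    reason = "insufficient-diet-score",
    trigger = paste0("score<", rules$dhdi_cutoffs[names(scores)[low]]),
    value = unname(scores[low])
  )
  if ("carotenoids" %in% names(profile) && !is.na(profile[["carotenoids"]]) &&
      profile[["carotenoids"]] < rules$carotenoid_cutoff) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      category = c("fruit", "vegetables"),
      reason = "insufficient-biomarker",
      trigger = paste0("carotenoids<", rules$carotenoid_cutoff),
      value = unname(profile[["carotenoids"]])
    ))
  }
  if (nrow(out) == 0) out <- empty_triggers()
  out
}

#' Map metabolic abnormalities to emphasized food categories
#'
#' Pass 2 of the advice algorithm: the union of the rule-set mapping over
#' all risk flags that are present.
#'
#' @param flags One row from [flag_risk_factors()] (or a named logical
#'   vector over the flag names).
#' @param rules An [default_advice_rules()] rule set.
#' @return Tibble `category`, `reason` (`"metabolic-emphasis"`), `trigger`
#'   (the flag), `value` (1).
#' @export
map_metabolic_abnormalities <- function(flags, rules = default_advice_rules()) {
  if (is.data.frame(flags)) {
    if (nrow(flags) != 1) abort("supply flags for a single subject")
    flags <- unlist(flags[intersect(names(flags),
                                    c("waist_excessive", secondary_flags))])
  }
  flags <- flags[intersect(names(flags), c("waist_excessive", secondary_flags))]
  on <- names(flags)[as.logical(flags)]
  missing_map <- setdiff(on, names(rules$flag_map))
  if (length(missing_map)) {
    abort(paste("flag(s) missing from the advice mapping table:",
                paste(missing_map, collapse = ", ")))
  }
  if (!length(on)) return(empty_triggers())
  dplyr::bind_rows(lapply(on, function(f) {
    tibble::tibble(category = rules$flag_map[[f]],
                   reason = "metabolic-emphasis", trigger = f, value = 1)
  }))
}

#' Compose an advice plan
#'
#' Merges the diet-insufficiency and metabolic-emphasis triggers into one
#' plan: the union of categories in the canonical [dhdi_categories] order,
#' each carrying all of its reasons (a category advised on both paths keeps
#' both). Re-running this composition on a plan's own triggers regenerates
#' the plan exactly.
#'
#' @param diet_insufficient Output of [evaluate_diet_sufficiency()].
#' @param metabolic_emphasis Output of [map_metabolic_abnormalities()].
#' @param rules Optional rule set; honors `max_categories` when set.
#' @return Tibble of class `advice_plan`: `category`, `reason`, `trigger`,
#'   `value`, ordered by category (canonical order) then reason.
#' @export
compose_advice <- function(diet_insufficient, metabolic_emphasis,
                           rules = NULL) {
  plan <- dplyr::bind_rows(diet_insufficient, metabolic_emphasis)
  plan <- dplyr::distinct(plan)
  plan <- plan[order(match(plan$category, dhdi_categories), plan$reason), ]
  if (!is.null(rules$max_categories)) {
    keep <- head(unique(plan$category), rules$max_categories)
    plan <- plan[plan$category %in% keep, ]
  }
  class(plan) <- c("advice_plan", class(plan))
  plan
}

#' Categories advised by a plan
#'
#' @param plan An `advice_plan`.
#' @return Character vector in canonical order (no duplicates).
#' @export
advised_categories <- function(plan) unique(plan$category)

#' Select a behavior-change strategy from a plan
#'
#' Stage 2 proxy: the participant (or a seeded random draw standing in for
#' the dietitian consultation) picks a non-empty subset of the advised
#' categories to work on.
#'
#' @param plan A non-empty `advice_plan`.
#' @param choose Explicit character subset of the advised categories; when
#'   given, `probs`/`seed` are ignored.
#' @param probs Per-category selection probability (single value or named
#'   over the advised categories, default 0.5); empty draws are redrawn so
#'   the strategy is non-empty.
#' @param seed Integer seed for the probabilistic draw.
#' @return Character vector of chosen categories (canonical order).
#' @export
select_strategy <- function(plan, choose = NULL, probs = 0.5, seed = NULL) {
  cats <- advised_categories(plan)
  if (!length(cats)) abort("cannot select a strategy from an empty plan")
  if (!is.null(choose)) {
    bad <- setdiff(choose, cats)
    if (length(bad)) abort(paste("chosen categories not in the plan:",
                                 paste(bad, collapse = ", ")))
    if (!length(choose)) abort("a strategy must contain at least one category")
    return(cats[cats %in% choose])
  }
  if (is.null(seed)) abort("probabilistic selection needs a seed")
  if (is.null(names(probs))) {
    probs <- setNames(rep(probs, length(cats)), cats)
  }
  probs <- probs[cats]
  if (anyNA(probs)) abort("probs must cover every advised category")
  withr::with_seed(seed, {
    repeat {
      inc <- runif(length(cats)) < probs
      if (any(inc) || all(probs == 0)) break
    }
    if (!any(inc)) inc[1] <- TRUE  # degenerate all-zero probabilities
    cats[inc]
  })
}

#' Advise one subject end to end
#'
#' Convenience wrapper running both advice passes and the composition for a
#' single subject.
#'
#' @param profile Named numeric: 8 category scores, optional `carotenoids`.
#' @param flags One row of [flag_risk_factors()] output.
#' @param rules An [default_advice_rules()] rule set.
#' @return An `advice_plan`.
#' @export
advise <- function(profile, flags, rules = default_advice_rules()) {
  compose_advice(
    evaluate_diet_sufficiency(profile, rules),
    map_metabolic_abnormalities(flags, rules),
    rules
  )
}
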