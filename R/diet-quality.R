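# DHDI diet-quality scoring.

check_category_scores <- function(scores) {
  if (!setequal(names(scores), dhdi_categories)) {
    abort(paste("need exactly the 8 DHDI categories:",
                paste(dhdi_categories, collapse = ", ")))
  }
  if (anyNA(scores)) abort("missing category score")
  if (any(scores < 1 | scores > 10)) abort("category scores must be in [1, 10]")
  invisible(scores)
}

#' Total DHDI score
#'
#' Sum of the eight DHDI category scores (each 1-10), giving the total
#' diet-quality score on the 8-80 scale.
#'
#' @param scores Either a named numeric vector with exactly the
#'   [dhdi_categories] names, or a data frame containing those columns
#'   (one total per row).
#' @return Numeric total(s) in `[8, 80]`.
#' @export
#' @examples
#' total_dhdi(setNames(rep(10, 8), dhdi_categories))  # 80
total_dhdi <- function(scores) {
  if (is.data.frame(scores)) {
    miss <- setdiff(dhdi_categories, names(scores))
    if (length(miss)) abort(paste("missing categories:", paste(miss, collapse = ", ")))
    m <- as.matrix(scores[dhdi_categories])
    if (anyNA(m)) abort("missing category score")
    if (any(m < 1 | m > 10)) abort("category scores must be in [1, 10]")
    return(unname(rowSums(m)))
  }
  check_category_scores(scores)
  sum(scores)
}

#' Score one food category from intake
#'
#' Linear guideline-adherence scoring between two intake bounds. For an
#' adequacy component (e.g. vegetables) the score is 1 at or below the lower
#' bound, 10 at or above the upper bound, linear in between; a moderation
#' component (e.g. sugar-containing beverages) is mirrored: 10 at or below
#' the lower bound, 1 at or above the upper bound. Offered as a convenience
#' for synthetic intake data; the pipeline's canonical input is the category
#' score itself.
#'
#' @param intake Intake amount per day (any consistent unit).
#' @param lower,upper Guideline bounds, `upper > lower`.
#' @param direction `"adequacy"` (more is better) or `"moderation"`.
#' @return Score(s) in `[1, 10]`.
#' @export
#' @examples
#' score_component(150, 100, 200, "adequacy")  # midpoint -> 5.5
score_component <- function(intake, lower, upper,
                            direction = c("adequacy", "moderation")) {
  direction <- match.arg(direction)
  if (upper <= lower) abort("`upper` must exceed `lower`")
  frac <- pmin(pmax((intake - lower) / (upper - lower), 0), 1)
  if (direction == "moderation") frac <- 1 - frac
  1 + 9 * frac
}

#' Change in diet profile between two visits
#'
#' Signed per-category (and total) differences, later profile minus earlier.
#' When both profiles carry the full category set and no explicit
#' `dhdi_total`, the total change is appended as the sum of category
#' changes.
#'
#' @param p0,p1 Named numeric vectors (same names): category scores,
#'   optionally `dhdi_total` and/or `carotenoids`.
#' @return Named numeric vector of signed changes `p1 - p0`.
#' @export
#' @examples
#' diet_delta(c(dhdi_total = 52.9), c(dhdi_total = 57.2))  # +4.3
diet_delta <- function(p0, p1) {
  if (!setequal(names(p0), names(p1))) {
    abort("the two profiles must cover the same categories")
  }
  if (anyNA(p0) || anyNA(p1)) abort("missing values in profiles")
  delta <- p1[names(p0)] - p0
  if (all(dhdi_categories %in% names(delta)) && !"dhdi_total" %in% names(delta)) {
    delta <- c(delta, dhdi_total = sum(delta[dhdi_categories]))
  }
  delta
}
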