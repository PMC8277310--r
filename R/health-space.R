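# The personal health score ("health space" projection).
#
# A two-group multivariate model is trained on a MetS reference group
# (outcome coded 1) and a healthy reference group (coded 2); projecting an
# individual's standardized biomarker panel through the fitted coefficients
# yields a continuous unitless score anchored at the two groups.

#' Healthiest-extreme direction per ranking feature
#'
#' Which extreme of each biomarker is considered healthiest when ranking
#' candidates for the healthy reference group: low triglycerides, low LDL,
#' high HDL, low glucose, low C-peptide.
#'
#' @return Named character vector (`"lower"`/`"higher"`) over
#'   [health_space_features].
#' @export
default_rank_directions <- function() {
  c(triglycerides = "lower", ldl = "lower", hdl = "higher",
    glucose = "lower", c_peptide = "lower")
}

#' Normalized within-pool ranks of one feature
#'
#' Ranks a feature across a subject pool so that the healthiest value gets
#' the smallest normalized rank (position / n, ties sharing the mean
#' position). Small normalized ranks therefore mean "near the healthy top",
#' the convention the rank-aggregation score expects.
#'
#' @param values Numeric vector, no missing values.
#' @param direction `"higher"` if large values are healthiest (e.g. HDL),
#'   `"lower"` otherwise.
#' @return Normalized ranks in `(0, 1]`.
#' @export
#' @examples
#' normalize_ranks(c(1.6, 1.0, 1.2), "higher")  # 1/3, 1, 2/3
normalize_ranks <- function(values, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (length(values) == 0) abort("empty pool")
  if (anyNA(values)) abort("missing values in pool")
  r <- if (direction == "higher") rank(-values, ties.method = "average")
       else rank(values, ties.method = "average")
  r / length(values)
}

#' Robust rank aggregation score
#'
#' The rho score of one subject given their normalized ranks across `m`
#' feature lists: the minimum over k of the probability that the k-th order
#' statistic of m independent uniforms falls at or below the subject's k-th
#' smallest rank, i.e. `min_k P(Beta(k, m - k + 1) <= r_(k))`. Small rho
#' means the subject sits consistently near the healthy top of the lists.
#' Multiplying rho by m gives a Bonferroni-style conservative p-value.
#'
#' @param r Numeric vector of normalized ranks in `(0, 1]` (any order).
#' @return rho in `(0, 1]`.
#' @export
#' @examples
#' rra_rho(c(0.2, 0.5))  # min(1 - 0.8^2, 0.5^2) = 0.25
rra_rho <- function(r) {
  if (length(r) == 0) abort("need at least one rank")
  if (anyNA(r) || any(r <= 0 | r > 1)) abort("ranks must lie in (0, 1]")
  m <- length(r)
  r <- sort(r)
  min(pbeta(r, seq_len(m), m - seq_len(m) + 1))
}

#' Select the healthy reference group
#'
#' Filters a screened pool to subjects with BMI in `bmi_range` and no MetS
#' risk flag at all, ranks the five model biomarkers within the eligible
#' pool, aggregates each subject's ranks with [rra_rho()], and returns the
#' `n_top` subjects with the smallest rho (ties broken by participant id
#' for determinism).
#'
#' @param pool Subject table with `participant_id`, `sex`, `bmi` and the
#'   screening/model biomarker columns.
#' @param n_top Number of subjects to keep (default 10).
#' @param bmi_range Eligible BMI window (default `c(18, 25)` kg/m2).
#' @param rules Screening thresholds, see [default_risk_rules()].
#' @param directions Healthiest-extreme map, see
#'   [default_rank_directions()].
#' @return The selected rows of `pool` with an appended `rho` column,
#'   ordered healthiest first.
#' @export
select_healthy_reference <- function(pool, n_top = 10, bmi_range = c(18, 25),
                                     rules = default_risk_rules(),
                                     directions = default_rank_directions()) {
  flags <- flag_risk_factors(pool, rules)
  eligible <- pool$bmi >= bmi_range[1] & pool$bmi <= bmi_range[2] &
    !flags$waist_excessive & flags$n_secondary == 0
  cand <- pool[eligible, , drop = FALSE]
  if (nrow(cand) < n_top) {
    abort(paste0("only ", nrow(cand), " eligible subjects for n_top = ", n_top))
  }
  ranks <- vapply(names(directions), function(f) {
    normalize_ranks(cand[[f]], directions[[f]])
  }, numeric(nrow(cand)))
  ranks <- matrix(ranks, nrow = nrow(cand))
  cand$rho <- apply(ranks, 1, rra_rho)
  cand <- cand[order(cand$rho, cand$participant_id), , drop = FALSE]
  head(cand, n_top)
}

#' Select the MetS reference group
#'
#' Subjects of a screened pool meeting the MetS rule ([classify_mets()]):
#' central obesity plus at least two secondary risk factors.
#'
#' @inheritParams select_healthy_reference
#' @return The MetS rows of `pool`.
#' @export
select_mets_reference <- function(pool, rules = default_risk_rules()) {
  if (nrow(pool) == 0) return(pool)
  flags <- flag_risk_factors(pool, rules)
  pool[classify_mets(flags, rules), , drop = FALSE]
}

#' Fit the health-space model
#'
#' Fits the two-group multivariate model behind the personal health score.
#' The outcome is the class code (MetS = 1, healthy = 2); triglycerides,
#' LDL, HDL, glucose and C-peptide enter as fixed effects after
#' standardization with the pooled training mean/SD (stored in the model so
#' projection of new individuals is self-contained); sex enters as a random
#' effect so the final coefficients may differ between men and women. The
#' default random structure is an (uncorrelated) random intercept plus
#' random slopes on all five features; with only two sex levels the
#' variance components are weakly identified and the fit is often singular,
#' which is tolerated -- the sex adjustments then shrink toward zero.
#'
#' @param healthy,mets Subject tables with `sex` and the five biomarker
#'   columns ([health_space_features]); both non-empty.
#' @param random `"slopes"` (default), `"intercept"`, or `"none"` (plain
#'   linear model, also the fallback when only one sex is present).
#' @param threshold Classification threshold between the class codes
#'   (default 1.5).
#' @return An object of class `health_space_model`: standardization table,
#'   population coefficients, per-sex coefficient adjustments, coding,
#'   threshold.
#' @export
fit_health_space <- function(healthy, mets,
                             random = c("slopes", "intercept", "none"),
                             threshold = 1.5) {
  random <- match.arg(random)
  if (nrow(healthy) == 0 || nrow(mets) == 0) {
    abort("both reference groups must be non-empty")
  }
  if (threshold <= 1 || threshold >= 2) {
    abort("threshold must lie strictly between the class codes 1 and 2")
  }
  feats <- health_space_features
  dat <- dplyr::bind_rows(
    dplyr::mutate(healthy[c("sex", feats)], y = 2),
    dplyr::mutate(mets[c("sex", feats)], y = 1)
  )
  if (anyNA(dat[feats])) abort("missing biomarker values in training data")

  std <- tibble::tibble(
    feature = feats,
    mean = vapply(dat[feats], mean, numeric(1)),
    sd = vapply(dat[feats], sd, numeric(1))
  )
  if (any(std$sd <= 0)) abort("singular design: a feature has zero variance")
  for (j in seq_along(feats)) {
    dat[[feats[j]]] <- (dat[[feats[j]]] - std$mean[j]) / std$sd[j]
  }

  one_sex <- length(unique(dat$sex)) < 2
  if (one_sex && random != "none") {
    warn("only one sex present; sex random effect degenerates to a fixed-only fit")
    random <- "none"
  }

  fixed <- paste("y ~", paste(feats, collapse = " + "))
  sex_adj <- list()
  singular <- FALSE
  if (random == "none") {
    fit <- stats::lm(as.formula(fixed), data = dat)
    beta <- stats::coef(fit)
  } else {
    re <- if (random == "slopes") {
      paste0("(1 + ", paste(feats, collapse = " + "), " || sex)")
    } else "(1 | sex)"
    fml <- as.formula(paste(fixed, "+", re))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    ))
    singular <- lme4::isSingular(fit)
    beta <- lme4::fixef(fit)
    re_sex <- lme4::ranef(fit)$sex
    sex_adj <- lapply(setNames(rownames(re_sex), rownames(re_sex)), function(s) {
      adj <- setNames(as.numeric(re_sex[s, ]), colnames(re_sex))
      names(adj)[names(adj) == "(Intercept)"] <- "(Intercept)"
      adj
    })
  }

  structure(
    list(features = feats, standardization = std,
         coef = beta, sex_coef = sex_adj,
         coding = c(mets = 1, healthy = 2),
         threshold = threshold, random = random, singular = singular,
         n_train = c(healthy = nrow(healthy), mets = nrow(mets))),
    class = "health_space_model"
  )
}

#' @export
print.health_space_model <- function(x, ...) {
  cat("<health_space_model> score = intercept + sum(coef_sex * z)\n",
      "  coding: MetS = 1, healthy = 2; threshold ", x$threshold,
      "; random: ", x$random,
      if (x$singular) " (singular variance fit)" else "", "\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

#' Project individuals into the health space
#'
#' Computes the personal health score for new measurements: each biomarker
#' is standardized with the training statistics stored in the model, then
#' score = intercept + sum of (sex-specific) coefficients times the
#' standardized features. Scores live nominally near `[1, 2]` (1 = MetS
#' reference, 2 = healthy reference) but are not clipped.
#'
#' @param model A fitted [fit_health_space()] model.
#' @param newdata Data frame with the five biomarker columns; `sex`,
#'   `participant_id` and `week` are used when present. Rows with unknown
#'   sex fall back to the population coefficients with a warning.
#' @return Tibble with any id columns plus `score`.
#' @export
predict_score <- function(model, newdata) {
  feats <- model$features
  miss <- setdiff(feats, names(newdata))
  if (length(miss)) abort(paste("missing biomarkers:", paste(miss, collapse = ", ")))
  if (anyNA(newdata[feats])) abort("missing biomarker values")
  Z <- as.matrix(newdata[feats])
  Z <- sweep(Z, 2, model$standardization$mean, "-")
  Z <- sweep(Z, 2, model$standardization$sd, "/")

  sex <- if ("sex" %in% names(newdata)) as.character(newdata$sex)
         else rep(NA_character_, nrow(Z))
  known <- names(model$sex_coef)
  if (length(known) && any(!sex %in% known)) {
    warn("unknown sex for some rows; using population coefficients")
  }
  base <- c(model$coef["(Intercept)"], model$coef[feats])
  score <- vapply(seq_len(nrow(Z)), function(i) {
    b <- base
    if (!is.na(sex[i]) && sex[i] %in% known) {
      adj <- model$sex_coef[[sex[i]]]
      b[names(adj)] <- b[names(adj)] + adj
    }
    unname(b["(Intercept)"] + sum(b[feats] * Z[i, ]))
  }, numeric(1))

  id_cols <- intersect(c("participant_id", "week"), names(newdata))
  out <- tibble::as_tibble(newdata[id_cols])
  out$score <- score
  out
}

#' Classification accuracy and Cohen's kappa
#'
#' Dichotomizes scores at the model threshold (healthy iff score >
#' threshold) and compares with true class labels.
#'
#' @param truth True classes: `"healthy"`/`"mets"`, or the class codes
#'   2/1.
#' @param scores Continuous health scores.
#' @param threshold Classification threshold (default 1.5).
#' @return List with `accuracy`, `kappa` and the 2x2 `confusion` table.
#' @export
#' @examples
#' classification_metrics(rep(c("healthy", "mets"), c(5, 5)),
#'                        c(rep(1.9, 5), rep(1.1, 5)))
classification_metrics <- function(truth, scores, threshold = 1.5) {
  if (is.numeric(truth)) {
    truth <- ifelse(truth == 2, "healthy", ifelse(truth == 1, "mets", NA))
  }
  if (anyNA(truth) || !all(truth %in% c("healthy", "mets"))) {
    abort("truth must be 'healthy'/'mets' (or codes 2/1)")
  }
  if (any(!is.finite(scores))) abort("scores must be finite")
  if (length(unique(truth)) < 2) {
    abort("kappa undefined: only one class present in truth")
  }
  pred <- ifelse(scores > threshold, "healthy", "mets")
  lev <- c("mets", "healthy")
  tab <- table(factor(truth, lev), factor(pred, lev), dnn = c("truth", "pred"))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(accuracy = po, kappa = kappa, confusion = tab)
}

#' Serialize / restore a health-space model
#'
#' JSON round-trip of the standardization table, coefficients, sex
#' adjustments, class coding and threshold, so a fitted model can be stored
#' next to the scores it produced.
#'
#' @param model A `health_space_model`.
#' @param path File path.
#' @return `write_health_space()`: `path`, invisibly.
#'   `read_health_space()`: the restored model.
#' @export
write_health_space <- function(model, path) {
  obj <- list(
    features = model$features,
    standardization = model$standardization,
    coef = as.list(model$coef),
    sex_coef = lapply(model$sex_coef, as.list),
    coding = as.list(model$coding),
    threshold = model$threshold,
    random = model$random,
    singular = model$singular,
    n_train = as.list(model$n_train)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_health_space
#' @export
read_health_space <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(features = obj$features,
         standardization = tibble::as_tibble(obj$standardization),
         coef = unlist(obj$coef),
         sex_coef = lapply(obj$sex_coef, unlist),
         coding = unlist(obj$coding),
         threshold = obj$threshold, random = obj$random,
         singular = obj$singular, n_train = unlist(obj$n_train)),
    class = "health_space_model"
  )
}
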