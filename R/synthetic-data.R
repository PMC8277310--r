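# Synthetic cohort generation.
#
# Marginals are truncated normals whose underlying (mu0, sigma0) are
# moment-calibrated so the *realized* truncated distribution has the
# requested mean/SD; dependence enters through a Gaussian copula.

#' Cohort specification
#'
#' Describes the marginal distribution of one subject group: per-feature
#' mean, SD and physiological truncation bounds, the male proportion, and an
#' optional between-feature correlation matrix (Gaussian copula).
#'
#' @param label Group label, e.g. `"healthy-reference"`.
#' @param features Tibble with columns `feature`, `mean`, `sd`, `lower`,
#'   `upper`. SDs must be non-negative and each mean must lie inside its
#'   bounds.
#' @param male_prop Proportion of male subjects in `[0, 1]`.
#' @param correlations Optional correlation matrix with dimnames drawn from
#'   `features$feature`; unnamed pairs default to 0. `NULL` means
#'   independent features.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(label, features, male_prop = 0.5, correlations = NULL) {
  features <- tibble::as_tibble(features)
  need <- c("feature", "mean", "sd", "lower", "upper")
  if (!all(need %in% names(features))) {
    abort("`features` needs columns feature, mean, sd, lower, upper")
  }
  if (anyDuplicated(features$feature)) abort("duplicated feature names")
  if (any(features$sd < 0)) abort("all SDs must be >= 0")
  if (any(features$mean < features$lower | features$mean > features$upper)) {
    abort("truncation bounds must contain the mean")
  }
  if (male_prop < 0 || male_prop > 1) abort("male_prop must be in [0, 1]")
  if (!is.null(correlations)) {
    stopifnot(is.matrix(correlations),
              identical(rownames(correlations), colnames(correlations)))
    if (!all(rownames(correlations) %in% features$feature)) {
      abort("correlation dimnames must be features of the spec")
    }
  }
  structure(
    list(label = label, features = features, male_prop = male_prop,
         correlations = correlations),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$label, ": ", nrow(x$features),
      " features, male proportion ", round(x$male_prop, 3), "\n", sep = "")
  print(x$features, n = 5)
  invisible(x)
}

# Physiological truncation bounds shared by the default specs.
default_feature_bounds <- function() {
  tibble::tribble(
    ~feature,            ~lower, ~upper,
    "age",               18,   95,
    "bmi",               14,   60,
    "waist",             50,   180,
    "total_cholesterol", 2,    12,
    "hdl",               0.4,  3.5,
    "ldl",               0.5,  8,
    "triglycerides",     0.2,  15,
    "glucose",           3,    25,
    "c_peptide",         0.05, 6,
    "sbp",               80,   230,
    "dbp",               40,   140
  )
}

#' Default cohort specifications
#'
#' Cohort specifications built from the published group summary statistics
#' ([study_summary_tables()]): the motivated pre-MetS intervention cohort
#' and the two health-space reference groups. The default copula carries a
#' single non-zero correlation, HDL vs triglycerides of -0.3 (the well-known
#' inverse association); everything else is independent, since only
#' marginal moments are published.
#'
#' @param group `"healthy-reference"`, `"mets-reference"` or
#'   `"intervention"`.
#' @param hdl_tg_correlation Correlation imposed between HDL and
#'   triglycerides (set 0 for fully independent features).
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(group = c("healthy-reference",
                                          "mets-reference",
                                          "intervention"),
                                hdl_tg_correlation = -0.3) {
  group <- match.arg(group)
  tabs <- study_summary_tables()
  moments <- tabs$cohorts[tabs$cohorts$group == group, c("feature", "mean", "sd")]
  features <- dplyr::inner_join(moments, default_feature_bounds(), by = "feature")
  info <- tabs$cohort_info[tabs$cohort_info$group == group, ]
  corr <- NULL
  if (hdl_tg_correlation != 0) {
    corr <- diag(2)
    dimnames(corr) <- list(c("hdl", "triglycerides"), c("hdl", "triglycerides"))
    corr["hdl", "triglycerides"] <- corr["triglycerides", "hdl"] <- hdl_tg_correlation
  }
  cohort_spec(group, features, male_prop = info$male_prop, correlations = corr)
}

# Mean and SD of a N(mu, sigma) truncated to [lo, hi] (closed form).
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the underlying (mu0, sigma0) whose truncated moments equal the
# requested (mean, sd). Keeps generated sample moments convergent to the
# spec even when the bounds bite (e.g. a glucose SD of 3 against a floor
# of 3 mmol/L).
calibrate_truncnorm <- function(mean, sd, lo, hi) {
  if (sd == 0) return(c(mu = mean, sigma = 0))
  # negligible truncation: identity
  if ((mean - lo) / sd > 8 && (hi - mean) / sd > 8) {
    return(c(mu = mean, sigma = sd))
  }
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    if (anyNA(mom) || any(!is.finite(mom))) return(1e10)
    ((mom[1] - mean) / sd)^2 + ((mom[2] - sd) / sd)^2
  }
  # heavily truncated features have a narrow feasible ridge; multi-start
  # keeps the optimizer off the sigma -> Inf plateau
  starts <- list(c(mean, log(sd)),
                 c(mean - sd / 2, log(2 * sd)),
                 c(mean + sd / 2, log(2 * sd)),
                 c(mean, log(4 * sd)))
  fits <- lapply(starts, function(s) {
    optim(s, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 5000))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF draw of the calibrated truncated normal from uniforms.
qtruncnorm_cal <- function(u, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, length(u)))
  cal <- calibrate_truncnorm(mean, sd, lo, hi)
  pa <- pnorm(lo, cal["mu"], cal["sigma"])
  pb <- pnorm(hi, cal["mu"], cal["sigma"])
  qnorm(pa + u * (pb - pa), cal["mu"], cal["sigma"])
}

# Full feature correlation matrix for a spec (identity + declared entries).
full_correlation <- function(spec) {
  f <- spec$features$feature
  R <- diag(length(f)); dimnames(R) <- list(f, f)
  if (!is.null(spec$correlations)) {
    nm <- rownames(spec$correlations)
    R[nm, nm] <- spec$correlations
  }
  R
}

#' Generate a reference subject pool
#'
#' Draws `n` subjects from a [cohort_spec()]: sex by the spec's male
#' proportion, features from moment-calibrated truncated normals coupled by
#' the spec's Gaussian copula. Reproducible for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; all randomness is local to this call.
#' @return A tibble with `participant_id`, `sex` (`"M"`/`"F"`) and one
#'   column per spec feature.
#' @export
#' @examples
#' pool <- generate_reference_pool(default_cohort_spec("healthy-reference"),
#'                                 n = 50, seed = 1)
generate_reference_pool <- function(spec, n, seed) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec")
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be >= 1")
  n <- as.integer(n)
  feats <- spec$features
  R <- full_correlation(spec)
  withr::with_seed(seed, {
    sex <- ifelse(runif(n) < spec$male_prop, "M", "F")
    Z <- matrix(rnorm(n * nrow(feats)), n, nrow(feats))
    Z <- Z %*% chol(R)
    U <- pnorm(Z)
    X <- vapply(seq_len(nrow(feats)), function(j) {
      qtruncnorm_cal(U[, j], feats$mean[j], feats$sd[j],
                     feats$lower[j], feats$upper[j])
    }, numeric(n))
    X <- matrix(X, nrow = n)
    colnames(X) <- feats$feature
    dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("S%04d", seq_len(n)), sex = sex),
      tibble::as_tibble(X)
    )
  })
}

#' Trajectory specification for a longitudinal intervention cohort
#'
#' Describes how each outcome evolves over the week 0/8/16 visit schedule:
#' baseline mean/SD, mean change at each post-baseline week, the
#' within-subject correlation of repeated measures (a random-intercept ICC),
#' bounds, outcome type, and -- for DHDI food categories -- the strategy
#' gating that restricts the change to subjects whose behavior-change
#' strategy includes that category.
#'
#' @param outcomes Tibble with columns `outcome`, `baseline_mean`,
#'   `baseline_sd`, `lower`, `upper`, `delta_wk8`, `delta_wk16`, `icc`,
#'   `type` (`"continuous"` or `"likert"`), `strategy_category` (`NA` or a
#'   category of [dhdi_categories]) and list-column `weeks` (measurement
#'   weeks for that outcome).
#' @param strategy_probs Named probability per DHDI category that a subject
#'   includes the category in their behavior-change strategy.
#' @param dropout_n Number of subjects losing all post-baseline visits
#'   (complete-record dropout after week 0).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(outcomes, strategy_probs = NULL, dropout_n = 0) {
  outcomes <- tibble::as_tibble(outcomes)
  need <- c("outcome", "baseline_mean", "baseline_sd", "lower", "upper",
            "delta_wk8", "delta_wk16", "icc", "type", "strategy_category")
  if (!all(need %in% names(outcomes))) {
    abort(paste("`outcomes` needs columns:", paste(need, collapse = ", ")))
  }
  if (!"weeks" %in% names(outcomes)) {
    outcomes$weeks <- rep(list(c(0, 8, 16)), nrow(outcomes))
  }
  if (any(outcomes$icc < 0 | outcomes$icc >= 1)) {
    abort("within-subject correlations (icc) must be in [0, 1)")
  }
  if (any(outcomes$baseline_sd < 0)) abort("baseline SDs must be >= 0")
  if (!is.null(strategy_probs)) {
    if (any(strategy_probs < 0 | strategy_probs > 1)) {
      abort("strategy probabilities must be in [0, 1]")
    }
    gated <- outcomes$strategy_category[!is.na(outcomes$strategy_category)]
    if (!all(gated %in% names(strategy_probs))) {
      abort("every gated category needs a strategy probability")
    }
  }
  if (dropout_n < 0) abort("dropout_n must be >= 0")
  structure(
    list(outcomes = outcomes, strategy_probs = strategy_probs,
         dropout_n = as.integer(dropout_n)),
    class = "trajectory_spec"
  )
}

#' Default trajectory specification
#'
#' Built from the published visit-by-visit means and SDs
#' ([study_summary_tables()]): metabolic outcomes and total DHDI follow the
#' whole-cohort trajectories; each DHDI food category's change is gated on
#' the subject's behavior-change strategy, with inclusion probabilities
#' equal to the published strategy frequencies (e.g. vegetables 31/34);
#' Likert items are latent-normal outcomes measured at weeks 0 and 16 only.
#' The within-subject correlation of repeated measures is not published;
#' the default ICC of 0.6 is a stated assumption.
#'
#' @param icc Within-subject correlation of repeated measures, in `[0, 1)`.
#' @param dropout_n Complete-record dropouts after week 0 (default 0).
#' @return A [trajectory_spec()].
#' @export
default_trajectory_spec <- function(icc = 0.6, dropout_n = 0) {
  tabs <- study_summary_tables()
  n_total <- tabs$cohort_info$n[tabs$cohort_info$group == "intervention"]

  d <- tabs$diet
  diet <- tibble::tibble(
    outcome = d$outcome,
    baseline_mean = d$mean_wk0, baseline_sd = d$sd_wk0,
    lower = ifelse(d$outcome == "dhdi_total", 8,
                   ifelse(d$outcome == "carotenoids", 0.05, 1)),
    upper = ifelse(d$outcome == "dhdi_total", 80,
                   ifelse(d$outcome == "carotenoids", 6, 10)),
    delta_wk8 = d$mean_wk8 - d$mean_wk0,
    delta_wk16 = d$mean_wk16 - d$mean_wk0,
    icc = icc, type = "continuous",
    strategy_category = ifelse(d$outcome %in% dhdi_categories, d$outcome, NA),
    weeks = rep(list(c(0, 8, 16)), nrow(d))
  )

  m <- tabs$metabolic[tabs$metabolic$outcome != "health_score", ]
  bounds <- default_feature_bounds()
  m <- dplyr::left_join(m, bounds, by = c(outcome = "feature"))
  metab <- tibble::tibble(
    outcome = m$outcome,
    baseline_mean = m$mean_wk0, baseline_sd = m$sd_wk0,
    lower = m$lower, upper = m$upper,
    delta_wk8 = m$mean_wk8 - m$mean_wk0,
    delta_wk16 = m$mean_wk16 - m$mean_wk0,
    icc = icc, type = "continuous", strategy_category = NA_character_,
    weeks = rep(list(c(0, 8, 16)), nrow(m))
  )

  l <- tabs$likert
  likert <- tibble::tibble(
    outcome = l$outcome,
    baseline_mean = l$mean_wk0, baseline_sd = l$sd_wk0,
    lower = 1, upper = 7,
    delta_wk8 = NA_real_,
    delta_wk16 = l$mean_wk16 - l$mean_wk0,
    icc = icc, type = "likert", strategy_category = NA_character_,
    weeks = rep(list(c(0, 16)), nrow(l))
  )

  probs <- setNames(d$n_strategy[match(dhdi_categories, d$outcome)] / n_total,
                    dhdi_categories)
  trajectory_spec(dplyr::bind_rows(diet, metab, likert),
                  strategy_probs = probs, dropout_n = dropout_n)
}

draw_strategies <- function(n, probs) {
  # Bernoulli inclusion per category; empty draws are redrawn so every
  # subject works on at least one category (as in the study population).
  t(vapply(seq_len(n), function(i) {
    repeat {
      inc <- runif(length(probs)) < probs
      if (any(inc) || all(probs == 0)) return(inc)
    }
  }, logical(length(probs))))
}

#' Generate a longitudinal intervention cohort
#'
#' Simulates `n` subjects over the week 0/8/16 visit schedule. Each subject
#' carries a fixed behavior-change strategy (subset of [dhdi_categories])
#' drawn with the spec's inclusion probabilities; gated outcomes shift only
#' for subjects whose strategy includes the category. Repeated measures are
#' built as subject random intercept plus residual, so the within-subject
#' correlation equals the spec's `icc`. Likert outcomes are latent-normal
#' values rounded and clamped to 1-7; bounded continuous outcomes are
#' clamped to their bounds (which slightly attenuates mean changes near a
#' bound -- see the package vignette).
#'
#' @param cohort A [cohort_spec()] supplying sex and age demographics.
#' @param traj A [trajectory_spec()].
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed; all randomness is local to this call.
#' @return A list of class `synthetic_cohort`:
#'   `visits` (tibble, one row per participant-visit, one column per
#'   outcome), `strategies` (tibble `participant_id`, `category`), and
#'   `seed`.
#' @export
#' @examples
#' coh <- generate_intervention_cohort(default_cohort_spec("intervention"),
#'                                     default_trajectory_spec(),
#'                                     n = 10, seed = 7)
#' head(coh$visits)
generate_intervention_cohort <- function(cohort, traj, n, seed) {
  if (!inherits(traj, "trajectory_spec")) abort("`traj` must be a trajectory_spec")
  if (!is.numeric(n) || length(n) != 1 || n < 2) abort("`n` must be >= 2")
  n <- as.integer(n)
  out <- traj$outcomes
  weeks_all <- sort(unique(unlist(out$weeks)))

  withr::with_seed(seed, {
    sex <- ifelse(runif(n) < cohort$male_prop, "M", "F")
    agerow <- cohort$features[cohort$features$feature == "age", ]
    age <- if (nrow(agerow) == 1) {
      qtruncnorm_cal(runif(n), agerow$mean, agerow$sd, agerow$lower, agerow$upper)
    } else rep(NA_real_, n)

    probs <- traj$strategy_probs
    if (is.null(probs)) probs <- setNames(numeric(0), character(0))
    inc <- draw_strategies(n, probs)
    colnames(inc) <- names(probs)

    ids <- sprintf("P%03d", seq_len(n))
    visits <- tidyr::expand_grid(participant_id = ids, week = weeks_all)
    visits$sex <- sex[match(visits$participant_id, ids)]
    visits$age <- round(age[match(visits$participant_id, ids)])

    for (j in seq_len(nrow(out))) {
      o <- out[j, ]
      sd2 <- o$baseline_sd^2
      u <- rnorm(n, 0, sqrt(o$icc * sd2))
      gate <- if (!is.na(o$strategy_category)) {
        inc[, o$strategy_category]
      } else rep(TRUE, n)
      wk <- o$weeks[[1]]
      delta <- setNames(c(0, o$delta_wk8, o$delta_wk16), c("0", "8", "16"))
      vals <- matrix(NA_real_, n, length(weeks_all),
                     dimnames = list(ids, as.character(weeks_all)))
      for (w in wk) {
        e <- rnorm(n, 0, sqrt((1 - o$icc) * sd2))
        vals[, as.character(w)] <-
          o$baseline_mean + ifelse(gate, delta[[as.character(w)]], 0) + u + e
      }
      if (o$type == "likert") {
        vals <- pmin(pmax(round(vals), o$lower), o$upper)
      } else {
        vals <- pmin(pmax(vals, o$lower), o$upper)
      }
      visits[[o$outcome]] <-
        vals[cbind(match(visits$participant_id, ids),
                   match(as.character(visits$week), colnames(vals)))]
    }

    if (traj$dropout_n > 0) {
      if (traj$dropout_n >= n) abort("dropout_n must be < n")
      drop_ids <- ids[sample.int(n, traj$dropout_n)]
      visits <- visits[!(visits$participant_id %in% drop_ids & visits$week > 0), ]
    }

    strategies <- if (ncol(inc) > 0) {
      tibble::tibble(
        participant_id = rep(ids, each = ncol(inc)),
        category = rep(colnames(inc), times = n)
      )[as.vector(t(inc)), ]
    } else {
      tibble::tibble(participant_id = character(), category = character())
    }

    structure(list(visits = visits, strategies = strategies, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", dplyr::n_distinct(x$visits$participant_id),
      " subjects, weeks ", paste(sort(unique(x$visits$week)), collapse = "/"),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `visits.csv` and `strategies.csv` plus a JSON sidecar recording
#' the seed and column dictionary, so a generated cohort is self-describing.
#'
#' @param cohort A `synthetic_cohort` (see [generate_intervention_cohort()]).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  write.csv(cohort$strategies, file.path(dir, "strategies.csv"), row.names = FALSE)
  sidecar <- list(
    seed = cohort$seed,
    n_subjects = dplyr::n_distinct(cohort$visits$participant_id),
    weeks = sort(unique(cohort$visits$week)),
    columns = names(cohort$visits)
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
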