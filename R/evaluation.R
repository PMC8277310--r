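# Longitudinal evaluation statistics.
#
# Continuous outcomes: linear mixed model, time (categorical) fixed +
# subject random intercept, ML estimation; the overall time effect is a
# likelihood-ratio test; pairwise timepoint contrasts use t statistics with
# n_subjects - 1 df and are BH-adjusted within outcome. Observations with
# |residual| > 3 x RMSE are flagged as outliers and the model is refitted
# once without them (single pass, no iteration).

#' Flag statistical outliers from model residuals
#'
#' Observations whose absolute residual exceeds `multiplier` times the root
#' mean square error (strictly greater; a residual of exactly 3 x RMSE is
#' kept).
#'
#' @param residuals Numeric residual vector.
#' @param rmse Root mean square error of the fitted model.
#' @param multiplier Threshold multiplier (default 3).
#' @return Integer indices of flagged observations.
#' @export
flag_outliers <- function(residuals, rmse, multiplier = 3) {
  which(abs(residuals) > multiplier * rmse)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (monotone, capped at 1, original order restored).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Linear mixed model for a time effect
#'
#' Fits `value ~ time + (1 | subject)` by maximum likelihood with time as a
#' categorical fixed effect, applies the single-pass 3xRMSE outlier rule,
#' and reports model-based timepoint means, the likelihood-ratio test of
#' the overall time effect, and BH-adjusted pairwise timepoint contrasts.
#'
#' @param data Data frame with columns `participant_id`, `week`, `value`
#'   (at most one value per participant-week).
#' @param outlier_rule Apply the 3xRMSE flag-remove-refit pass (default
#'   `TRUE`).
#' @param conf_level Confidence level of the contrast intervals.
#' @param contrasts Compute pairwise contrasts (default `TRUE`; switching
#'   off speeds up large simulation loops).
#' @return Object of class `time_effect`: `p_overall`, `emm` (week, mean,
#'   se), `contrasts` (estimate, se, df, p, p_adj, CI per week pair),
#'   `rmse`, `outliers` (flagged participant-weeks), `n_subjects`,
#'   `n_obs`, and the final `fit`.
#' @export
fit_time_mixed_model <- function(data, outlier_rule = TRUE,
                                 conf_level = 0.95, contrasts = TRUE) {
  need <- c("participant_id", "week", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  data <- tibble::as_tibble(data[need])
  data <- data[!is.na(data$value), ]
  if (anyDuplicated(data[c("participant_id", "week")])) {
    abort("at most one value per participant-week")
  }
  weeks <- sort(unique(data$week))
  if (length(weeks) < 2) abort("need at least two timepoints")
  if (dplyr::n_distinct(data$participant_id) < 2) abort("need at least two subjects")
  if (var(data$value) == 0) abort("degenerate outcome: all values constant")
  data$week_f <- factor(data$week, levels = weeks)

  ctrl <- lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore")
  fit_once <- function(d) {
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ week_f + (1 | participant_id), data = d,
                 REML = FALSE, control = ctrl)
    ))
  }
  fit <- fit_once(data)
  outliers <- tibble::tibble(participant_id = character(), week = numeric())
  if (outlier_rule) {
    idx <- flag_outliers(residuals(fit), stats::sigma(fit))
    if (length(idx)) {
      outliers <- data[idx, c("participant_id", "week")]
      data <- data[-idx, ]
      fit <- fit_once(data)
    }
  }

  null_fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | participant_id), data = data,
               REML = FALSE, control = ctrl)
  ))
  lr <- 2 * as.numeric(logLik(fit) - logLik(null_fit))
  p_overall <- pchisq(max(lr, 0), df = length(weeks) - 1, lower.tail = FALSE)

  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  L <- cbind(1, rbind(0, diag(length(weeks) - 1)))  # week-level means
  means <- as.numeric(L %*% beta)
  se_means <- sqrt(diag(L %*% V %*% t(L)))
  emm <- tibble::tibble(week = weeks, mean = means, se = se_means)

  ctr <- NULL
  if (contrasts) {
    pairs <- utils::combn(seq_along(weeks), 2)
    df <- dplyr::n_distinct(data$participant_id) - 1
    ctr <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      l <- L[b, ] - L[a, ]
      est <- sum(l * beta)
      se <- sqrt(as.numeric(t(l) %*% V %*% l))
      tstat <- est / se
      tibble::tibble(
        week_a = weeks[a], week_b = weeks[b],
        estimate = est, se = se, df = df,
        p = 2 * pt(-abs(tstat), df),
        lwr = est - qt(1 - (1 - conf_level) / 2, df) * se,
        upr = est + qt(1 - (1 - conf_level) / 2, df) * se
      )
    })
    ctr$p_adj <- bh_adjust(ctr$p)
  }

  structure(
    list(p_overall = p_overall, emm = emm, contrasts = ctr,
         rmse = stats::sigma(fit), outliers = outliers,
         n_subjects = dplyr::n_distinct(data$participant_id),
         n_obs = nrow(data), fit = fit),
    class = "time_effect"
  )
}

#' @export
print.time_effect <- function(x, ...) {
  cat("<time_effect> overall P =", format.pval(x$p_overall, digits = 3),
      "|", x$n_subjects, "subjects,", x$n_obs, "observations,",
      nrow(x$outliers), "outlier(s) removed\n")
  print(x$emm)
  if (!is.null(x$contrasts)) print(x$contrasts)
  invisible(x)
}

# ---- ordinal mixed regression (cumulative logit, subject random intercept)

gh_rule <- function(n) pracma::gaussHermite(n)

clmm_nll <- function(par, y, X, subj_idx, J, gh) {
  p <- ncol(X)
  theta <- if (J == 2) par[1] else cumsum(c(par[1], exp(par[2:(J - 1)])))
  beta <- if (p > 0) par[(J - 1) + seq_len(p)] else numeric(0)
  sigma <- exp(par[length(par)])
  up <- c(theta, Inf)[y]
  lo <- c(-Inf, theta)[y]
  eta0 <- if (p > 0) as.numeric(X %*% beta) else numeric(length(y))
  n_subj <- max(subj_idx)
  LS <- matrix(NA_real_, n_subj, length(gh$x))
  for (k in seq_along(gh$x)) {
    b <- sqrt(2) * sigma * gh$x[k]
    pr <- plogis(up - eta0 - b) - plogis(lo - eta0 - b)
    pr <- pmax(pr, 1e-300)
    LS[, k] <- rowsum(log(pr), subj_idx)[, 1]
  }
  lw <- log(gh$w / sqrt(pi))
  M <- apply(LS, 1, max)
  ll <- sum(M + log(rowSums(exp(sweep(LS, 1, M) + matrix(lw, n_subj,
                                                         length(lw), byrow = TRUE)))))
  -ll
}

fit_clmm <- function(y, X, subj_idx, J, gh) {
  # starting values: marginal cumulative logits, beta = 0, sigma = 1
  cum <- cumsum(tabulate(y, J))[seq_len(J - 1)] / length(y)
  cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
  th0 <- qlogis(cum)
  par0 <- c(th0[1], if (J > 2) log(pmax(diff(th0), 1e-3)),
            rep(0, ncol(X)), 0)
  opt <- optim(par0, clmm_nll, y = y, X = X, subj_idx = subj_idx, J = J,
               gh = gh, method = "BFGS", control = list(maxit = 500))
  opt
}

#' Ordinal mixed regression for Likert outcomes
#'
#' Cumulative-logit (proportional odds) model with time as a categorical
#' fixed effect and a subject random intercept, estimated by maximum
#' likelihood with Gauss-Hermite quadrature over the random effect. The
#' overall time effect is a likelihood-ratio test against the
#' intercept-only model. Response levels with no observations are collapsed
#' out (with a warning when interior levels are empty), the standard
#' cumulative-link convention.
#'
#' @param data Data frame with `participant_id`, `week`, `value` (integer
#'   Likert scores, e.g. 1-7).
#' @param gh_points Quadrature nodes (default 15).
#' @return Object of class `ordinal_time_effect`: `coef` (log odds of
#'   higher categories per post-baseline week), `thresholds`, `sigma`
#'   (random-intercept SD), `p_overall`, `logLik`, `n_subjects`.
#' @export
fit_ordinal_mixed <- function(data, gh_points = 15) {
  need <- c("participant_id", "week", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  data <- tibble::as_tibble(data[need])
  data <- data[!is.na(data$value), ]
  if (any(data$value != round(data$value))) abort("Likert values must be integers")
  lev <- sort(unique(data$value))
  if (length(lev) < 2) abort("degenerate outcome: all responses identical")
  if (length(lev) < diff(range(lev)) + 1) {
    warn("empty interior response categories collapsed")
  }
  y <- match(data$value, lev)
  J <- length(lev)
  weeks <- sort(unique(data$week))
  if (length(weeks) < 2) abort("need at least two timepoints")
  X <- model.matrix(~ factor(week, levels = weeks), data)[, -1, drop = FALSE]
  colnames(X) <- paste0("week", weeks[-1])
  subj <- factor(data$participant_id)
  subj_idx <- as.integer(subj)

  gh <- gh_rule(gh_points)
  full <- fit_clmm(y, X, subj_idx, J, gh)
  null <- fit_clmm(y, X[, 0, drop = FALSE], subj_idx, J, gh)
  lr <- 2 * (null$value - full$value)
  p_overall <- pchisq(max(lr, 0), df = ncol(X), lower.tail = FALSE)

  theta <- cumsum(c(full$par[1], if (J > 2) exp(full$par[2:(J - 1)])))
  beta <- setNames(full$par[(J - 1) + seq_len(ncol(X))], colnames(X))
  structure(
    list(coef = beta, thresholds = setNames(theta, paste(lev[-J], lev[-1], sep = "|")),
         sigma = exp(full$par[length(full$par)]),
         p_overall = p_overall, logLik = -full$value,
         n_subjects = nlevels(subj), convergence = full$convergence),
    class = "ordinal_time_effect"
  )
}

#' @export
print.ordinal_time_effect <- function(x, ...) {
  cat("<ordinal_time_effect> overall P =",
      format.pval(x$p_overall, digits = 3),
      "| time log-odds:", paste(names(x$coef), round(x$coef, 3),
                                collapse = ", "),
      "| sigma =", round(x$sigma, 3), "\n")
  invisible(x)
}

#' Pearson correlations between change scores
#'
#' Pairwise Pearson correlations (with two-sided p-values) between
#' per-subject change scores, e.g. dietary deltas against metabolic deltas.
#' Significant correlations are additionally screened for fragility: a
#' correlation whose significance vanishes when the single most influential
#' subject is removed is flagged (`fragile`), replacing the study
#' convention of visual scatterplot confirmation with an explicit
#' diagnostic.
#'
#' @param deltas_a,deltas_b Data frames of per-subject changes, rows
#'   aligned (same subjects), at least 3 rows.
#' @param alpha Significance level for the fragility screen.
#' @param influence Run the leave-one-out fragility screen (default
#'   `TRUE`).
#' @return Tibble `var_a`, `var_b`, `n`, `rho`, `p`, `fragile`.
#' @export
delta_correlations <- function(deltas_a, deltas_b, alpha = 0.05,
                               influence = TRUE) {
  deltas_a <- as.data.frame(deltas_a)
  deltas_b <- as.data.frame(deltas_b)
  if (nrow(deltas_a) != nrow(deltas_b)) abort("deltas must be paired")
  if (nrow(deltas_a) < 3) abort("need at least 3 paired subjects")
  grid <- expand.grid(var_a = names(deltas_a), var_b = names(deltas_b),
                      stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    x <- deltas_a[[grid$var_a[i]]]
    y <- deltas_b[[grid$var_b[i]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) abort("fewer than 3 complete pairs")
    if (var(x) == 0 || var(y) == 0) abort("zero variance in a delta vector")
    ct <- cor.test(x, y, method = "pearson")
    fragile <- NA
    if (influence && ct$p.value < alpha && length(x) > 3) {
      loo <- vapply(seq_along(x), function(j) {
        cor.test(x[-j], y[-j], method = "pearson")$p.value
      }, numeric(1))
      fragile <- max(loo) > alpha
    }
    tibble::tibble(var_a = grid$var_a[i], var_b = grid$var_b[i],
                   n = length(x), rho = unname(ct$estimate),
                   p = ct$p.value, fragile = fragile)
  })
}

#' Subset longitudinal records by behavior-change strategy
#'
#' Keeps only the records of participants whose strategy includes the given
#' food category -- the per-category analysis population.
#'
#' @param records Data frame with `participant_id`.
#' @param strategies Tibble `participant_id`, `category`.
#' @param category One of [dhdi_categories].
#' @return Filtered records; attribute `n_strategy` carries the number of
#'   retained participants.
#' @export
subset_by_strategy <- function(records, strategies, category) {
  ids <- unique(strategies$participant_id[strategies$category == category])
  out <- records[records$participant_id %in% ids, , drop = FALSE]
  attr(out, "n_strategy") <- length(ids)
  out
}

#' Paired sample size for a mean change
#'
#' Sample size needed to detect a mean within-subject change `delta` with
#' SD `sd` at the given significance level and power (one-sample t test on
#' the change scores).
#'
#' @param delta Expected mean change.
#' @param sd SD of the change scores.
#' @param sig_level Significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param two_sided Two-sided test (default `TRUE`).
#' @return Required number of subjects (rounded up).
#' @export
sample_size_paired <- function(delta, sd, sig_level = 0.05, power = 0.8,
                               two_sided = TRUE) {
  res <- power.t.test(delta = delta, sd = sd, sig.level = sig_level,
                      power = power, type = "one.sample",
                      alternative = if (two_sided) "two.sided" else "one.sided")
  ceiling(res$n)
}
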