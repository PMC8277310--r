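# Shared fixture builders (everything is generated in code).

# Single-outcome trajectory spec with non-binding bounds, for clean checks
# of the longitudinal generator's convergence properties.
one_outcome_spec <- function(delta8, delta16, baseline = 52.9, sd = 3,
                             icc = 0.6, weeks = c(0, 8, 16)) {
  trajectory_spec(tibble::tibble(
    outcome = "y", baseline_mean = baseline, baseline_sd = sd,
    lower = -Inf, upper = Inf,
    delta_wk8 = delta8, delta_wk16 = delta16,
    icc = icc, type = "continuous", strategy_category = NA_character_,
    weeks = list(weeks)
  ))
}

# A screening-clean subject row (all panels far from every threshold).
clean_subject <- function(id = "S1", sex = "F", bmi = 22,
                          triglycerides = 1.0, ldl = 2.5, hdl = 1.8,
                          glucose = 4.8, c_peptide = 0.4) {
  tibble::tibble(
    participant_id = id, sex = sex, bmi = bmi,
    waist = if (sex == "F") 75 else 85,
    sbp = 115, dbp = 70,
    triglycerides = triglycerides, ldl = ldl, hdl = hdl,
    glucose = glucose, c_peptide = c_peptide
  )
}

# Random diet profile (8 category scores, optional carotenoids).
random_profile <- function(carotenoids = NULL) {
  pr <- stats::setNames(stats::runif(8, 1, 10), dhdi_categories)
  if (!is.null(carotenoids)) pr <- c(pr, carotenoids = carotenoids)
  pr
}

# Random flag row with consistent n_secondary.
random_flags <- function() {
  f <- as.logical(stats::rbinom(5, 1, 0.5))
  tibble::tibble(
    waist_excessive = f[1], tg_high = f[2], hdl_low = f[3],
    bp_high = f[4], glucose_high = f[5],
    n_secondary = sum(f[2:5])
  )
}

# Brute-force BH step-up, written independently of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force rho: all m beta order-statistic probabilities via the
# binomial-tail identity P(Beta(k, m-k+1) <= r) = P(Binom(m, r) >= k).
rra_oracle <- function(r) {
  m <- length(r)
  r <- sort(r)
  probs <- vapply(seq_len(m), function(k) {
    j <- k:m
    sum(choose(m, j) * r[k]^j * (1 - r[k])^(m - j))
  }, numeric(1))
  min(probs)
}

# Longitudinal Likert data from a latent-normal shift model.
likert_sim <- function(n, shift, seed) {
  withr::with_seed(seed, {
    lat0 <- stats::rnorm(n, 4.7, 1.1)
    u <- stats::rnorm(n, 0, 0.8)
    y0 <- pmin(pmax(round(lat0 + u), 1), 7)
    y1 <- pmin(pmax(round(lat0 + shift + u + stats::rnorm(n, 0, 0.6)), 1), 7)
    tibble::tibble(
      participant_id = rep(sprintf("P%03d", seq_len(n)), 2),
      week = rep(c(0, 16), each = n),
      value = c(y0, y1)
    )
  })
}
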