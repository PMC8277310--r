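make_long <- function(mat, weeks = c(0, 8, 16)) {
  n <- nrow(mat)
  tibble::tibble(
    participant_id = rep(sprintf("P%03d", seq_len(n)), times = ncol(mat)),
    week = rep(weeks, each = n),
    value = as.vector(mat)
  )
}

test_that("BH adjustment matches hand and brute-force step-up computations", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  withr::with_seed(70, {
    for (i in 1:200) {
      p <- runif(sample(1:6, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-12 & adj <= 1))
      # order invariance
      o <- sample(length(p))
      expect_equal(bh_adjust(p[o]), adj[o])
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mixed-model contrasts on balanced complete data equal paired mean differences", {
  withr::with_seed(71, {
    n <- 25
    u <- rnorm(n, 0, 3)
    mat <- cbind(50 + u + rnorm(n), 53 + u + rnorm(n), 55 + u + rnorm(n))
  })
  fit <- fit_time_mixed_model(make_long(mat), outlier_rule = FALSE)
  c016 <- fit$contrasts[fit$contrasts$week_a == 0 & fit$contrasts$week_b == 16, ]
  expect_equal(c016$estimate, mean(mat[, 3] - mat[, 1]), tolerance = 1e-6)
  expect_equal(fit$emm$mean, colMeans(mat), tolerance = 1e-6)
  # adjusted p never below raw p, capped at 1
  expect_true(all(fit$contrasts$p_adj >= fit$contrasts$p - 1e-12))
  expect_true(all(fit$contrasts$p_adj <= 1))
})

test_that("a pure subject offset without time structure gives a null time effect", {
  mat <- rbind(c(5, 5, 5), c(9, 9, 9), c(7, 7, 7))
  fit <- fit_time_mixed_model(make_long(mat))
  expect_equal(unname(diff(fit$emm$mean)), c(0, 0), tolerance = 1e-8)
  expect_gt(fit$p_overall, 0.9)
})

test_that("the 3xRMSE outlier rule is strict and scale-equivariant", {
  res <- c(0, 1, -1, 3, -3.1)
  rmse <- 1
  expect_equal(flag_outliers(res, rmse), 5L)        # 3.0 not flagged, 3.1 is
  expect_equal(flag_outliers(rep(0, 10), 0), integer(0))

  withr::with_seed(72, {
    n <- 30
    u <- rnorm(n, 0, 2)
    mat <- cbind(50 + u + rnorm(n), 52 + u + rnorm(n), 54 + u + rnorm(n))
    mat[3, 2] <- 90  # gross outlier
  })
  fit1 <- fit_time_mixed_model(make_long(mat))
  expect_true(nrow(fit1$outliers) >= 1)
  expect_true("P003" %in% fit1$outliers$participant_id)
  fit2 <- fit_time_mixed_model(make_long(mat * 10))
  expect_equal(fit1$outliers, fit2$outliers)
})

test_that("degenerate longitudinal inputs are rejected", {
  mat <- rbind(c(5, 5, 5), c(5, 5, 5))
  expect_error(fit_time_mixed_model(make_long(mat)), "constant")
  one <- tibble::tibble(participant_id = "P1", week = c(0, 16), value = c(1, 2))
  expect_error(fit_time_mixed_model(one), "two subjects")
  dup <- tibble::tibble(participant_id = c("P1", "P1", "P2"),
                        week = c(0, 0, 0), value = 1:3)
  expect_error(fit_time_mixed_model(dup), "one value per")
})

test_that("ordinal mixed regression detects a latent shift and respects degeneracy", {
  up <- fit_ordinal_mixed(likert_sim(200, shift = 1, seed = 73))
  expect_gt(up$coef[["week16"]], 0)
  expect_lt(up$p_overall, 0.05)

  null <- fit_ordinal_mixed(likert_sim(200, shift = 0, seed = 74))
  expect_gt(null$p_overall, 0.01)
  expect_lt(abs(null$coef[["week16"]]), 1)

  flat <- tibble::tibble(participant_id = rep(sprintf("P%02d", 1:10), 2),
                         week = rep(c(0, 16), each = 10), value = 4)
  expect_error(fit_ordinal_mixed(flat), "identical")

  gap <- tibble::tibble(participant_id = rep(sprintf("P%02d", 1:20), 2),
                        week = rep(c(0, 16), each = 20),
                        value = rep(c(1, 1, 5, 5), 10))
  expect_warning(fit_ordinal_mixed(gap), "collapsed")
})

test_that("delta correlations recover exact linear relations and flag fragile ones", {
  a <- data.frame(x = c(1, 2, 3, 4))
  expect_equal(delta_correlations(a, data.frame(y = c(1, 2, 3, 4)))$rho, 1)
  expect_equal(delta_correlations(a, data.frame(y = -c(1, 2, 3, 4)))$rho, -1)
  expect_equal(delta_correlations(data.frame(x = c(1, 2, 3)),
                                  data.frame(y = c(2, 4, 6)),
                                  influence = FALSE)$rho, 1)
  expect_error(delta_correlations(a, data.frame(y = rep(1, 4))), "variance")
  expect_error(delta_correlations(a[1:2, , drop = FALSE],
                                  data.frame(y = c(1, 2))), "3 paired")

  # significance driven by one extreme pair is flagged as fragile
  withr::with_seed(75, {
    x <- c(rnorm(12), 20)
    y <- c(rnorm(12), 20)
  })
  res <- delta_correlations(data.frame(x = x), data.frame(y = y))
  expect_lt(res$p, 0.05)
  expect_true(res$fragile)

  # a broad-based strong correlation is not fragile
  withr::with_seed(76, {
    x2 <- rnorm(30)
    y2 <- x2 + rnorm(30, 0, 0.4)
  })
  res2 <- delta_correlations(data.frame(x = x2), data.frame(y = y2))
  expect_false(res2$fragile)
})

test_that("strategy subsetting keeps exactly the participants working on the category", {
  records <- tibble::tibble(participant_id = rep(sprintf("P%d", 1:5), each = 3),
                            week = rep(c(0, 8, 16), 5), value = 1)
  strategies <- tibble::tibble(
    participant_id = c("P1", "P2", "P4", "P1"),
    category = c("nuts", "nuts", "nuts", "fish")
  )
  nuts <- subset_by_strategy(records, strategies, "nuts")
  expect_setequal(unique(nuts$participant_id), c("P1", "P2", "P4"))
  expect_equal(attr(nuts, "n_strategy"), 3)
  none <- subset_by_strategy(records, strategies, "dairy")
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_strategy"), 0)
  all_in <- subset_by_strategy(records,
                               tibble::tibble(participant_id = sprintf("P%d", 1:5),
                                              category = "fruit"), "fruit")
  expect_equal(nrow(all_in), nrow(records))
})

test_that("paired sample-size utility behaves sensibly", {
  n1 <- sample_size_paired(1.85, 2.67)
  expect_true(n1 >= 2 && n1 == ceiling(n1))
  # more power or smaller effects need more subjects
  expect_gt(sample_size_paired(1.85, 2.67, power = 0.95), n1)
  expect_gt(sample_size_paired(0.9, 2.67), n1)
  # one-sided needs fewer
  expect_lt(sample_size_paired(1.85, 2.67, two_sided = FALSE), n1)
})
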