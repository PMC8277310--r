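test_that("rank normalization puts the healthiest value on the smallest rank", {
  expect_equal(normalize_ranks(c(1.6, 1.0, 1.2), "higher"),
               c(1 / 3, 1, 2 / 3))
  expect_equal(normalize_ranks(c(1.6, 1.0, 1.2), "lower"),
               c(1, 1 / 3, 2 / 3))
  expect_equal(normalize_ranks(5, "lower"), 1)
  expect_equal(normalize_ranks(rep(2, 4), "higher"), rep(0.625, 4))
  expect_error(normalize_ranks(numeric(0)), "empty")
})

test_that("rra_rho equals the beta order-statistic minimum", {
  expect_equal(rra_rho(0.1), 0.1)                   # m = 1: identity
  expect_equal(rra_rho(c(0.2, 0.5)), 0.25)          # min(1-(1-.2)^2, .5^2)
  expect_equal(rra_rho(c(0.5, 0.2)), 0.25)          # order-free input

  withr::with_seed(77, {
    for (i in 1:200) {
      m <- sample(1:6, 1)
      r <- runif(m)
      expect_equal(rra_rho(r), rra_oracle(r), tolerance = 1e-12)
    }
  })
  expect_error(rra_rho(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(rra_rho(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("m * rho is a conservative (super-uniform) p-value under uniform ranks", {
  withr::with_seed(99, {
    m <- 5
    rho <- replicate(4000, rra_rho(runif(m)))
    for (alpha in c(0.05, 0.1, 0.25)) {
      expect_lte(mean(m * rho <= alpha), alpha + 0.02)
    }
  })
})

test_that("healthy-reference selection matches brute-force enumeration", {
  withr::with_seed(10, {
    pool <- dplyr::bind_rows(lapply(1:20, function(i) {
      clean_subject(id = sprintf("S%02d", i),
                    sex = sample(c("M", "F"), 1),
                    triglycerides = runif(1, 0.5, 1.6),
                    ldl = runif(1, 1.5, 3.5),
                    hdl = runif(1, 1.3, 2.2),
                    glucose = runif(1, 4, 5.5),
                    c_peptide = runif(1, 0.2, 0.7))
    }))
  })
  sel <- select_healthy_reference(pool, n_top = 5)
  # brute force: rho over the whole eligible pool, directly
  dirs <- default_rank_directions()
  rho_all <- vapply(seq_len(nrow(pool)), function(i) {
    r <- vapply(names(dirs), function(f) {
      normalize_ranks(pool[[f]], dirs[[f]])[i]
    }, numeric(1))
    rra_oracle(r)
  }, numeric(1))
  want <- pool$participant_id[order(rho_all, pool$participant_id)][1:5]
  expect_equal(sel$participant_id, want)

  # a dominating subject ranks first
  pool2 <- pool
  pool2[1, c("triglycerides", "ldl", "glucose", "c_peptide")] <- 0.1
  pool2$hdl[1] <- 3
  expect_equal(select_healthy_reference(pool2, 1)$participant_id,
               pool2$participant_id[1])

  # n_top = pool size returns the whole eligible pool
  expect_equal(nrow(select_healthy_reference(pool, nrow(pool))), nrow(pool))
  expect_error(select_healthy_reference(pool, nrow(pool) + 1), "eligible")
})

test_that("selection is invariant to strictly monotone feature transforms", {
  withr::with_seed(20, {
    pool <- dplyr::bind_rows(lapply(1:15, function(i) {
      clean_subject(id = sprintf("S%02d", i),
                    triglycerides = runif(1, 0.5, 1.6),
                    ldl = runif(1, 1.5, 3.5), hdl = runif(1, 1.3, 2.2),
                    glucose = runif(1, 4, 5.5), c_peptide = runif(1, 0.2, 0.7))
    }))
  })
  sel1 <- select_healthy_reference(pool, 4)$participant_id
  pool2 <- pool
  pool2$c_peptide <- exp(pool2$c_peptide)  # strictly increasing, stays in bounds
  sel2 <- select_healthy_reference(pool2, 4)$participant_id
  expect_equal(sel1, sel2)
})

test_that("MetS reference selection applies the central-obesity-plus-two rule", {
  pool <- dplyr::bind_rows(
    clean_subject("A"),
    # waist + 2 secondary
    dplyr::mutate(clean_subject("B", sex = "F"), waist = 95,
                  triglycerides = 2.0, glucose = 6.0),
    # waist + 1 secondary only
    dplyr::mutate(clean_subject("C", sex = "F"), waist = 95,
                  triglycerides = 2.0)
  )
  expect_equal(select_mets_reference(pool)$participant_id, "B")
  empty <- pool[0, ]
  expect_equal(nrow(select_mets_reference(empty)), 0)
})

test_that("separable reference groups are classified perfectly", {
  withr::with_seed(30, {
    healthy <- dplyr::bind_rows(lapply(1:40, function(i) {
      clean_subject(sprintf("H%02d", i), sex = sample(c("M", "F"), 1),
                    triglycerides = runif(1, 0.5, 1.0), ldl = runif(1, 1.5, 2.5),
                    hdl = runif(1, 1.8, 2.4), glucose = runif(1, 4, 4.8),
                    c_peptide = runif(1, 0.2, 0.4))
    }))
    mets <- dplyr::bind_rows(lapply(1:40, function(i) {
      clean_subject(sprintf("M%02d", i), sex = sample(c("M", "F"), 1),
                    triglycerides = runif(1, 2.5, 4), ldl = runif(1, 3.5, 5),
                    hdl = runif(1, 0.6, 0.9), glucose = runif(1, 6.5, 9),
                    c_peptide = runif(1, 1.2, 2))
    }))
  })
  model <- fit_health_space(healthy, mets)
  sc <- rbind(predict_score(model, healthy), predict_score(model, mets))
  met <- classification_metrics(rep(c("healthy", "mets"), each = 40), sc$score)
  expect_equal(met$accuracy, 1)
  expect_equal(met$kappa, 1)
})

test_that("identically distributed groups give near-zero coefficients and midpoint scores", {
  spec <- default_cohort_spec("healthy-reference")
  a <- generate_reference_pool(spec, 300, seed = 41)
  b <- generate_reference_pool(spec, 300, seed = 42)
  model <- fit_health_space(a, b, random = "none")
  expect_true(all(abs(model$coef[health_space_features]) < 0.1))
  sc <- predict_score(model, a)
  expect_lt(abs(mean(sc$score) - 1.5), 0.1)
})

test_that("the projection is affine with monotone response to each biomarker", {
  h <- generate_reference_pool(default_cohort_spec("healthy-reference"), 150, seed = 1)
  m <- generate_reference_pool(default_cohort_spec("mets-reference"), 150, seed = 2)
  model <- fit_health_space(h, m)

  base <- clean_subject("X")
  grid <- seq(0.8, 2.4, by = 0.2)
  scores <- vapply(grid, function(v) {
    row <- base; row$hdl <- v
    predict_score(model, row)$score
  }, numeric(1))
  # strictly monotone in HDL with a positive HDL coefficient, and affine
  expect_gt(model$coef[["hdl"]], 0)
  expect_true(all(diff(scores) > 0))
  slopes <- diff(scores) / diff(grid)
  expect_true(all(abs(slopes - slopes[1]) < 1e-8))

  # hand-built zero model returns its intercept for any input
  null_model <- model
  null_model$coef[health_space_features] <- 0
  null_model$coef["(Intercept)"] <- 1.5
  null_model$sex_coef <- list()
  expect_equal(predict_score(null_model, base)$score, 1.5)
})

test_that("swapping the class coding reflects scores about the midpoint", {
  h <- generate_reference_pool(default_cohort_spec("healthy-reference"), 100, seed = 3)
  m <- generate_reference_pool(default_cohort_spec("mets-reference"), 100, seed = 4)
  ab <- fit_health_space(h, m, random = "none")
  ba <- fit_health_space(m, h, random = "none")
  s1 <- predict_score(ab, h)$score
  s2 <- predict_score(ba, h)$score
  expect_equal(s1 - 1.5, 1.5 - s2, tolerance = 1e-8)
})

test_that("single-sex training degrades gracefully to a fixed-only fit", {
  h <- generate_reference_pool(default_cohort_spec("healthy-reference"), 80, seed = 5)
  m <- generate_reference_pool(default_cohort_spec("mets-reference"), 80, seed = 6)
  h$sex <- "F"; m$sex <- "F"
  expect_warning(model <- fit_health_space(h, m), "one sex")
  expect_equal(model$random, "none")
  # unknown sex at prediction time falls back to population coefficients
  full <- fit_health_space(
    generate_reference_pool(default_cohort_spec("healthy-reference"), 80, seed = 7),
    generate_reference_pool(default_cohort_spec("mets-reference"), 80, seed = 8))
  row <- clean_subject("X"); row$sex <- NA
  expect_warning(predict_score(full, row), "population")
})

test_that("classification metrics reproduce hand-computed accuracy and kappa", {
  # confusion [[45, 5], [5, 45]]: p_o = 0.9, p_e = 0.5, kappa = 0.8
  truth <- rep(c("healthy", "mets"), each = 50)
  scores <- c(rep(1.9, 45), rep(1.1, 5), rep(1.1, 45), rep(1.9, 5))
  met <- classification_metrics(truth, scores)
  expect_equal(met$accuracy, 0.9)
  expect_equal(met$kappa, 0.8)

  perfect <- classification_metrics(truth, c(rep(2, 50), rep(1, 50)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)

  # prediction independent of truth with balanced marginals: kappa ~ 0
  withr::with_seed(50, {
    sc <- sample(c(1.1, 1.9), 2000, replace = TRUE)
    met0 <- classification_metrics(rep(c("healthy", "mets"), 1000), sc)
    expect_lt(abs(met0$kappa), 0.05)
  })
  expect_error(classification_metrics(rep("healthy", 5), rep(1.9, 5)), "one class")
})

test_that("a fitted model round-trips through JSON", {
  h <- generate_reference_pool(default_cohort_spec("healthy-reference"), 60, seed = 9)
  m <- generate_reference_pool(default_cohort_spec("mets-reference"), 60, seed = 10)
  model <- fit_health_space(h, m)
  path <- withr::local_tempfile(fileext = ".json")
  write_health_space(model, path)
  back <- read_health_space(path)
  expect_equal(predict_score(back, h)$score, predict_score(model, h)$score,
               tolerance = 1e-12)
})
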