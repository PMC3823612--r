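test_that("an exact linear relation is recovered exactly", {
  d <- data.frame(y = 2 * (1:20), x = 1:20)
  res <- suppressWarnings(linear_assoc(d, "y", "x"))
  expect_equal(res$beta, 2)
  expect_lt(res$p, 1e-12)
  expect_equal(res$n, 20L)
})

test_that("OLS engine matches the normal-equation closed form", {
  set.seed(21)
  n <- 40
  d <- data.frame(x = stats::rnorm(n), c1 = stats::rnorm(n),
                  c2 = stats::rnorm(n))
  d$y <- 1 + 0.5 * d$x - 0.3 * d$c1 + stats::rnorm(n)
  res <- linear_assoc(d, "y", "x", covariates = c("c1", "c2"))
  X <- cbind(1, d$x, d$c1, d$c2)
  XtXi <- solve(crossprod(X))
  bhat <- XtXi %*% crossprod(X, d$y)
  s2 <- sum((d$y - X %*% bhat)^2) / (n - 4)
  expect_equal(res$beta, bhat[2], tolerance = 1e-10)
  expect_equal(res$se, sqrt(s2 * XtXi[2, 2]), tolerance = 1e-10)
})

test_that("an independent exposure shows no association", {
  set.seed(22)
  d <- data.frame(y = stats::rnorm(5000), x = stats::rnorm(5000))
  res <- linear_assoc(d, "y", "x")
  expect_lt(abs(res$beta), 4 * res$se)
})

test_that("rank-deficient designs and tiny samples are fatal", {
  d <- data.frame(y = stats::rnorm(10), x = 1:10, x2 = 1:10)
  expect_error(linear_assoc(d, "y", "x", covariates = "x2"),
               "rank-deficient")
  expect_error(linear_assoc(d[1:2, ], "y", "x", covariates = "x2"),
               "too few")
  expect_error(linear_assoc(d, "y", "missing_col"), "not found")
})

test_that("milestone adjustment behaves in the no-confounding limits", {
  set.seed(23)
  n <- 800
  d <- data.frame(score = stats::rnorm(n))
  d$age_ar <- -0.04 * d$score + stats::rnorm(n)
  d$noise <- stats::rnorm(n)               # unrelated adjustment
  d$copy <- d$age_ar + stats::rnorm(n, 0, 1e-6)  # adjustment ~ outcome
  un <- linear_assoc(d, "age_ar", "score")
  adj <- milestone_adjusted_assoc(d, "age_ar", "score", partner = "noise")
  expect_lt(abs(adj$beta - un$beta), 2 * un$se)
  degen <- milestone_adjusted_assoc(d, "age_ar", "score", partner = "copy")
  expect_lt(abs(degen$beta), 1e-4)
})

test_that("attenuation appears when the partner mediates the score effect", {
  set.seed(24)
  n <- 2000
  score <- stats::rnorm(n)
  ## rebound BMI carries most of the score effect; rebound age responds to
  ## rebound BMI plus a small direct score effect -- adjusting for the
  ## partner then attenuates the marginal association
  d <- data.frame(score = score)
  d$bmi_ar <- 0.3 * score + stats::rnorm(n)
  d$age_ar <- -0.05 * score - 0.4 * d$bmi_ar + stats::rnorm(n, 0, 0.5)
  un <- linear_assoc(d, "age_ar", "score")
  adj <- milestone_adjusted_assoc(d, "age_ar", "score", partner = "bmi_ar")
  expect_lt(abs(adj$beta), abs(un$beta))
  expect_lt(abs(adj$beta - (-0.05)), 3 * adj$se)
})

test_that("final BMI extraction takes the last measure in the window", {
  g <- data.frame(
    individual_id = c("a", "a", "a", "b", "c"),
    sex = "female",
    age = c(14.0, 15.2, 16.9, 15.5, 14.9),
    measure = "bmi",
    value = c(20, 21, 22.5, 19.5, 23),
    stringsAsFactors = FALSE)
  fb <- final_bmi_values(g)
  expect_equal(fb$final_bmi[fb$individual_id == "a"], 22.5)
  expect_equal(fb$final_bmi[fb$individual_id == "b"], 19.5)
  expect_false("c" %in% fb$individual_id)  # no measure in [15, 17.5]
})

test_that("self-regression of final BMI gives R-squared one", {
  g <- data.frame(individual_id = as.character(1:50), sex = "female",
                  age = 16, measure = "bmi",
                  value = stats::rnorm(50, 21, 2))
  ms <- data.frame(individual_id = as.character(1:50),
                   kind = "adiposity_rebound", age = 5.5,
                   bmi = g$value, valid = TRUE,
                   reason_invalid = NA_character_)
  res <- suppressWarnings(final_bmi_assoc(ms, g, "bmi"))
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$beta, 1, tolerance = 1e-12)
  ## an independent milestone explains essentially nothing
  ms$bmi <- stats::rnorm(50)
  res0 <- final_bmi_assoc(ms, g, "bmi")
  expect_lt(res0$r_squared, 0.15)
})

test_that("variance explained is zero when the fits coincide", {
  fit <- cached_fit()
  ve <- variance_explained_curve(fit, fit)
  expect_equal(ve$overall, 0)
  expect_true(all(ve$by_age$r2 == 0))
  expect_true(all(ve$by_age$r2 >= 0 & ve$by_age$r2 <= 1))
})

test_that("score terms explain a positive share of BMI variance", {
  cc <- cached_cohort()
  fit <- cached_fit()
  spec0 <- growth_model_spec("bmi", genetic = "none",
                             covariates = "source01", sex = "female",
                             min_individuals = 20)
  fit0 <- fit_growth_model(cc$growth, spec0)
  ve <- variance_explained_curve(fit, fit0)
  expect_gt(ve$overall, 0)
  expect_lt(ve$overall, 0.1)
  expect_true(all(ve$by_age$r2 <= 1))
})
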