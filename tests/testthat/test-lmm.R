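## small clinic-only fits used for likelihood-level checks
cached_small <- function() {
  if (is.null(.cache$small)) {
    params <- simulation_params("raine", n = 150, seed = 3)
    cohort <- simulate_cohort(params)
    growth <- flag_implausible(cohort$growth, full_age_bin_scheme())$growth
    score <- compute_allelic_score(cohort$panel)
    spec <- growth_model_spec("bmi", genetic = "score",
                              covariates = character(), sex = "female",
                              min_individuals = 20)
    spec0 <- growth_model_spec("bmi", genetic = "none",
                               covariates = character(), sex = "female",
                               min_individuals = 20)
    .cache$small <- list(
      growth = growth, score = score,
      full_ml = fit_growth_model(growth, spec, score = score,
                                 method = "ML"),
      red_ml = fit_growth_model(growth, spec0, method = "ML"))
  }
  .cache$small
}

test_that("the fitted model carries coherent dimensions and parameters", {
  fit <- cached_fit()
  expect_true(fit$converged)
  expect_gte(model_rho(fit), 0)
  expect_lt(model_rho(fit), 1)
  G <- model_G(fit)
  expect_true(isSymmetric(G, tol = 1e-8))
  expect_true(all(eigen(G, only.values = TRUE)$values > -1e-8))
  expect_equal(model_aic(fit),
               -2 * as.numeric(logLik(fit)) +
                 2 * attr(logLik(fit), "df"))
  expect_equal(nrow(model_blups(fit)), fit$n_individuals)
})

test_that("hand-rolled marginal log-likelihood matches the fitting engine", {
  sm <- cached_small()
  expect_equal(marginal_log_lik(sm$full_ml),
               as.numeric(logLik(sm$full_ml)), tolerance = 1e-8)
  expect_equal(marginal_log_lik(sm$red_ml),
               as.numeric(logLik(sm$red_ml)), tolerance = 1e-8)
})

test_that("likelihood-ratio test behaves on nested, identical and non-ML fits", {
  sm <- cached_small()
  lrt <- lrt_genetic_effect(sm$full_ml, sm$red_ml)
  expect_gte(lrt$deviance, 0)
  expect_equal(lrt$df, 7L)   # score main effect + 6 basis interactions
  expect_gt(lrt$p, 0)
  expect_lte(lrt$p, 1)
  expect_equal(lrt$p,
               stats::pchisq(lrt$deviance, lrt$df, lower.tail = FALSE))
  same <- lrt_genetic_effect(sm$full_ml, sm$full_ml)
  expect_equal(same$deviance, 0)
  expect_equal(same$p, 1)
  expect_error(lrt_genetic_effect(sm$red_ml, sm$full_ml), "nested")
  expect_error(lrt_genetic_effect(cached_fit(), sm$red_ml), "ML")
})

test_that("genetic effect at an age equals the prediction difference", {
  fit <- cached_fit()
  d1 <- fit$prep$data[1, , drop = FALSE]
  spec <- fit$spec
  for (age in c(2.5, 8, 15)) {
    B <- eval_basis(spec$basis, age)
    nd <- d1[c(1, 1), ]
    for (cn in setdiff(colnames(B), "const")) nd[[cn]] <- B[1, cn]
    nd$source01 <- 0
    nd$gen <- c(30, 31)
    for (cn in setdiff(colnames(B), "const"))
      nd[[paste0("gen_", cn)]] <- nd$gen * nd[[cn]]
    pr <- predict(fit$lme, newdata = nd, level = 0)
    est <- effect_at_age(fit, age)
    expect_equal(unname(est["beta"]), unname(diff(pr)), tolerance = 1e-8)
    expect_gt(est["se"], 0)
  }
  expect_error(effect_at_age(fit, 25), "outside")
})

test_that("individual curves reproduce the model's fitted values", {
  fit <- cached_fit()
  d <- fit$prep$data
  fv <- stats::fitted(fit$lme, level = 1)
  beta <- model_fixef(fit)
  ids <- head(levels(d$id), 15)
  for (id in ids) {
    rows <- which(d$id == id)
    curve <- individual_curve(fit, id)
    pred <- evaluate_curve(curve, d$age[rows]) +
      beta["source01"] * d$source01[rows]
    expect_equal(unname(pred), unname(fv[rows]), tolerance = 1e-6)
  }
  ## population-average curve: zero BLUPs
  id <- ids[1]
  pc <- individual_curve(fit, id, blup = FALSE)
  ic <- individual_curve(fit, id)
  re <- model_blups(fit)[id, ]
  offset_diff <- evaluate_curve(ic, 8) - evaluate_curve(pc, 8)
  expect_equal(offset_diff,
               re[["(Intercept)"]] + 216 * re[["tp2_3"]], tolerance = 1e-8)
  expect_error(individual_curve(fit, "nobody"), "unknown individual")
})

test_that("likelihood is invariant to rescaling the genetic exposure", {
  sm <- cached_small()
  fit10 <- fit_growth_model(sm$growth, sm$full_ml$spec,
                            score = sm$score / 10, method = "ML")
  expect_equal(as.numeric(logLik(fit10$lme)),
               as.numeric(logLik(sm$full_ml$lme)), tolerance = 1e-4)
  expect_equal(unname(model_fixef(fit10)["gen"]),
               unname(10 * model_fixef(sm$full_ml)["gen"]),
               tolerance = 1e-4)
})

test_that("independent-residual data yield a near-zero CAR(1) estimate", {
  params <- simulation_params("raine", n = 400, seed = 13, rho = 0)
  cohort <- simulate_cohort(params)
  growth <- flag_implausible(cohort$growth, full_age_bin_scheme())$growth
  spec <- growth_model_spec("bmi", genetic = "none", sex = "female",
                            min_individuals = 20)
  fit <- fit_growth_model(growth, spec)
  expect_lt(model_rho(fit), 0.1)
})

test_that("children with fewer observations have more strongly shrunken BLUPs", {
  fit <- cached_fit()
  re <- model_blups(fit)
  nobs <- table(fit$prep$data$id)[rownames(re)]
  expect_gt(stats::cor(as.numeric(nobs), abs(re[["(Intercept)"]])), 0)
})
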