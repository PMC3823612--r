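cached_big_sim <- function() {
  if (is.null(.cache$bigsim)) {
    params <- simulation_params("alspac", n = 2000, seed = 2)
    .cache$bigsim <- simulate_cohort(params)
  }
  .cache$bigsim
}

test_that("identical parameters give byte-identical cohorts", {
  p <- simulation_params("raine", n = 50, seed = 99)
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(c1$growth, c2$growth)
  expect_identical(c1$panel$dosages, c2$panel$dosages)
  expect_identical(c1$info, c2$info)
  ## different seed, different data
  c3 <- simulate_cohort(simulation_params("raine", n = 50, seed = 100))
  expect_false(identical(c1$growth$value, c3$growth$value))
})

test_that("population curves pass through their calibration anchors", {
  for (sx in c("female", "male")) {
    pop <- population_bmi_curve(sx)
    ap <- find_adiposity_peak(pop)
    ar <- find_adiposity_rebound(pop)
    an <- bmigrowth:::growth_anchors[[sx]]
    expect_true(ap$valid)
    expect_equal(ap$age, an$ap_age, tolerance = 1e-6)
    expect_equal(ap$bmi, an$ap_bmi, tolerance = 1e-6)
    expect_true(ar$valid)
    expect_equal(ar$age, an$ar_age, tolerance = 1e-6)
    expect_equal(ar$bmi, an$ar_bmi, tolerance = 1e-6)
    expect_equal(evaluate_curve(pop, 17), an$bmi17, tolerance = 1e-6)
    ## only the two designed stationary points in (0, 17.4)
    tg <- seq(0.01, 17.4, by = 0.001)
    d <- evaluate_curve(pop, tg, deriv = 1)
    expect_equal(sum(diff(sign(d)) != 0), 2)
  }
})

test_that("sampled effect allele frequencies track the panel targets", {
  params <- simulation_params("alspac", n = 10000, seed = 5)
  panel <- simulate_genotypes(params)
  eaf <- effect_allele_frequency(panel)
  target <- params$eaf
  se <- sqrt(target * (1 - target) / (2 * params$n))
  expect_true(all(abs(eaf - target) < 4 * se + 0.003))
  ## degenerate frequency bounds are rejected
  expect_error(simulation_params("alspac", n = 10,
                                 eaf = stats::setNames(rep(0, 32),
                                                       names(target))))
})

test_that("a noise-free, effect-free cohort lies on the population curve", {
  params <- simulation_params(
    "alspac", n = 30, seed = 8,
    re_sd = c(const = 0, age_c = 0, age_c2 = 0, tp2_3 = 0),
    sigma = 0, g15 = 0, ar_shift = 0, ar_bmi_effect = 0,
    implausible_rate = 0, dosage_noise_sd = 0)
  cohort <- simulate_cohort(params)
  bmi <- cohort$growth[cohort$growth$measure == "bmi", ]
  for (sx in c("female", "male")) {
    rows <- bmi[bmi$sex == sx, ]
    if (nrow(rows) == 0) next
    mu <- evaluate_curve(population_bmi_curve(sx), rows$age)
    expect_lt(max(abs(rows$value - mu)), 0.0051)  # recorded to 2 decimals
  }
  ## all true milestones coincide with the population milestones
  gt <- ground_truth_milestones(cohort)
  ar <- gt[gt$kind == "adiposity_rebound", ]
  sexes <- cohort$truth$sex[match(ar$individual_id,
                                  rownames(cohort$panel$dosages))]
  for (sx in c("female", "male")) {
    expect_lt(diff(range(ar$age[sexes == sx])), 1e-9)
  }
})

test_that("within-child residual correlation decays like the CAR(1) target", {
  visits <- data.frame(age = 3:8, prob = 1, sd = 1e-6, source = "clinic",
                       stringsAsFactors = FALSE)
  params <- simulation_params("alspac", n = 1200, seed = 14,
                              visits = visits,
                              infancy_visits = visits[0, ],
                              implausible_rate = 0)
  cohort <- simulate_cohort(params)
  bmi <- cohort$growth[cohort$growth$measure == "bmi" &
                         cohort$growth$age > 1, ]
  truth <- vapply(seq_len(nrow(bmi)), function(i)
    evaluate_curve(cohort$truth$curves[[bmi$individual_id[i]]], bmi$age[i]),
    numeric(1))
  e <- bmi$value - truth
  em <- matrix(e, ncol = 6, byrow = TRUE)  # one row per child, ages 3..8
  lag1 <- mean(vapply(1:5, function(j) stats::cor(em[, j], em[, j + 1]),
                      numeric(1)))
  lag2 <- mean(vapply(1:4, function(j) stats::cor(em[, j], em[, j + 2]),
                      numeric(1)))
  expect_lt(abs(lag1 - params$rho), 0.05)
  expect_lt(abs(lag2 - params$rho^2), 0.06)
})

test_that("ground-truth milestones are the analytic extrema of true curves", {
  cohort <- cached_big_sim()
  gt <- ground_truth_milestones(cohort)
  ids <- names(cohort$truth$curves)[c(1, 50, 500, 1500)]
  for (id in ids) {
    cv <- cohort$truth$curves[[id]]
    expect_identical(gt[gt$individual_id == id &
                          gt$kind == "adiposity_peak", ]$age,
                     find_adiposity_peak(cv, id = id)$age)
    expect_identical(gt[gt$individual_id == id &
                          gt$kind == "adiposity_rebound", ]$age,
                     find_adiposity_rebound(cv, id = id)$age)
  }
})

test_that("true milestones and genetic shifts match the calibration", {
  cohort <- cached_big_sim()
  gt <- ground_truth_milestones(cohort)
  info <- cohort$info
  ar <- merge(gt[gt$kind == "adiposity_rebound" & gt$valid, ],
              info[c("individual_id", "sex")])
  expect_gt(nrow(ar), 1800)
  for (sx in c("female", "male")) {
    an <- bmigrowth:::growth_anchors[[sx]]
    expect_lt(abs(median(ar$age[ar$sex == sx]) - an$ar_age), 0.1)
  }
  ## regression of the true rebound age on the allelic score recovers the
  ## configured shift before any model fitting
  sc <- cohort$truth$score[ar$individual_id]
  fit <- stats::lm(ar$age ~ sc)
  est <- summary(fit)$coefficients[2, 1:2]
  expect_lt(abs(est[1] - (-0.036)), 3 * est[2])
})

test_that("measurement schedules match the two cohort templates", {
  cohort <- cached_big_sim()
  bmi <- cohort$growth[cohort$growth$measure == "bmi" &
                         cohort$growth$age >= 1, ]
  expect_equal(unname(stats::median(table(bmi$individual_id))), 9)
  expect_true(any(cohort$growth$source == "parental_report"))
  raine <- simulate_cohort(simulation_params("raine", n = 400, seed = 6))
  rbmi <- raine$growth[raine$growth$measure == "bmi" &
                         raine$growth$age >= 1, ]
  expect_equal(unname(stats::median(table(rbmi$individual_id))), 6)
  expect_true(all(raine$growth$source == "clinic"))
  ## the sparse 3--5.5 y gap of the clinic-only cohort
  expect_lt(mean(rbmi$age > 3.5 & rbmi$age < 5.5), 0.02)
})

test_that("weight, height and BMI records are mutually consistent", {
  cohort <- cached_big_sim()
  g <- cohort$growth[cohort$growth$age > 0, ]
  w <- g[g$measure == "weight", ]
  key <- paste(g$individual_id, g$age)
  h <- g[g$measure == "height", ][match(paste(w$individual_id, w$age),
                                        key[g$measure == "height"]), ]
  b <- g[g$measure == "bmi", ][match(paste(w$individual_id, w$age),
                                     key[g$measure == "bmi"]), ]
  implied <- w$value / (h$value / 100)^2
  ok <- is.finite(implied)
  ## agreement within rounding of the three recorded values
  expect_gt(mean(abs(implied[ok] - b$value[ok]) < 0.05), 0.99)
})
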