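## Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

## moderate synthetic cohort + QC + score, reused across test files
cached_cohort <- function() {
  if (is.null(.cache$cohort)) {
    params <- simulation_params("alspac", n = 400, seed = 1)
    cohort <- simulate_cohort(params)
    qc <- flag_implausible(cohort$growth, full_age_bin_scheme())
    .cache$cohort <- list(
      params = params, cohort = cohort, growth = qc$growth,
      score = compute_allelic_score(cohort$panel))
  }
  .cache$cohort
}

## female BMI model with allelic-score interactions on the cached cohort
cached_fit <- function() {
  if (is.null(.cache$fit)) {
    cc <- cached_cohort()
    spec <- growth_model_spec("bmi", genetic = "score",
                              covariates = "source01", sex = "female",
                              min_individuals = 20)
    .cache$fit <- fit_growth_model(cc$growth, spec, score = cc$score)
  }
  .cache$fit
}

## deterministic hand-made growth table
tiny_growth <- function() {
  data.frame(
    individual_id = rep(c("a", "b"), each = 3),
    sex = rep(c("female", "male"), each = 3),
    age = c(1.5, 3.0, 7.0, 2.0, 4.5, 8.0),
    measure = "bmi",
    value = c(16.5, 16.0, 15.8, 17.0, 16.2, 16.4),
    source = "clinic",
    cohort_id = "toy",
    stringsAsFactors = FALSE)
}

## random piecewise-cubic BMI-like curve on the childhood basis
random_bmi_curve <- function() {
  spec <- spline_spec("bmi")
  coef <- c(stats::rnorm(1, 16, 1), stats::rnorm(1, 0.2, 0.3),
            stats::rnorm(1, 0.02, 0.05), stats::rnorm(1, 0, 0.004),
            stats::rnorm(3, 0, 0.004))
  basis_curve(spec, coef, range = c(1, 17.5))
}

## grid-search oracle for curve extrema: locate every interior local
## minimum/maximum on a coarse 1e-3 grid, refine each on a 1e-5 grid, and
## return the one with the extreme value (the milestone selection rule).
## A piecewise cubic has finitely many local extrema, all wider than the
## coarse step, so the two-stage grid is exhaustive.
grid_extremum_oracle <- function(curve, window, type = c("min", "max")) {
  type <- match.arg(type)
  sgn <- if (type == "min") 1 else -1
  lo <- max(window[1], curve$breaks[1])
  hi <- min(window[2], curve$breaks[length(curve$breaks)])
  tg <- seq(lo, hi, by = 1e-3)
  v <- sgn * evaluate_curve(curve, tg)
  k <- length(v)
  cand <- which(v[2:(k - 1)] <= v[1:(k - 2)] & v[2:(k - 1)] <= v[3:k]) + 1L
  best <- NULL
  for (i in cand) {
    a <- max(lo, tg[i] - 2e-3); b <- min(hi, tg[i] + 2e-3)
    tf <- seq(a, b, by = 1e-5)
    vf <- sgn * evaluate_curve(curve, tf)
    j <- which.min(vf)
    ## refined point on the window edge is a clipped monotone trend, not a
    ## stationary point
    if (tf[j] <= lo + 1.1e-5 || tf[j] >= hi - 1.1e-5) next
    if (is.null(best) || vf[j] < best$obj) {
      best <- list(age = tf[j], value = sgn * vf[j], obj = vf[j])
    }
  }
  if (is.null(best)) return(list(found = FALSE))
  list(found = TRUE, age = best$age, value = best$value)
}
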