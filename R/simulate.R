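## Synthetic two-cohort generator.
##
## Each child's true BMI curve is a piecewise cubic, C^2 everywhere, built
## from two glued pieces:
##   * a childhood piece on [1, 17.5] expressed in the exact basis the
##     longitudinal model fits (cubic in centered age + cubic truncated
##     terms at 2, 8, 12 y), solved from descriptive anchors (BMI and slope
##     at 1 y, BMI and zero slope at the rebound, BMI at 10/13/17 y);
##   * an infancy piece on [0, 1] (cubic + truncated cubics at 0.5, 0.8,
##     0.9 y) solved from birth BMI, a mid-rise anchor, the adiposity peak
##     (value and zero slope) and second-order continuity with the
##     childhood piece at 1 y.
## The per-allele genetic effect g(t) lies in the span of the fitted
## model's interaction terms (g(t) = g1 t + g2 t^2 + g3 (t-2)_+^3) and is
## solved from three anchors: effect at 15 y, effect on BMI at the
## rebound, and the rebound age shift per allele (via the population
## curvature at the rebound).  Individual deviations are random effects on
## the model's default random columns; residuals follow a continuous AR(1)
## process in age.

growth_anchors <- list(
  male = list(bmi0 = 13.6, bmi035 = 16.2, ap_age = 8.90 / 12,
              ap_bmi = 18.03, bmi1 = 17.75, slope1 = -0.45,
              ar_age = 6.07, ar_bmi = 15.62, bmi10 = 17.8, bmi13 = 19.8,
              bmi17 = 23.0, ar_bmi_effect = 0.0364),
  female = list(bmi0 = 13.3, bmi035 = 15.8, ap_age = 9.36 / 12,
                ap_bmi = 17.45, bmi1 = 17.30, slope1 = -0.30,
                ar_age = 5.61, ar_bmi = 15.53, bmi10 = 17.6, bmi13 = 19.5,
                bmi17 = 22.4, ar_bmi_effect = 0.0332))

height_params <- list(
  male = list(A = 28, theta = 0.75, B = 5.3, P = 10, t0 = 12.8, s = 1.0,
              birth_length = 51.1),
  female = list(A = 27, theta = 0.75, B = 4.8, P = 6, t0 = 11.0, s = 1.0,
                birth_length = 50.4))

## truncated-power basis of the infancy piece of the true curve
truth_infancy_spec <- function() {
  knots <- c(0.5, 0.8, 0.9)
  terms <- rbind(
    basis_terms("const", "poly", 0, 0L),
    basis_terms("t", "poly", 0, 1L),
    basis_terms("t2", "poly", 0, 2L),
    basis_terms("t3", "poly", 0, 3L),
    basis_terms(sprintf("tp%g_3", knots), "trunc", knots, 3L)
  )
  structure(list(measure = "truth_infancy", center = 0, knots = knots,
                 support = c(0, 1), terms = terms),
            class = "spline_spec")
}

truth_breaks <- c(0, 0.5, 0.8, 0.9, 1, 2, 8, 12, 17.5)

## per-segment linear maps from basis coefficients to local Taylor
## coefficients (rows: constant..cubic), for building piecewise_poly fast
segment_maps <- function(spec, breaks) basis_segment_maps(spec, breaks)

## solve the sex-specific population BMI curve from the anchors
solve_population_coefs <- function(sex) {
  an <- growth_anchors[[sex]]
  child <- spline_spec("bmi")
  bc <- function(t, d = 0) eval_basis(child, t, d)
  A <- rbind(bc(1), bc(1, 1), bc(an$ar_age), bc(an$ar_age, 1),
             bc(10), bc(13), bc(17))
  y <- c(an$bmi1, an$slope1, an$ar_bmi, 0, an$bmi10, an$bmi13, an$bmi17)
  cc <- solve(A, y)
  inf <- truth_infancy_spec()
  bi <- function(t, d = 0) eval_basis(inf, t, d)
  Ai <- rbind(bi(0), bi(0.35), bi(an$ap_age), bi(an$ap_age, 1),
              bi(1), bi(1, 1), bi(1, 2))
  yi <- c(an$bmi0, an$bmi035, an$ap_bmi, 0,
          drop(bc(1) %*% cc), drop(bc(1, 1) %*% cc), drop(bc(1, 2) %*% cc))
  ci <- solve(Ai, yi)
  list(child = drop(cc), infancy = drop(ci))
}

#' Population-average BMI curve of the generator
#'
#' The sex-specific true mean BMI trajectory from birth to 17.5 years that
#' the synthetic cohorts are built around: rises to the adiposity peak
#' near 9 months, falls to the rebound near 5.6--6.1 years, then rises
#' through adolescence.
#'
#' @param sex `"female"` or `"male"`.
#' @return A [piecewise_poly()] curve on `[0, 17.5]`.
#' @export
population_bmi_curve <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  pp <- solve_population_coefs(sex)
  child <- spline_spec("bmi"); inf <- truth_infancy_spec()
  maps_i <- segment_maps(inf, truth_breaks)
  maps_c <- segment_maps(child, truth_breaks)
  cf <- t(vapply(seq_len(length(truth_breaks) - 1L), function(j) {
    if (truth_breaks[j] < 1) drop(maps_i[[j]] %*% pp$infancy)
    else drop(maps_c[[j]] %*% pp$child)
  }, numeric(4)))
  piecewise_poly(truth_breaks, cf)
}

## genetic effect coefficients (g1, g2, g3) for g(t) = g1 t + g2 t^2 +
## g3 (t-2)_+^3, solved from the three calibration anchors; all-zero
## anchors give an exact null effect
genetic_effect_coefs <- function(sex, g15 = 0.15, ar_shift = -0.036,
                                 ar_bmi_effect = NULL) {
  an <- growth_anchors[[sex]]
  if (is.null(ar_bmi_effect)) ar_bmi_effect <- an$ar_bmi_effect
  pop <- population_bmi_curve(sex)
  mu2 <- evaluate_curve(pop, an$ar_age, deriv = 2)
  gb <- function(t) c(t, t^2, truncated_power_term(t, 2, 3))
  gd <- function(t) c(1, 2 * t, 3 * truncated_power_term(t, 2, 2))
  A <- rbind(gb(15), gb(an$ar_age), gd(an$ar_age))
  y <- c(g15, ar_bmi_effect, -ar_shift * mu2)
  stats::setNames(solve(A, y), c("g1", "g2", "g3"))
}

## the genetic effect expressed in the childhood model basis
## {const, age_c, age_c2, age_c3, tp2_3, tp8_3, tp12_3} with center 8
genetic_effect_in_basis <- function(g) {
  c(const = unname(8 * g["g1"] + 64 * g["g2"]),
    age_c = unname(g["g1"] + 16 * g["g2"]),
    age_c2 = unname(g["g2"]), age_c3 = 0,
    tp2_3 = unname(g["g3"]), tp8_3 = 0, tp12_3 = 0)
}

default_visits <- function(preset) {
  if (preset == "alspac") {
    data.frame(
      age = c(1.18, 1.76, 2.95, 3.77, 5.05, 5.90, 7.31, 7.74, 8.71, 9.94,
              10.75, 11.82, 12.97, 13.89, 15.32, 15.72, 16.83),
      prob = c(0.36, 0.90, 0.32, 0.88, 0.23, 0.49, 0.36, 0.51, 0.56, 0.86,
               0.62, 0.67, 0.86, 0.60, 0.30, 0.21, 0.12),
      sd = c(0.18, 0.25, 0.28, 0.23, 0.33, 0.24, 0.30, 0.33, 0.22, 0.29,
             0.23, 0.21, 0.22, 0.17, 0.15, 0.22, 0.24),
      source = c("clinic", "parental_report", "clinic", "parental_report",
                 "parental_report", "clinic", "clinic", "clinic", "clinic",
                 "parental_report", "clinic", "clinic", "parental_report",
                 "clinic", "clinic", "clinic", "clinic"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      age = c(1.15, 2.14, 3.09, 5.91, 8.02, 10.55, 14.06, 17.05),
      prob = c(0.91, 0.27, 0.65, 0.87, 0.71, 0.84, 0.82, 0.67),
      sd = c(0.09, 0.13, 0.09, 0.17, 0.27, 0.15, 0.17, 0.24),
      source = "clinic", stringsAsFactors = FALSE)
  }
}

default_infancy_visits <- function(preset) {
  if (preset != "alspac")
    return(data.frame(age = numeric(0), prob = numeric(0), sd = numeric(0),
                      source = character(0)))
  data.frame(age = c(0.09, 0.21, 0.38, 0.60, 0.83),
             prob = c(0.65, 0.55, 0.55, 0.50, 0.60),
             sd = c(0.02, 0.03, 0.04, 0.05, 0.05),
             source = "clinic", stringsAsFactors = FALSE)
}

#' Parameters of the synthetic cohort generator
#'
#' The defaults describe the two study-like cohorts: a large cohort with a
#' dense mixed clinic/parental-report measurement schedule (median 9 BMI
#' measures per child, including infancy visits that support the adiposity
#' peak model) and a smaller clinic-only cohort (median 6 measures, sparse
#' between 3 and 5.5 years).  Trajectory, genetic and noise parameters are
#' calibrated to the reference cohorts' descriptive statistics: see
#' [population_bmi_curve()], the per-allele effect reaching 0.15 kg/m^2 at
#' 15 y, a rebound-age shift of -0.036 y per allele, CAR(1) residual
#' correlation 0.9 per year, inflated parental-report noise and a small
#' rate of grossly implausible values.
#'
#' @param preset `"alspac"`-like (dense, mixed-source) or `"raine"`-like
#'   (sparse, clinic-only) cohort template.
#' @param n Number of children.
#' @param seed Non-negative integer seed; the generator is fully
#'   deterministic given `params`.
#' @param ... Overrides for any listed component (e.g. `sigma`, `rho`,
#'   `g15`, `ar_shift`, `re_sd`, `implausible_rate`, `visits`).
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(preset = c("alspac", "raine"), n = 2000,
                              seed = 1L, ...) {
  preset <- match.arg(preset)
  ref <- bmi_snp_panel()
  p <- list(
    preset = preset,
    cohort_id = paste0(preset, "_like"),
    n = as.integer(n),
    seed = as.integer(seed),
    prop_male = 0.5125,
    eaf = stats::setNames(
      if (preset == "alspac") ref$eaf_alspac else ref$eaf_raine, ref$snp),
    dosage_noise_sd = 0.04,
    re_sd = c(const = 1.0, age_c = 0.15, age_c2 = 0.012, tp2_3 = 8e-4),
    sigma = 0.7,
    rho = 0.9,
    g15 = 0.15,
    ar_shift = -0.036,
    ar_bmi_effect = NULL,   # NULL: sex-specific calibration anchors
    parental_noise = 1.5,
    implausible_rate = 0.001,
    implausible_factor = 10,
    height_noise = 0.5,
    height_scale_sd = 0.04,
    ga_mean = 39.5, ga_sd = 1.7,
    n_pcs = 5L,
    birth_score_effect = 0,
    visits = default_visits(preset),
    infancy_visits = default_infancy_visits(preset)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(all(p$eaf > 0 & p$eaf < 1), p$rho >= 0, p$rho < 1,
            p$seed >= 0)
  class(p) <- "simulation_params"
  p
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Synthetic cohort parameters (", x$cohort_id, "): n = ", x$n,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  sigma =", x$sigma, "| rho =", x$rho, "| g(15) =", x$g15,
      "| AR shift =", x$ar_shift, "y/allele\n")
  invisible(x)
}

#' Simulate a genotype dosage panel
#'
#' Independent binomial(2, EAF) allele counts per SNP, optionally smoothed
#' with small clamped Gaussian noise to mimic the non-integer posterior
#' mean dosages of imputed data.
#'
#' @param params A [simulation_params()] object.
#' @param seed Seed; `NULL` continues the current RNG stream (used
#'   internally by [simulate_cohort()]).
#' @return A [dosage_panel()].
#' @export
simulate_genotypes <- function(params, seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  m <- length(params$eaf)
  d <- vapply(params$eaf, function(f) stats::rbinom(n, 2L, f), numeric(n))
  d <- matrix(as.numeric(d), n, m, dimnames = list(NULL, names(params$eaf)))
  if (params$dosage_noise_sd > 0) {
    ## imputation-style uncertainty: largest for heterozygous calls and
    ## vanishing at the homozygous bounds, so allele frequencies stay
    ## unbiased after clamping
    d <- d + stats::rnorm(length(d), 0, params$dosage_noise_sd) *
      sqrt(d * (2 - d))
    d <- pmin(pmax(d, 0), 2)
  }
  rownames(d) <- sprintf("%s_%05d", params$cohort_id, seq_len(n))
  dosage_panel(d)
}

h_population <- function(t, sex) {
  hp <- height_params[[sex]]
  hp$A * t / (t + hp$theta) + hp$B * t +
    hp$P * stats::plogis((t - hp$t0) / hp$s)
}

## CAR(1) residual draw at given ages
car1_noise <- function(ages, sigma, rho) {
  n <- length(ages)
  if (n == 1L) return(stats::rnorm(1, 0, sigma))
  R <- rho^abs(outer(ages, ages, "-"))
  drop(crossprod(chol(R), stats::rnorm(n))) * sigma
}

#' Simulate growth trajectories for a genotyped cohort
#'
#' Generates the full synthetic cohort around a dosage panel: true
#' individual BMI curves (population curve + allelic-score effect +
#' individual random effects), observed BMI/weight/height records on the
#' preset visit schedule with CAR(1) residual noise (inflated for
#' parental-report visits), birth measures, ancestry PCs, and the ground
#' truth (curves, milestones, generative parameters).
#'
#' @param panel A [dosage_panel()] for the cohort, e.g. from
#'   [simulate_genotypes()].
#' @param params A [simulation_params()] object.
#' @param seed Seed; `NULL` continues the current RNG stream.
#' @return List of class `synthetic_cohort` with elements `growth`,
#'   `info`, `panel`, `truth`.
#' @export
simulate_trajectories <- function(panel, params, seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel$dosages)
  ids <- rownames(panel$dosages)
  score <- compute_allelic_score(panel)
  mean_score <- sum(2 * params$eaf)   # centre the genetic effect
  sex <- ifelse(stats::runif(n) < params$prop_male, "male", "female")

  child_spec <- spline_spec("bmi")
  inf_spec <- truth_infancy_spec()
  maps_c <- segment_maps(child_spec, truth_breaks)
  maps_i <- segment_maps(inf_spec, truth_breaks)
  nseg <- length(truth_breaks) - 1L
  pop_taylor <- list(); gvec <- list(); gcoef <- list()
  for (sx in c("female", "male")) {
    pc <- solve_population_coefs(sx)
    pop_taylor[[sx]] <- t(vapply(seq_len(nseg), function(j) {
      if (truth_breaks[j] < 1) drop(maps_i[[j]] %*% pc$infancy)
      else drop(maps_c[[j]] %*% pc$child)
    }, numeric(4)))
    gcoef[[sx]] <- genetic_effect_coefs(sx, params$g15, params$ar_shift,
                                        params$ar_bmi_effect)
    gvec[[sx]] <- genetic_effect_in_basis(gcoef[[sx]])
  }
  re_cols <- c("const", "age_c", "age_c2", "tp2_3")
  re_idx <- match(re_cols, child_spec$terms$label)

  ## per-individual covariates and birth measures
  ga <- pmin(43, pmax(32, stats::rnorm(n, params$ga_mean, params$ga_sd)))
  pcs <- matrix(stats::rnorm(n * params$n_pcs), n, params$n_pcs,
                dimnames = list(NULL, paste0("pc", seq_len(params$n_pcs))))
  b <- vapply(params$re_sd, function(s) stats::rnorm(n, 0, s), numeric(n))

  growth <- vector("list", n)
  curves <- vector("list", n)
  info <- vector("list", n)
  for (i in seq_len(n)) {
    sx <- sex[i]
    s_c <- score[i] - mean_score
    ## basis-coefficient perturbation: random effects + genetic effect
    pert <- numeric(nrow(child_spec$terms))
    pert[re_idx] <- b[i, ]
    pert <- pert + s_c * gvec[[sx]] + params$birth_score_effect * 0
    cf <- pop_taylor[[sx]] +
      t(vapply(seq_len(nseg), function(j) drop(maps_c[[j]] %*% pert),
               numeric(4)))
    curve <- piecewise_poly(truth_breaks, cf)
    curves[[i]] <- curve

    ## visit schedule
    vs <- params$visits
    keep <- stats::runif(nrow(vs)) < vs$prob
    iv <- params$infancy_visits
    ikeep <- if (nrow(iv)) stats::runif(nrow(iv)) < iv$prob else logical(0)
    ages <- c(iv$age[ikeep] + stats::rnorm(sum(ikeep), 0, iv$sd[ikeep]),
              vs$age[keep] + stats::rnorm(sum(keep), 0, vs$sd[keep]))
    src <- c(iv$source[ikeep], vs$source[keep])
    ok <- ages > 0.02 & ages < 17.45
    ages <- ages[ok]; src <- src[ok]
    o <- order(ages); ages <- round(ages[o], 3); src <- src[o]
    keep2 <- !duplicated(ages)
    ages <- ages[keep2]; src <- src[keep2]

    ## birth measures (gestational-age adjusted)
    blen <- height_params[[sx]]$birth_length + 0.45 * (ga[i] - 39.5) +
      stats::rnorm(1, 0, 2.1)
    bmi_birth <- evaluate_curve(curve, 0) + 0.12 * (ga[i] - 39.5) +
      stats::rnorm(1, 0, 0.8) +
      params$birth_score_effect * s_c
    bweight <- bmi_birth * (blen / 100)^2

    info[[i]] <- data.frame(
      individual_id = ids[i], sex = sx,
      birth_weight = round(bweight, 3), birth_length = round(blen, 1),
      gestational_age = round(ga[i], 1), t(pcs[i, ]),
      cohort_id = params$cohort_id, stringsAsFactors = FALSE)

    if (length(ages) == 0L) {
      growth[[i]] <- NULL
      next
    }
    parental <- src == "parental_report"
    e <- car1_noise(ages, params$sigma, params$rho)
    e <- e * ifelse(parental, params$parental_noise, 1)
    bmi_obs <- evaluate_curve(curve, ages) + e
    e_h <- car1_noise(ages, params$height_noise, params$rho)
    hgt <- blen + (h_population(ages, sx)) *
      (1 + stats::rnorm(1, 0, params$height_scale_sd)) +
      e_h * ifelse(parental, 2, 1)
    bmi_obs <- round(bmi_obs, 2)
    hgt <- round(hgt, 1)
    wgt <- round(bmi_obs * (hgt / 100)^2, 2)
    g <- data.frame(
      individual_id = ids[i], sex = sx,
      age = rep(ages, 3),
      measure = rep(c("bmi", "weight", "height"), each = length(ages)),
      value = c(bmi_obs, wgt, hgt),
      source = rep(src, 3),
      cohort_id = params$cohort_id, stringsAsFactors = FALSE)
    ## birth weight/length records (age 0)
    g <- rbind(g, data.frame(
      individual_id = ids[i], sex = sx, age = 0,
      measure = c("weight", "height"),
      value = c(round(bweight, 2), round(blen, 1)),
      source = "clinic", cohort_id = params$cohort_id,
      stringsAsFactors = FALSE))
    growth[[i]] <- g
  }
  growth <- do.call(rbind, growth)
  info <- do.call(rbind, info)
  rownames(growth) <- rownames(info) <- NULL

  ## implausible-value injection: decimal-shift recording errors (a
  ## dropped decimal point multiplies the value tenfold), the kind of
  ## gross error the 4 SD screen exists to remove
  n_rows <- nrow(growth)
  hit <- stats::runif(n_rows) < params$implausible_rate & growth$age > 0
  if (any(hit)) {
    growth$value[hit] <- round(growth$value[hit] * params$implausible_factor,
                               2)
  }

  truth <- list(params = params, score = score, sex = sex,
                curves = stats::setNames(curves, ids),
                g_coef = gcoef, mean_score = mean_score,
                n_implausible = sum(hit))
  structure(list(growth = growth, info = info, panel = panel,
                 truth = truth),
            class = "synthetic_cohort")
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [simulate_genotypes()] then
#' [simulate_trajectories()] under a single RNG stream, so the result is
#' byte-identical for identical `params`.
#'
#' @param params A [simulation_params()] object.
#' @return A `synthetic_cohort`.
#' @export
simulate_cohort <- function(params) {
  set.seed(params$seed)
  panel <- simulate_genotypes(params, seed = NULL)
  simulate_trajectories(panel, params, seed = NULL)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort", x$truth$params$cohort_id, ":",
      nrow(x$info), "children,", nrow(x$growth), "growth records\n")
  invisible(x)
}

#' Ground-truth milestones of a synthetic cohort
#'
#' Analytic extrema of each child's *true* curve (the generative curve,
#' before any noise or model fitting): adiposity peak in `[0, 2.5]` y and
#' adiposity rebound in `[2, 8]` y, computed with the same solvers used on
#' fitted curves.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame with `adiposity_peak` and `adiposity_rebound` rows
#'   per child.
#' @export
ground_truth_milestones <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- names(cohort$truth$curves)
  out <- vector("list", 2L * length(ids))
  for (k in seq_along(ids)) {
    cv <- cohort$truth$curves[[k]]
    out[[2L * k - 1L]] <- find_adiposity_peak(cv, id = ids[k])
    out[[2L * k]] <- find_adiposity_rebound(cv, id = ids[k])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
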