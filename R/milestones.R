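## Milestone derivation: adiposity peak and rebound from individual curves.

milestone_row <- function(id, kind, age = NA_real_, bmi = NA_real_,
                          valid = FALSE, reason = NA_character_) {
  data.frame(individual_id = id, kind = kind, age = age, bmi = bmi,
             valid = valid, reason_invalid = reason,
             stringsAsFactors = FALSE)
}

## shared solver: stationary points of the right curvature strictly inside
## the window; pick the extreme value (min or max), earliest age on ties
find_extremum <- function(curve, window, type, kind,
                          id = NA_character_, tol = 1e-6) {
  stopifnot(inherits(curve, "piecewise_poly"), length(window) == 2L)
  st <- pp_stationary_points(curve, window)
  if (nrow(st) == 0L)
    return(milestone_row(id, kind, reason = "no_stationary_point"))
  interior <- st$age > window[1] + tol & st$age < window[2] - tol
  if (!any(interior)) {
    return(milestone_row(id, kind, reason = "boundary"))
  }
  st <- st[interior, , drop = FALSE]
  good <- if (type == "min") st$second > 0 else st$second < 0
  if (!any(good))
    return(milestone_row(id, kind, reason = "wrong_curvature"))
  st <- st[good, , drop = FALSE]
  pick <- if (type == "min") which(st$value == min(st$value))
          else which(st$value == max(st$value))
  pick <- pick[which.min(st$age[pick])]
  milestone_row(id, kind, age = st$age[pick], bmi = st$value[pick],
                valid = TRUE)
}

#' Adiposity rebound of a BMI curve
#'
#' Solves the first derivative of the (piecewise polynomial) BMI curve for
#' zero inside the window and returns the interior minimum: the age at
#' which childhood BMI turns from falling to rising.  Roots are obtained
#' analytically per segment (the derivative of a cubic segment is
#' quadratic).  A milestone is valid only if a stationary point with
#' positive second derivative lies strictly inside the window; among
#' several, the one with the lowest BMI (earliest age on ties) is taken.
#'
#' @param curve A [piecewise_poly()] BMI curve, e.g. from
#'   [individual_curve()].
#' @param window Search window in years, default `[2, 8]`.
#' @param id Individual id carried into the output.
#' @return One-row data frame: `individual_id`, `kind`, `age`, `bmi`,
#'   `valid`, `reason_invalid`.
#' @export
find_adiposity_rebound <- function(curve, window = c(2, 8),
                                   id = NA_character_) {
  find_extremum(curve, window, "min", "adiposity_rebound", id)
}

#' Adiposity peak of a BMI curve
#'
#' The infancy maximum of the BMI curve: as [find_adiposity_rebound()] but
#' seeking an interior maximum (negative second derivative) in the window,
#' by default birth to 2.5 years, from the infancy model fit.
#'
#' @inheritParams find_adiposity_rebound
#' @param window Search window in years, default `[0, 2.5]`.
#' @return One-row data frame as in [find_adiposity_rebound()].
#' @export
find_adiposity_peak <- function(curve, window = c(0, 2.5),
                                id = NA_character_) {
  find_extremum(curve, window, "max", "adiposity_peak", id)
}

#' Derive milestones for every individual in a fitted model
#'
#' Builds each child's curve (fixed effects at the child's covariates and
#' score plus the child's random effects) and extracts the requested
#' milestone.
#'
#' @param fit A converged `growth_fit` (BMI model for the rebound, infancy
#'   model for the peak).
#' @param kind `"adiposity_rebound"` or `"adiposity_peak"`.
#' @param window Search window; defaults to `[2, 8]` y for the rebound and
#'   `[0, 2.5]` y for the peak.
#' @return Data frame with one row per individual.
#' @export
derive_milestones <- function(fit,
                              kind = c("adiposity_rebound",
                                       "adiposity_peak"),
                              window = NULL) {
  kind <- match.arg(kind)
  if (is.null(window))
    window <- if (kind == "adiposity_rebound") c(2, 8) else c(0, 2.5)
  if (!fit$converged)
    stop("refusing to derive milestones from a non-converged fit")
  ids <- levels(fit$prep$data$id)
  beta <- model_fixef(fit)
  re <- model_blups(fit)
  rng <- if (fit$spec$measure == "infancy") c(0, 5) else c(1, 17.5)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    cf <- individual_coef(fit, ids[k], beta = beta, re = re)
    curve <- basis_curve(fit$spec$basis, cf, range = rng)
    out[[k]] <- if (kind == "adiposity_rebound")
      find_adiposity_rebound(curve, window, id = ids[k])
    else
      find_adiposity_peak(curve, window, id = ids[k])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the infancy (birth to 5 years) BMI model
#'
#' The adiposity peak cannot be placed by the childhood model, which
#' starts at 1 year; a second mixed model is fitted to BMI from birth to 5
#' years for children with more than two BMI measures in that window, on a
#' cubic basis in age with cubic truncated terms at 0.5, 1 and 2 years and
#' random effects on `{1, t, t^2}`.
#'
#' @inheritParams fit_growth_model
#' @param genetic,covariates,sex Passed to [growth_model_spec()].
#' @return A `growth_fit` for the infancy model.
#' @export
fit_infancy_model <- function(growth, score = NULL, info = NULL,
                              genetic = if (is.null(score)) "none"
                                        else "score",
                              covariates = character(), sex = NULL,
                              method = "REML") {
  spec <- growth_model_spec("infancy", genetic = genetic,
                            covariates = covariates, sex = sex)
  fit_growth_model(growth, spec, score = score, info = info,
                   method = method)
}
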