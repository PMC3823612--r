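#' Cross-sectional linear association
#'
#' Ordinary least squares of `outcome` on `exposure`, adjusted for
#' `covariates`; reports the exposure coefficient.  Used for the allelic
#' score against birth measures (adjusting for gestational age), against
#' milestone ages/BMIs, and for milestones against final BMI.
#'
#' @param data Data frame holding all referenced columns.
#' @param outcome,exposure Column names.
#' @param covariates Character vector of adjustment column names.
#' @param sex,cohort Optional labels carried into the result.
#' @return One-row data frame of class `assoc_result`: `outcome`,
#'   `exposure`, `term`, `beta`, `se`, `p`, `n`, `r_squared`, `covariates`,
#'   `sex`, `cohort`.
#' @export
linear_assoc <- function(data, outcome, exposure,
                         covariates = character(),
                         sex = NA_character_, cohort = NA_character_) {
  cols <- c(outcome, exposure, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop("column(s) not found: ", paste(missing, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(d) < length(covariates) + 2L)
    stop("too few complete cases (", nrow(d), ") for ",
         length(covariates), " covariates")
  fml <- stats::as.formula(
    paste(outcome, "~", paste(c(exposure, covariates), collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients[exposure, ]
  out <- data.frame(outcome = outcome, exposure = exposure,
                    term = paste0(outcome, "~", exposure),
                    beta = unname(co[1]), se = unname(co[2]),
                    p = unname(co[4]), n = nrow(d),
                    r_squared = sm$r.squared,
                    covariates = paste(covariates, collapse = "+"),
                    sex = sex, cohort = cohort,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", class(out))
  out
}

#' Milestone association with adjustment for the partner milestone
#'
#' Association of the allelic score with a milestone's age (or BMI),
#' additionally adjusted for the milestone's BMI (or age) -- the analysis
#' that shows the score's rebound-age effect attenuating once rebound BMI
#' is controlled.
#'
#' @param data Data frame with the score and both milestone columns.
#' @param outcome,exposure,partner Column names; `partner` joins the
#'   covariate list.
#' @param covariates Further adjustment columns.
#' @inheritParams linear_assoc
#' @return An `assoc_result` row.
#' @export
milestone_adjusted_assoc <- function(data, outcome, exposure, partner,
                                     covariates = character(),
                                     sex = NA_character_,
                                     cohort = NA_character_) {
  linear_assoc(data, outcome, exposure,
               covariates = c(partner, covariates),
               sex = sex, cohort = cohort)
}

#' Final BMI per individual
#'
#' The last observed BMI measurement with age inside the window (default
#' 15--17.5 years); individuals without one are omitted.
#'
#' @param growth Growth data frame.
#' @param window Age window in years.
#' @return Data frame `individual_id`, `final_bmi`, `final_age`.
#' @export
final_bmi_values <- function(growth, window = c(15, 17.5)) {
  d <- growth[growth$measure == "bmi" & !is.na(growth$value) &
                growth$age >= window[1] & growth$age <= window[2], ,
              drop = FALSE]
  d <- d[order(d$individual_id, d$age), , drop = FALSE]
  last <- !duplicated(d$individual_id, fromLast = TRUE)
  data.frame(individual_id = d$individual_id[last],
             final_bmi = d$value[last], final_age = d$age[last],
             stringsAsFactors = FALSE)
}

#' Association of a milestone with final BMI
#'
#' OLS of final BMI (last measurement at 15--17.5 y) on a milestone
#' variable, reporting the coefficient of determination alongside the
#' slope -- e.g. how much of the variation in late-adolescent BMI is
#' explained by BMI at the adiposity rebound.
#'
#' @param milestones Milestone data frame (from [derive_milestones()]),
#'   only `valid` rows are used.
#' @param growth Growth data frame supplying final BMI.
#' @param milestone_var `"age"` or `"bmi"`.
#' @param window Final-BMI age window.
#' @inheritParams linear_assoc
#' @return An `assoc_result` row (its `r_squared` column is the R^2).
#' @export
final_bmi_assoc <- function(milestones, growth, milestone_var = c("bmi",
                                                                  "age"),
                            window = c(15, 17.5), covariates = character(),
                            sex = NA_character_, cohort = NA_character_) {
  milestone_var <- match.arg(milestone_var)
  fb <- final_bmi_values(growth, window)
  mm <- milestones[milestones$valid, , drop = FALSE]
  d <- merge(mm, fb, by = "individual_id")
  kind <- unique(mm$kind)
  names(d)[names(d) == milestone_var] <- paste0(kind, "_", milestone_var)
  linear_assoc(d, "final_bmi", paste0(kind, "_", milestone_var),
               covariates = covariates, sex = sex, cohort = cohort)
}

#' Variance in the outcome explained by the genetic terms, by age bin
#'
#' Residual-sums-of-squares R^2 from two nested longitudinal fits on the
#' same records: per age bin `b`,
#' `R^2(b) = 1 - sum(r_full^2) / sum(r_reduced^2)` over the records in the
#' bin, using marginal (population-level) residuals.  Negative estimates
#' (Monte Carlo noise) are floored at zero.
#'
#' @param fit_full Fit including the genetic terms.
#' @param fit_reduced Same model without them, on identical records.
#' @param breaks Age bin boundaries in years; default yearly bins centred
#'   on integer ages 1--16.
#' @return List with `by_age` (data frame: `age_mid`, `r2`, `n`) and
#'   `overall` (single R^2 across all records).
#' @export
variance_explained_curve <- function(fit_full, fit_reduced,
                                     breaks = seq(0.5, 16.5, by = 1)) {
  if (fit_full$n_obs != fit_reduced$n_obs)
    stop("fits use different records")
  r_f <- stats::residuals(fit_full$lme, level = 0)
  r_r <- stats::residuals(fit_reduced$lme, level = 0)
  age <- fit_full$prep$data$age
  if (sum(r_f^2) > sum(r_r^2) * (1 + 1e-8))
    message("variance_explained_curve: full-model residual sum of squares",
            " exceeds the reduced model's (fit diagnostics advised)")
  bin <- findInterval(age, breaks)
  inside <- bin >= 1 & bin < length(breaks)
  mids <- (utils::head(breaks, -1) + breaks[-1]) / 2
  by_age <- do.call(rbind, lapply(seq_along(mids), function(b) {
    i <- inside & bin == b
    if (!any(i)) return(NULL)
    r2 <- 1 - sum(r_f[i]^2) / sum(r_r[i]^2)
    data.frame(age_mid = mids[b], r2 = max(0, r2), n = sum(i))
  }))
  overall <- max(0, 1 - sum(r_f^2) / sum(r_r^2))
  list(by_age = by_age, overall = overall)
}
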