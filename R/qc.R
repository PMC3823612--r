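#' Age bin scheme for outlier screening
#'
#' Half-open age intervals `[b_i, b_{i+1})` used to form the sex- and
#' age-specific cells in which implausible measurements are screened.  The
#' default reproduces the cohort descriptive strata: 1--1.49, 1.5--2.49,
#' ..., 15.5--16.49 and a final stratum above 16.5 years.
#'
#' @param breaks Increasing numeric vector of bin boundaries in years.
#' @return An object of class `age_bin_scheme`.
#' @export
age_bin_scheme <- function(breaks = c(1, 1.5, seq(2.5, 16.5, by = 1), 17.5)) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2,
            !is.unsorted(breaks, strictly = TRUE))
  labels <- paste0("[", utils::head(breaks, -1L), ",", breaks[-1L], ")")
  structure(list(breaks = breaks, labels = labels),
            class = "age_bin_scheme")
}

#' @export
print.age_bin_scheme <- function(x, ...) {
  cat("Age bins (years):", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @rdname age_bin_scheme
#' @details `full_age_bin_scheme()` prepends infancy strata (0--0.25,
#'   0.25--0.5, 0.5--0.75, 0.75--1 y) to the default scheme so that data
#'   feeding the birth--5 y adiposity-peak model are screened too.
#' @export
full_age_bin_scheme <- function() {
  age_bin_scheme(c(0.001, 0.25, 0.5, 0.75, 1, 1.5, seq(2.5, 16.5, by = 1),
                   17.5))
}

age_bin_of <- function(scheme, age) {
  idx <- findInterval(age, scheme$breaks)
  idx[age < scheme$breaks[1] |
        age >= scheme$breaks[length(scheme$breaks)]] <- NA_integer_
  idx
}

#' Hard plausibility limits per measure
#'
#' Absolute bounds outside which a value of the measure is impossible in
#' a paediatric sample regardless of age: BMI (kg/m^2), weight (kg),
#' height (cm).  Applied before any distributional screen: such values
#' (typically unit or decimal-point recording errors) would otherwise
#' inflate the very cell SDs used to detect them.
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
hard_value_limits <- function() {
  list(bmi = c(5, 100), weight = c(0.3, 300), height = c(20, 272))
}

#' Recode implausible anthropometric values to missing
#'
#' Two screens are applied.  First, values outside the absolute
#' plausibility bounds of their measure ([hard_value_limits()]) are
#' recoded to missing, whatever their age.  Second, within every
#' (sex, age bin, measure) cell the mean and sample SD of the remaining
#' values are computed once, and any value further than `sd_threshold`
#' standard deviations from the cell mean is recoded to missing.  The SD
#' rule is single-pass (means and SDs are not recomputed after recoding);
#' cells with fewer than two values, or with zero SD, are left untouched,
#' and records whose age falls outside the bin scheme (for example birth
#' measures) are not SD-screened.
#'
#' The hard-limit screen exists because the cell-SD rule is structurally
#' blind to gross errors in small cells: a single huge value inflates its
#' own cell's SD enough to mask itself whenever the cell holds fewer than
#' about 17 records, and can mask opposite-side outliers in any cell.
#'
#' @param growth Growth data frame with columns `individual_id`, `sex`,
#'   `age`, `measure`, `value` (and any others, which pass through).
#' @param scheme An [age_bin_scheme()].
#' @param sd_threshold Threshold in standard deviations (default 4).
#' @param hard_limits Named list of absolute `c(lower, upper)` bounds per
#'   measure, or `NULL` to disable the range screen.
#' @return A list with `growth` (same rows, outliers recoded to `NA`) and
#'   `flags`, a data frame counting recoded values per sex/bin/measure
#'   (hard-limit flags appear with bin `"range"`).
#' @export
flag_implausible <- function(growth, scheme = age_bin_scheme(),
                             sd_threshold = 4,
                             hard_limits = hard_value_limits()) {
  stopifnot(all(c("sex", "age", "measure", "value") %in% names(growth)))
  hard <- logical(nrow(growth))
  if (!is.null(hard_limits)) {
    for (m in intersect(names(hard_limits), unique(growth$measure))) {
      lim <- hard_limits[[m]]
      hard <- hard | (growth$measure == m & !is.na(growth$value) &
                        (growth$value < lim[1] | growth$value > lim[2]))
    }
  }
  bin <- age_bin_of(scheme, growth$age)
  cell <- interaction(growth$sex, bin, growth$measure, drop = TRUE)
  flag <- logical(nrow(growth))
  ok <- !is.na(bin) & !is.na(growth$value) & !hard
  for (cl in levels(cell)) {
    i <- which(ok & cell == cl)
    if (length(i) < 2L) next
    v <- growth$value[i]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) next
    flag[i] <- abs(v - m) > sd_threshold * s
  }
  flag <- flag | hard
  cleaned <- growth
  cleaned$value[flag] <- NA_real_
  fl <- growth[flag, c("sex", "measure"), drop = FALSE]
  fl$bin <- ifelse(hard[flag], "range", scheme$labels[bin[flag]])
  flags <- if (nrow(fl)) {
    stats::aggregate(list(n_flagged = rep(1L, nrow(fl))),
                     fl[c("sex", "bin", "measure")], FUN = sum)
  } else {
    data.frame(sex = character(0), bin = character(0),
               measure = character(0), n_flagged = integer(0))
  }
  list(growth = cleaned, flags = flags, n_flagged = sum(flag))
}

#' Eligibility for the adiposity peak (infancy) model
#'
#' A child enters the birth--5 y model only with more than `min_measures`
#' BMI measurements inside the window (strictly greater, so the default
#' requires at least 3 measures in `[0, 5)`).
#'
#' @param growth Growth data frame (see [flag_implausible()]).
#' @param window Age window in years, default `[0, 5)`.
#' @param min_measures Strict lower bound on the BMI measure count.
#' @return Named logical vector, one entry per individual present in
#'   `growth`.
#' @export
eligible_for_ap <- function(growth, window = c(0, 5), min_measures = 2L) {
  stopifnot(all(c("individual_id", "age", "measure", "value") %in%
                  names(growth)))
  ids <- unique(growth$individual_id)
  in_win <- growth$measure == "bmi" & !is.na(growth$value) &
    growth$age >= window[1] & growth$age < window[2]
  counts <- table(factor(growth$individual_id[in_win], levels = ids))
  stats::setNames(as.vector(counts) > min_measures, ids)
}
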