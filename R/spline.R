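#' Truncated power term
#'
#' Evaluates `(t - knot)_+^p`, the building block of the truncated power
#' spline basis: zero at and below the knot, `(t - knot)^p` above it.  With
#' all segment polynomials of degree `p` this construction guarantees
#' continuity of the curve and its first `p - 1` derivatives at the knot.
#'
#' @param t Numeric vector of ages in years.
#' @param knot Knot location in years.
#' @param p Integer power, one of 1, 2 or 3.
#' @return Numeric vector of the same length as `t`.
#' @export
#' @examples
#' truncated_power_term(c(1.5, 3, 10), knot = 2, p = 3)
truncated_power_term <- function(t, knot, p) {
  stopifnot(is.numeric(t), length(knot) == 1L, p %in% 1:3)
  ifelse(t > knot, (t - knot)^p, 0)
}

## Internal term representation for a spline basis -------------------------
##
## A basis is a data.frame of terms, one row per column:
##   label  : column label used in design matrices and model formulas
##   kind   : "poly" (global polynomial in t - offset) or "trunc"
##   offset : centering age (poly) or knot (trunc)
##   power  : polynomial power (0 = constant)
##   minus_knot / minus_power: optional second truncated term subtracted
##       from the first (used to absorb a linear constraint, see the
##       weight basis); NA when unused.

basis_terms <- function(labels, kind, offset, power,
                        minus_knot = NA_real_, minus_power = NA_integer_) {
  data.frame(label = labels, kind = kind, offset = offset, power = power,
             minus_knot = minus_knot, minus_power = minus_power,
             stringsAsFactors = FALSE)
}

## d-th derivative of (t - off)^p (falling factorial coefficient)
poly_deriv_eval <- function(t, off, p, d) {
  if (d > p) return(numeric(length(t)) * 0)
  coef <- prod(seq.int(p, by = -1L, length.out = d))
  if (d == 0L) coef <- 1
  coef * (t - off)^(p - d)
}

trunc_deriv_eval <- function(t, knot, p, d) {
  v <- poly_deriv_eval(t, knot, p, d)
  v[t <= knot] <- 0
  v
}

eval_term <- function(term, t, deriv = 0L) {
  v <- switch(term$kind,
              poly  = poly_deriv_eval(t, term$offset, term$power, deriv),
              trunc = trunc_deriv_eval(t, term$offset, term$power, deriv),
              stop("unknown basis term kind: ", term$kind))
  if (!is.na(term$minus_knot)) {
    v <- v - trunc_deriv_eval(t, term$minus_knot, term$minus_power, deriv)
  }
  v
}

#' Spline basis specification for a growth measure
#'
#' Returns the fixed-effect spline specification used for each measure:
#' * `"bmi"`, `"height"`: cubic polynomial in centered age plus cubic
#'   truncated power terms at the knots -- piecewise cubic with continuous
#'   first and second derivatives at every knot.
#' * `"weight"`: linear below the first knot, cubic on the two middle
#'   segments and quadratic above the last knot.  The drop from cubic to
#'   quadratic beyond the last knot is enforced by absorbing the constraint
#'   "total cubic coefficient above 12 y equals zero" into the design: the
#'   cubic truncated columns at 2 and 8 years each have the cubic term at
#'   12 years subtracted, and no free cubic column at 12 years exists.
#' * `"infancy"`: cubic polynomial in age plus cubic truncated terms at
#'   0.5, 1 and 2 years; used for the birth--5 y model from which the
#'   adiposity peak is derived.  The extra infancy knots give the curve
#'   enough local flexibility to place the peak without bias given the
#'   steep rise and turn of BMI in the first year.
#'
#' @param measure One of `"bmi"`, `"height"`, `"weight"`, `"infancy"`.
#' @param center Centering age in years for the global polynomial columns
#'   (fixed at 8 years for the childhood models so that intercepts are
#'   comparable across datasets; 0 for the infancy model).
#' @param knots Knot locations in years.
#' @return An object of class `spline_spec`: a list with `measure`,
#'   `center`, `knots`, `support` (the age range the basis is intended
#'   for), and `terms` (the column definitions).
#' @export
spline_spec <- function(measure = c("bmi", "height", "weight", "infancy"),
                        center = NULL, knots = NULL) {
  measure <- match.arg(measure)
  if (measure %in% c("bmi", "height")) {
    if (is.null(center)) center <- 8
    if (is.null(knots)) knots <- c(2, 8, 12)
    stopifnot(length(knots) == 3L, !is.unsorted(knots, strictly = TRUE))
    terms <- rbind(
      basis_terms("const", "poly", center, 0L),
      basis_terms("age_c", "poly", center, 1L),
      basis_terms("age_c2", "poly", center, 2L),
      basis_terms("age_c3", "poly", center, 3L),
      basis_terms(sprintf("tp%g_3", knots), "trunc", knots, 3L)
    )
    support <- c(0.5, 18)
  } else if (measure == "weight") {
    if (is.null(center)) center <- 8
    if (is.null(knots)) knots <- c(2, 8, 12)
    stopifnot(length(knots) == 3L, !is.unsorted(knots, strictly = TRUE))
    k <- knots
    terms <- rbind(
      basis_terms("const", "poly", center, 0L),
      basis_terms("age_c", "poly", center, 1L),
      basis_terms(sprintf("tp%g_2", k[1]), "trunc", k[1], 2L),
      basis_terms(sprintf("tp%g_3c", k[1]), "trunc", k[1], 3L,
                  minus_knot = k[3], minus_power = 3L),
      basis_terms(sprintf("tp%g_2", k[2]), "trunc", k[2], 2L),
      basis_terms(sprintf("tp%g_3c", k[2]), "trunc", k[2], 3L,
                  minus_knot = k[3], minus_power = 3L),
      basis_terms(sprintf("tp%g_2", k[3]), "trunc", k[3], 2L)
    )
    support <- c(0.5, 18)
  } else { # infancy
    if (is.null(center)) center <- 0
    if (is.null(knots)) knots <- c(0.5, 1, 2)
    terms <- rbind(
      basis_terms("const", "poly", center, 0L),
      basis_terms("age_c", "poly", center, 1L),
      basis_terms("age_c2", "poly", center, 2L),
      basis_terms("age_c3", "poly", center, 3L),
      basis_terms(sprintf("tp%g_3", knots), "trunc", knots, 3L)
    )
    support <- c(0, 5)
  }
  structure(list(measure = measure, center = center, knots = knots,
                 support = support, terms = terms),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Spline basis for measure:", x$measure, "\n")
  cat("  centering age:", x$center, "y; knots:",
      paste(x$knots, collapse = ", "), "y\n")
  cat("  columns:", paste(x$terms$label, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a spline basis (or its derivatives) at a set of ages
#'
#' @param spec A [spline_spec()] object.
#' @param t Ages in years.
#' @param deriv Derivative order (0 to 3).
#' @return Matrix with one column per basis term, labelled.
#' @export
eval_basis <- function(spec, t, deriv = 0L) {
  stopifnot(inherits(spec, "spline_spec"), deriv %in% 0:3)
  out <- vapply(seq_len(nrow(spec$terms)),
                function(i) eval_term(spec$terms[i, ], t, deriv),
                numeric(length(t)))
  out <- matrix(out, nrow = length(t),
                dimnames = list(NULL, spec$terms$label))
  out
}

#' BMI / height design columns
#'
#' Convenience wrapper returning the design matrix of the piecewise-cubic
#' basis used for BMI and height: `{1, a, a^2, a^3, (t-2)_+^3, (t-8)_+^3,
#' (t-12)_+^3}` with `a = t - 8`.
#'
#' @param ages Ages in years.
#' @param center,knots See [spline_spec()].
#' @return Design matrix, one row per age.
#' @export
build_bmi_height_basis <- function(ages, center = 8, knots = c(2, 8, 12)) {
  eval_basis(spline_spec("bmi", center, knots), ages)
}

#' Weight design columns
#'
#' Basis realizing segment degrees (1, 3, 3, 2) across the knots: linear
#' from 1--2 y, cubic from 2--8 y and 8--12 y, quadratic above 12 y.
#'
#' @inheritParams build_bmi_height_basis
#' @return Design matrix, one row per age.
#' @export
build_weight_basis <- function(ages, center = 8, knots = c(2, 8, 12)) {
  eval_basis(spline_spec("weight", center, knots), ages)
}

#' Infancy (birth to 5 years) design columns
#'
#' @param ages Ages in years.
#' @return Design matrix, one row per age.
#' @export
build_infancy_basis <- function(ages) {
  eval_basis(spline_spec("infancy"), ages)
}

#' Convert basis coefficients to an explicit piecewise polynomial
#'
#' Given a spline specification and a coefficient vector (one per basis
#' column) the curve is re-expressed segment by segment as a polynomial in
#' local coordinates `t - segment_start`, which is the representation the
#' milestone solvers work on.
#'
#' @param spec A [spline_spec()] object.
#' @param coef Coefficient vector, one entry per basis column.
#' @param range Age range covered by the returned piecewise polynomial.
#' @return A [piecewise_poly()] object.
#' @export
basis_curve <- function(spec, coef, range = spec$support) {
  stopifnot(length(coef) == nrow(spec$terms))
  brk <- sort(unique(c(range[1], spec$knots[spec$knots > range[1] &
                                              spec$knots < range[2]],
                       range[2])))
  maps <- basis_segment_maps(spec, brk)
  cf <- t(vapply(maps, function(M) drop(M %*% coef), numeric(4)))
  piecewise_poly(brk, cf)
}

## per-segment linear maps from basis coefficients to local Taylor
## coefficients; memoised, since curve construction is a hot path when
## milestones are derived for thousands of individuals
.basis_cache <- new.env(parent = emptyenv())

basis_segment_maps <- function(spec, brk) {
  key <- paste(spec$measure, spec$center,
               paste(spec$knots, collapse = ","),
               paste(signif(brk, 12), collapse = ","), sep = "|")
  hit <- .basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  maps <- lapply(seq_len(length(brk) - 1L), function(j) {
    tau <- brk[j]
    ## Taylor expansion just inside the segment so truncated terms
    ## switched on at tau count; shift back to tau (exact for cubics)
    eps <- (brk[j + 1L] - tau) * 1e-9
    M <- t(vapply(0:3, function(d)
      eval_basis(spec, tau + eps, deriv = d)[1, ] / factorial(d),
      numeric(nrow(spec$terms))))
    apply(M, 2, shift_poly, h = -eps)
  })
  .basis_cache[[key]] <- maps
  maps
}

## shift polynomial sum c_k x^k to sum c'_k (x + h)^k, i.e. re-center
shift_poly <- function(coef, h) {
  p <- length(coef) - 1L
  out <- numeric(p + 1L)
  for (k in 0:p) {
    for (m in 0:k) {
      out[m + 1L] <- out[m + 1L] + coef[k + 1L] * choose(k, m) * h^(k - m)
    }
  }
  out
}
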