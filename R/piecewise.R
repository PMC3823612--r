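#' Piecewise polynomial curves
#'
#' A minimal piecewise polynomial container: `breaks` are the segment
#' boundaries (increasing, length `K + 1`), and `coef` is a `K x (d + 1)`
#' matrix where row `j` holds the polynomial coefficients on segment `j`
#' in *local* coordinates, `f(t) = sum_k coef[j, k + 1] * (t - breaks[j])^k`.
#' Local coordinates keep the evaluation well conditioned across the full
#' 0--17.5 y age range.
#'
#' @param breaks Increasing numeric vector of segment boundaries (years).
#' @param coef Coefficient matrix, one row per segment.
#' @return An object of class `piecewise_poly`.
#' @export
piecewise_poly <- function(breaks, coef) {
  coef <- rbind(coef)
  stopifnot(is.numeric(breaks), !is.unsorted(breaks, strictly = TRUE),
            nrow(coef) == length(breaks) - 1L)
  structure(list(breaks = as.numeric(breaks), coef = unname(coef)),
            class = "piecewise_poly")
}

#' @export
print.piecewise_poly <- function(x, ...) {
  cat("Piecewise polynomial:", nrow(x$coef), "segments on [",
      x$breaks[1], ",", x$breaks[length(x$breaks)], "] y, degree",
      ncol(x$coef) - 1L, "\n")
  invisible(x)
}

pp_segment_index <- function(pp, t) {
  idx <- findInterval(t, pp$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  idx
}

#' Evaluate a piecewise polynomial curve or its derivatives
#'
#' @param curve A [piecewise_poly()] object.
#' @param t Ages in years (inside the curve's break range).
#' @param deriv Derivative order (non-negative integer).
#' @return Numeric vector of curve (or derivative) values.
#' @export
evaluate_curve <- function(curve, t, deriv = 0L) {
  stopifnot(inherits(curve, "piecewise_poly"))
  j <- pp_segment_index(curve, t)
  x <- t - curve$breaks[j]
  p <- ncol(curve$coef) - 1L
  out <- numeric(length(t))
  if (deriv > p) return(out)
  for (k in deriv:p) {
    fac <- prod(seq.int(k, by = -1L, length.out = deriv))
    if (deriv == 0L) fac <- 1
    out <- out + curve$coef[cbind(j, k + 1L)] * fac * x^(k - deriv)
  }
  out
}

## derivative of a piecewise polynomial as a new piecewise_poly
pp_derivative <- function(pp) {
  p <- ncol(pp$coef) - 1L
  if (p == 0L) return(piecewise_poly(pp$breaks, pp$coef * 0))
  dcf <- pp$coef[, -1L, drop = FALSE] %*% diag(seq_len(p), p, p)
  piecewise_poly(pp$breaks, dcf)
}

## real roots of a polynomial given by local coefficients, within [lo, hi]
## (local coordinates); uses the closed quadratic form where possible and
## polyroot() otherwise.
poly_real_roots <- function(coef, lo, hi, tol = 1e-9) {
  ## strip trailing zero coefficients
  nz <- which(abs(coef) > 0)
  if (length(nz) == 0L) return(numeric(0))      # identically zero
  coef <- coef[seq_len(max(nz))]
  deg <- length(coef) - 1L
  if (deg == 0L) return(numeric(0))
  if (deg == 1L) {
    r <- -coef[1] / coef[2]
  } else if (deg == 2L) {
    a <- coef[3]; b <- coef[2]; cc <- coef[1]
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(numeric(0))
    s <- sqrt(disc)
    ## numerically stable quadratic roots
    q <- -0.5 * (b + sign(b + (b == 0)) * s)
    r <- unique(c(q / a, if (abs(q) > 0) cc / q else -b / (2 * a)))
  } else {
    z <- polyroot(coef)
    scale <- max(abs(z), 1)
    r <- Re(z)[abs(Im(z)) < 1e-8 * scale]
  }
  r[r >= lo - tol & r <= hi + tol]
}

## stationary points of a piecewise polynomial inside a window:
## returns data.frame(age, value, second) for every real root of the first
## derivative inside [window[1], window[2]]
pp_stationary_points <- function(pp, window) {
  lo <- max(window[1], pp$breaks[1])
  hi <- min(window[2], pp$breaks[length(pp$breaks)])
  out <- list()
  for (j in seq_len(nrow(pp$coef))) {
    s0 <- pp$breaks[j]; s1 <- pp$breaks[j + 1L]
    a <- max(lo, s0); b <- min(hi, s1)
    if (a >= b) next
    cf <- pp$coef[j, ]
    p <- length(cf) - 1L
    dcf <- if (p >= 1) cf[-1L] * seq_len(p) else 0
    roots <- poly_real_roots(dcf, a - s0, b - s0)
    for (x in roots) {
      age <- s0 + x
      out[[length(out) + 1L]] <- data.frame(
        age = age,
        value = evaluate_curve(pp, age),
        second = evaluate_curve(pp, age, deriv = 2L))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(age = numeric(0), value = numeric(0),
                      second = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(round(res$age, 10)), , drop = FALSE]
  res[order(res$age), , drop = FALSE]
}
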