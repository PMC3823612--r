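#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-cohort estimates with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w_i b_i) / sum(w_i)`, `se = 1 / sqrt(sum(w_i))`, two-sided
#' normal p-value.  Heterogeneity is reported via Cochran's Q but never
#' switches the model to random effects.
#'
#' @param betas,ses Numeric vectors of per-study estimates and standard
#'   errors (all positive), same length.
#' @return List of class `meta_result`: `beta`, `se`, `z`, `p`, `Q`,
#'   `Q_df`, `Q_p`, `k`, `method`.
#' @export
fixed_effect_meta <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), all(ses > 0))
  k <- length(betas)
  if (k < 2L)
    warning("single study supplied: pooled result is a pass-through")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  q <- cochran_q(betas, ses)
  structure(list(beta = beta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 Q = q$Q, Q_df = q$df, Q_p = q$p, k = k,
                 method = "inverse_variance"),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  if (x$method == "inverse_variance") {
    cat(sprintf(
      "Fixed-effect meta-analysis (k = %d): beta = %.4g (SE %.4g), p = %.3g\n",
      x$k, x$beta, x$se, x$p))
    cat(sprintf("  Cochran's Q = %.4g on %d df, p = %.3g\n",
                x$Q, x$Q_df, x$Q_p))
  } else {
    cat(sprintf("Fisher combined p-value (k = %d): X = %.4g, p = %.3g\n",
                x$k, x$X, x$p))
  }
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i (b_i - pooled)^2)` with inverse-variance weights, referred
#' to chi-square with `k - 1` degrees of freedom.
#'
#' @inheritParams fixed_effect_meta
#' @return List `Q`, `df`, `p`.
#' @export
cochran_q <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), all(ses > 0))
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - pooled)^2)
  df <- length(betas) - 1L
  p <- if (df >= 1L) stats::pchisq(Q, df, lower.tail = FALSE) else 1
  list(Q = Q, df = df, p = p)
}

#' Fisher's unweighted p-value combination
#'
#' Combines independent p-values (e.g. per-cohort likelihood-ratio test
#' p-values) without weighting: `X = -2 sum(log p_i)` is chi-square with
#' `2k` degrees of freedom under the joint null.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @return List of class `meta_result`: `X`, `df`, `p`, `k`, `method`.
#' @export
fisher_combine <- function(pvalues) {
  stopifnot(length(pvalues) >= 1L)
  if (any(pvalues <= 0))
    stop("Fisher combination undefined for p = 0")
  if (any(pvalues > 1)) stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  structure(list(X = X, df = df,
                 p = stats::pchisq(X, df, lower.tail = FALSE),
                 k = length(pvalues), method = "fisher"),
            class = "meta_result")
}

#' Bonferroni significance threshold
#'
#' Family-wise threshold `fwer / n_tests`; with the 32-SNP panel at a 0.05
#' family-wise error rate this is 0.0015625, conventionally displayed at
#' two significant figures as 0.0016.
#'
#' @param n_tests Number of tests (>= 1).
#' @param fwer Family-wise error rate.
#' @return List `threshold` (full precision) and `display` (2 significant
#'   figures).
#' @export
bonferroni_threshold <- function(n_tests, fwer = 0.05) {
  stopifnot(n_tests >= 1, fwer > 0, fwer < 1)
  thr <- fwer / n_tests
  list(threshold = thr, display = signif(thr, 2))
}
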