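#' Growth model specification
#'
#' Describes one semi-parametric linear mixed model: the measure and its
#' spline basis, the covariates, the genetic term and whether it interacts
#' with every basis column, the random-effect columns and the sex stratum.
#'
#' @param measure `"bmi"`, `"weight"`, `"height"` or `"infancy"` (the
#'   birth--5 y BMI model from which the adiposity peak is derived).
#' @param genetic `"none"`, `"score"` (allelic score) or `"snp"` (a single
#'   SNP dosage, named in `snp`).
#' @param snp SNP id when `genetic = "snp"`.
#' @param interaction Include the genetic term's interaction with all
#'   basis columns (the age-varying genetic effect); implies the main
#'   effect.
#' @param covariates Character vector of per-record or per-individual
#'   covariate columns (e.g. `"source01"` for the parental-report
#'   indicator, `"pc1"`..`"pc5"` for ancestry principal components).
#' @param random Random-effect columns (subset of the basis columns,
#'   `"const"` meaning the intercept).  Defaults: `{const, age_c, age_c2,
#'   tp2_3}` for BMI/height, `{const, age_c, tp2_2}` for weight, `{const,
#'   age_c, age_c2}` for infancy.
#' @param re_structure `"diagonal"` (independent random effects, the
#'   default for estimability) or `"general"` (unstructured covariance).
#' @param source_variance When the parental-report indicator `source01` is
#'   among the covariates, also let the residual variance differ by
#'   measurement source (differential measurement error affects spread,
#'   not just the mean).  Default `TRUE`.
#' @param sex `NULL` for pooled, else `"female"` or `"male"` to stratify.
#' @param age_range Ages used for fitting; defaults to (1, 17.5) for the
#'   childhood models and [0, 5) for the infancy model.
#' @param min_individuals Fit refuses datasets with fewer individuals.
#' @return Object of class `growth_model_spec`.
#' @export
growth_model_spec <- function(measure = c("bmi", "weight", "height",
                                          "infancy"),
                              genetic = c("none", "score", "snp"),
                              snp = NULL,
                              interaction = TRUE,
                              covariates = character(),
                              random = NULL,
                              re_structure = c("diagonal", "general"),
                              source_variance = TRUE,
                              sex = NULL,
                              age_range = NULL,
                              min_individuals = 30L) {
  measure <- match.arg(measure)
  genetic <- match.arg(genetic)
  re_structure <- match.arg(re_structure)
  if (genetic == "snp" && is.null(snp))
    stop("genetic = \"snp\" needs a snp id")
  basis <- spline_spec(if (measure == "height") "bmi" else measure)
  if (is.null(random)) {
    random <- switch(measure,
                     bmi = , height = c("const", "age_c", "age_c2", "tp2_3"),
                     weight = c("const", "age_c", "tp2_2"),
                     infancy = c("const", "age_c", "age_c2"))
  }
  bad <- setdiff(random, basis$terms$label)
  if (length(bad))
    stop("random-effect columns not in the basis: ",
         paste(bad, collapse = ", "))
  if (is.null(age_range))
    age_range <- if (measure == "infancy") c(0, 5) else c(1, 17.5)
  structure(list(measure = measure, genetic = genetic, snp = snp,
                 interaction = interaction, covariates = covariates,
                 random = random, re_structure = re_structure,
                 source_variance = source_variance, sex = sex,
                 age_range = age_range, basis = basis,
                 min_individuals = min_individuals),
            class = "growth_model_spec")
}

#' @export
print.growth_model_spec <- function(x, ...) {
  cat("Growth model spec:", x$measure,
      if (!is.null(x$sex)) paste0("(", x$sex, ")"), "\n")
  cat("  genetic term:", x$genetic,
      if (x$genetic != "none" && x$interaction) "x spline basis", "\n")
  cat("  covariates:", if (length(x$covariates))
    paste(x$covariates, collapse = ", ") else "(none)", "\n")
  cat("  random effects (", x$re_structure, "): ",
      paste(x$random, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## assemble the analysis-ready model frame for one spec
prepare_model_frame <- function(growth, spec, score = NULL, info = NULL) {
  d <- growth
  target_measure <- if (spec$measure == "infancy") "bmi" else spec$measure
  d <- d[d$measure == target_measure & !is.na(d$value), , drop = FALSE]
  d <- d[d$age > spec$age_range[1] | (spec$measure == "infancy" &
                                        d$age >= spec$age_range[1]), ,
         drop = FALSE]
  d <- d[d$age < spec$age_range[2], , drop = FALSE]
  if (!is.null(spec$sex)) d <- d[d$sex == spec$sex, , drop = FALSE]
  if (spec$measure == "infancy") {
    elig <- eligible_for_ap(growth)
    d <- d[elig[as.character(d$individual_id)], , drop = FALSE]
  }
  if (is.null(d$source)) d$source <- "clinic"
  d$source01 <- as.numeric(d$source == "parental_report")
  if (!is.null(info)) {
    keep <- setdiff(intersect(spec$covariates, names(info)), names(d))
    if (length(keep)) {
      m <- match(d$individual_id, info$individual_id)
      for (cn in keep) d[[cn]] <- info[[cn]][m]
    }
  }
  missing_cov <- setdiff(spec$covariates, names(d))
  if (length(missing_cov))
    stop("covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "))
  ## constant covariates (e.g. no parental reports in a clinic-only
  ## cohort) carry no information and would make the design singular
  covariates <- spec$covariates
  constant <- vapply(covariates,
                     function(cn) length(unique(d[[cn]])) < 2L, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  ## genetic exposure
  if (spec$genetic != "none") {
    if (is.null(score))
      stop("spec has a genetic term but no score/dosage vector given")
    g <- score[as.character(d$individual_id)]
    if (anyNA(g))
      stop("score/dosage missing for some individuals in the growth data")
    d$gen <- as.numeric(g)
  }
  ## complete cases on covariates
  if (length(covariates)) {
    cc <- stats::complete.cases(d[covariates])
    d <- d[cc, , drop = FALSE]
  }
  ## basis columns (omit the constant: the formula supplies an intercept)
  B <- eval_basis(spec$basis, d$age)
  bl <- setdiff(colnames(B), "const")
  for (cn in bl) d[[cn]] <- B[, cn]
  ## genetic x basis interaction columns, precomputed so coefficient
  ## names are deterministic
  gen_terms <- character(0)
  if (spec$genetic != "none") {
    gen_terms <- "gen"
    if (spec$interaction) {
      for (cn in bl) {
        d[[paste0("gen_", cn)]] <- d$gen * d[[cn]]
        gen_terms <- c(gen_terms, paste0("gen_", cn))
      }
    }
  }
  ## drop duplicated (id, age) rows: zero time lags break the CAR(1) fit
  d <- d[order(d$individual_id, d$age), , drop = FALSE]
  dup <- duplicated(data.frame(d$individual_id, round(d$age, 9)))
  if (any(dup)) d <- d[!dup, , drop = FALSE]
  d$id <- factor(d$individual_id, levels = unique(d$individual_id))
  rownames(d) <- NULL
  fixed_terms <- c(bl, covariates, gen_terms)
  list(data = d, basis_labels = bl, fixed_terms = fixed_terms,
       gen_terms = gen_terms, covariates = covariates,
       source_variance = isTRUE(spec$source_variance) &&
         "source01" %in% covariates &&
         length(unique(d$source01)) > 1L)
}

re_formula <- function(spec) {
  rnd <- setdiff(spec$random, "const")
  intercept <- if ("const" %in% spec$random) "1" else "-1"
  stats::as.formula(paste("~", paste(c(intercept, rnd), collapse = " + ")))
}

lme_engine <- function(prep, spec, method, random_cols = spec$random) {
  fixed <- stats::as.formula(paste("value ~",
                                   paste(prep$fixed_terms, collapse = " + ")))
  rnd <- setdiff(random_cols, "const")
  refrm <- stats::as.formula(
    paste("~", paste(c(if ("const" %in% random_cols) "1" else "-1", rnd),
                     collapse = " + ")))
  pd <- if (spec$re_structure == "general") nlme::pdSymm(refrm)
        else nlme::pdDiag(refrm)
  ctrl <- nlme::lmeControl(maxIter = 150, msMaxIter = 200, niterEM = 30,
                           returnObject = TRUE)
  args <- list(fixed = fixed, data = prep$data,
               random = list(id = pd),
               correlation = nlme::corCAR1(form = ~ age | id),
               method = method, control = ctrl)
  if (prep$source_variance)
    args$weights <- nlme::varIdent(form = ~ 1 | source01)
  warned <- character(0)
  fit <- withCallingHandlers(
    do.call(nlme::lme, args),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(fit = fit, warnings = warned)
}

#' Fit a semi-parametric growth mixed model
#'
#' Fits `value ~ spline(age) + covariates + genetic terms` with individual
#' random effects on a subset of the spline columns and a continuous AR(1)
#' correlation structure on the within-individual residuals,
#' `corr(e_s, e_t) = rho^|age_s - age_t|`.  Variance components are
#' estimated by REML by default; likelihood-ratio tests of genetic fixed
#' effects should use `method = "ML"` fits (see [lrt_genetic_effect()] and
#' [refit_ml()]).  If the full random-effect set fails to fit, the model
#' is automatically retried with reduced sets (dropping the last column
#' each time), which is recorded in the returned object.
#'
#' @param growth Growth data frame (long format; see
#'   [read_growth_table()]).
#' @param spec A [growth_model_spec()].
#' @param score Named vector: allelic score (or single-SNP dosage) per
#'   individual; required when the spec has a genetic term.
#' @param info Optional per-individual covariate table.
#' @param method `"REML"` (default) or `"ML"`.
#' @return Object of class `growth_fit`.
#' @export
fit_growth_model <- function(growth, spec, score = NULL, info = NULL,
                             method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "growth_model_spec"))
  prep <- prepare_model_frame(growth, spec, score, info)
  n_ind <- nlevels(prep$data$id)
  if (n_ind < spec$min_individuals)
    stop("only ", n_ind, " individuals available; need at least ",
         spec$min_individuals)
  attempts <- list(spec$random)
  while (length(attempts[[length(attempts)]]) > 2L) {
    last <- attempts[[length(attempts)]]
    attempts[[length(attempts) + 1L]] <- utils::head(last, -1L)
  }
  fit <- NULL; used_random <- NULL; warns <- character(0)
  for (rnd in attempts) {
    res <- tryCatch(lme_engine(prep, spec, method, rnd),
                    error = function(e) e)
    if (!inherits(res, "error")) {
      fit <- res$fit; used_random <- rnd; warns <- res$warnings
      break
    }
  }
  if (is.null(fit))
    stop("growth model failed to fit for every random-effect fallback")
  if (!identical(used_random, spec$random))
    message("fit_growth_model: random effects reduced to {",
            paste(used_random, collapse = ", "), "}")
  converged <- !any(grepl("iteration limit|convergence", warns,
                          ignore.case = TRUE))
  structure(list(lme = fit, spec = spec, prep = prep,
                 random_used = used_random,
                 n_individuals = n_ind, n_obs = nrow(prep$data),
                 method = method, converged = converged,
                 warnings = warns),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth mixed model (", x$spec$measure,
      if (!is.null(x$spec$sex)) paste0(", ", x$spec$sex), "): ",
      x$n_individuals, " individuals, ", x$n_obs, " observations\n",
      sep = "")
  cat("  method:", x$method, "| CAR(1) rho:", signif(model_rho(x), 4),
      "| sigma:", signif(model_sigma(x), 4), "\n")
  cat("  logLik:", signif(as.numeric(stats::logLik(x$lme)), 8),
      "| AIC:", signif(model_aic(x), 8),
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Accessors for a fitted growth model
#'
#' `model_fixef`, `model_vcov`: fixed coefficients and their covariance;
#' `model_sigma`, `model_rho`: residual SD and CAR(1) correlation
#' parameter; `model_G`: random-effect covariance matrix; `model_blups`:
#' per-individual random-effect predictions; `model_aic`: Akaike
#' information criterion `-2 logLik + 2 (number of parameters)`.
#'
#' @param fit A `growth_fit`.
#' @return See individual descriptions.
#' @export
model_fixef <- function(fit) nlme::fixef(fit$lme)

#' @rdname model_fixef
#' @export
model_vcov <- function(fit) stats::vcov(fit$lme)

#' @rdname model_fixef
#' @export
model_sigma <- function(fit) fit$lme$sigma

#' @rdname model_fixef
#' @export
model_rho <- function(fit) {
  unname(stats::coef(fit$lme$modelStruct$corStruct, unconstrained = FALSE))
}

#' @rdname model_fixef
#' @export
model_G <- function(fit) {
  G <- nlme::getVarCov(fit$lme)
  m <- matrix(as.numeric(G), nrow(G), ncol(G),
              dimnames = list(rownames(G), colnames(G)))
  m
}

#' @rdname model_fixef
#' @export
model_blups <- function(fit) nlme::ranef(fit$lme)

#' @rdname model_fixef
#' @export
model_aic <- function(fit) {
  ll <- stats::logLik(fit$lme)
  -2 * as.numeric(ll) + 2 * attr(ll, "df")
}

#' @export
logLik.growth_fit <- function(object, ...) stats::logLik(object$lme, ...)

#' Refit a growth model by maximum likelihood
#'
#' @param fit A `growth_fit`.
#' @return The same model refitted with `method = "ML"` (for
#'   likelihood-ratio tests of fixed effects).
#' @export
refit_ml <- function(fit) {
  if (fit$method == "ML") return(fit)
  res <- lme_engine(fit$prep, fit$spec, "ML", fit$random_used)
  out <- fit
  out$lme <- res$fit
  out$method <- "ML"
  out$warnings <- res$warnings
  out$converged <- !any(grepl("iteration limit|convergence", res$warnings,
                              ignore.case = TRUE))
  out
}

#' Marginal log-likelihood of a fitted growth model, from first principles
#'
#' Recomputes the (ML) marginal Gaussian log-likelihood implied by the
#' fitted parameters: for individual `i` with design `X_i`, random-effect
#' design `Z_i` and ages `t_i`, the marginal covariance is
#' `Sigma_i = Z_i G Z_i' + sigma^2 R_i(rho)` with
#' `R_i[s, t] = rho^|t_s - t_t|`, and the log-likelihood is the sum of the
#' corresponding multivariate-normal log-densities of the residuals
#' `y_i - X_i beta`.  Serves as an independent check on the fitting
#' engine and as a diagnostic for externally supplied parameter values.
#'
#' @param fit A `growth_fit`.
#' @param beta,G,sigma2,rho Optional parameter overrides; defaults are the
#'   fitted values.
#' @return Log-likelihood (scalar).
#' @export
marginal_log_lik <- function(fit, beta = NULL, G = NULL, sigma2 = NULL,
                             rho = NULL) {
  d <- fit$prep$data
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(fit$prep$fixed_terms,
                                       collapse = " + "))), d)
  rnd <- setdiff(fit$random_used, "const")
  Z <- stats::model.matrix(
    stats::as.formula(paste("~",
                            paste(c(if ("const" %in% fit$random_used) "1"
                                    else "-1", rnd), collapse = " + "))), d)
  if (is.null(beta)) beta <- model_fixef(fit)
  if (is.null(G)) G <- model_G(fit)
  if (is.null(sigma2)) sigma2 <- model_sigma(fit)^2
  if (is.null(rho)) rho <- model_rho(fit)
  r <- d$value - drop(X %*% beta)
  ## per-record residual SD multipliers under a by-source variance model
  smult <- rep(1, nrow(d))
  vs <- fit$lme$modelStruct$varStruct
  if (!is.null(vs)) {
    vc <- stats::coef(vs, unconstrained = FALSE, allCoef = TRUE)
    smult <- unname(vc[as.character(d$source01)])
  }
  ll <- 0
  for (ix in split(seq_len(nrow(d)), d$id)) {
    if (length(ix) == 0L) next
    ages <- d$age[ix]
    Ri <- rho^abs(outer(ages, ages, "-"))
    si <- smult[ix]
    Zi <- Z[ix, , drop = FALSE]
    Sig <- Zi %*% G %*% t(Zi) + sigma2 * (si %o% si) * Ri
    ch <- chol(Sig)
    u <- backsolve(ch, r[ix], transpose = TRUE)
    ll <- ll - 0.5 * (length(ix) * log(2 * pi) +
                        2 * sum(log(diag(ch))) + sum(u^2))
  }
  ll
}

#' Likelihood-ratio test for the genetic fixed effects
#'
#' Both fits must be ML fits of nested specifications on identical
#' records.  The test statistic is twice the log-likelihood difference,
#' referred to a chi-square distribution with degrees of freedom equal to
#' the difference in fixed-parameter count (1 main effect + one
#' interaction per basis column for the full allelic-score model).
#'
#' @param fit_full,fit_reduced `growth_fit` objects fitted with
#'   `method = "ML"`.
#' @return List with `deviance`, `df` and `p`.
#' @export
lrt_genetic_effect <- function(fit_full, fit_reduced) {
  if (fit_full$method != "ML" || fit_reduced$method != "ML")
    stop("likelihood-ratio tests require ML fits (see refit_ml())")
  if (fit_full$n_obs != fit_reduced$n_obs)
    stop("fits use different records: LRT undefined")
  pf <- length(model_fixef(fit_full))
  pr <- length(model_fixef(fit_reduced))
  if (pf <= pr) {
    if (pf == pr && identical(sort(names(model_fixef(fit_full))),
                              sort(names(model_fixef(fit_reduced))))) {
      ## identical models: deviance 0 by definition
      return(list(deviance = 0, df = 0L, p = 1))
    }
    stop("models are not nested (full model must add fixed effects)")
  }
  if (!all(names(model_fixef(fit_reduced)) %in%
             names(model_fixef(fit_full))))
    stop("models are not nested: reduced terms missing from full model")
  dev <- 2 * (as.numeric(stats::logLik(fit_full$lme)) -
                as.numeric(stats::logLik(fit_reduced$lme)))
  if (dev < 0 && dev > -1e-6) dev <- 0
  df <- pf - pr
  list(deviance = dev, df = df,
       p = stats::pchisq(dev, df, lower.tail = FALSE))
}

## full basis coefficient vector (const first) for one individual:
## fixed part at the individual's covariates/score + BLUP contributions;
## beta/re can be supplied to avoid re-extraction in per-individual loops
individual_coef <- function(fit, id, blup = TRUE, beta = NULL, re = NULL) {
  d <- fit$prep$data
  rows <- which(d$id == id)
  if (length(rows) == 0L) stop("unknown individual id: ", id)
  r1 <- d[rows[1L], , drop = FALSE]
  if (is.null(beta)) beta <- model_fixef(fit)
  labels <- fit$spec$basis$terms$label
  cf <- stats::setNames(numeric(length(labels)), labels)
  cf["const"] <- beta["(Intercept)"]
  for (cn in setdiff(labels, "const"))
    if (cn %in% names(beta)) cf[cn] <- beta[cn]
  ## time-constant covariates shift the intercept (the parental-report
  ## indicator is record-level and excluded: curves are on the clinic scale)
  for (cv in setdiff(fit$prep$covariates, "source01"))
    cf["const"] <- cf["const"] + beta[cv] * r1[[cv]]
  if (fit$spec$genetic != "none") {
    cf["const"] <- cf["const"] + beta["gen"] * r1$gen
    if (fit$spec$interaction) {
      for (cn in setdiff(labels, "const")) {
        gcn <- paste0("gen_", cn)
        if (gcn %in% names(beta)) cf[cn] <- cf[cn] + beta[gcn] * r1$gen
      }
    }
  }
  if (blup) {
    if (is.null(re)) re <- model_blups(fit)
    b <- re[as.character(id), , drop = FALSE]
    renames <- sub("^\\(Intercept\\)$", "const", colnames(re))
    for (k in seq_along(renames)) cf[renames[k]] <- cf[renames[k]] + b[[k]]
  }
  cf
}

#' Individual growth curve from a fitted model
#'
#' The child's predicted curve: population fixed effects evaluated at the
#' child's covariates and genetic score, plus the child's predicted random
#' effects (BLUPs), expressed as an explicit piecewise polynomial over the
#' model's age support.  Parental-report measurement-source effects are
#' not included (curves are on the clinic measurement scale).
#'
#' @param fit A converged `growth_fit`.
#' @param id Individual id present in the fit.
#' @param blup Include the individual's random effects (default); with
#'   `blup = FALSE` the population-average curve at the individual's
#'   covariates is returned.
#' @return A [piecewise_poly()] curve.
#' @export
individual_curve <- function(fit, id, blup = TRUE) {
  if (!fit$converged)
    stop("refusing to derive curves from a non-converged fit")
  cf <- individual_coef(fit, id, blup = blup)
  rng <- if (fit$spec$measure == "infancy") c(0, 5) else c(1, 17.5)
  basis_curve(fit$spec$basis, cf, range = rng)
}

#' Per-allele genetic effect at an age
#'
#' The fitted per-allele (or per-score-unit) effect on the outcome at age
#' `t` is the linear combination of the genetic main effect and its basis
#' interactions with the basis evaluated at `t`; its standard error comes
#' from the fixed-effect covariance by the delta method (the combination
#' is linear, so this is exact).
#'
#' @param fit A converged `growth_fit` with genetic terms.
#' @param age Age in years (within the fitting range).
#' @return Named vector `c(beta, se)`.
#' @export
effect_at_age <- function(fit, age) {
  if (fit$spec$genetic == "none")
    stop("fit has no genetic terms")
  if (!fit$converged)
    stop("refusing to evaluate effects from a non-converged fit")
  if (age < fit$spec$age_range[1] - 1e-9 ||
        age > fit$spec$age_range[2] + 1e-9)
    stop("age ", age, " outside the model's fitting range")
  beta <- model_fixef(fit)
  L <- stats::setNames(numeric(length(beta)), names(beta))
  L["gen"] <- 1
  if (fit$spec$interaction) {
    B <- eval_basis(fit$spec$basis, age)
    for (cn in setdiff(colnames(B), "const")) {
      gcn <- paste0("gen_", cn)
      if (gcn %in% names(L)) L[gcn] <- B[1, cn]
    }
  }
  V <- model_vcov(fit)
  est <- sum(L * beta)
  se <- sqrt(drop(t(L) %*% V %*% L))
  c(beta = est, se = se)
}
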