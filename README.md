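# bmigrowth

Longitudinal genetic epidemiology of childhood growth: spline linear
mixed models for BMI, weight and height trajectories; per-child
adiposity peak and rebound; and association of a 32-SNP adult-BMI
allelic score with trajectories, milestones and birth measures, combined
across cohorts by meta-analysis.

## Who this is for

Analysts of birth-cohort data (repeated anthropometry from infancy to
late adolescence plus genotype dosages) who want to ask *when* known
adult-BMI genetic variants begin to shape growth and *which features of
the growth curve* they move. Because such cohort records are
access-controlled, the package also ships a calibrated synthetic cohort
generator, so the whole pipeline is demonstrable and testable
end-to-end with no external data.

## The model

For child *j* at age *t* (years), a growth measure is modelled as

    y_j(t) = β₀ + β₁a + β₂a² + β₃a³ + Σ_k γ_k (t − κ_k)₊³
             + δ'x_j + s_j·g(t) + z(t)'b_j + e_j(t)

with `a = t − 8` (age centred at 8 years), truncated power terms
`(t − κ)₊³` at knots κ ∈ {2, 8, 12} giving a C² piecewise cubic,
study covariates `x_j` (measurement source, ancestry PCs), the allelic
score `s_j` entering as a main effect plus interactions with every
spline column (the age-varying per-allele effect `g(t)`), child random
effects `b_j ~ N(0, G)`, and continuous-AR(1) residuals,
`corr(e_j(s), e_j(t)) = ρ^|s−t|`. The weight model uses segment degrees
(1, 3, 3, 2); a second infancy model (birth–5 y) supports the adiposity
peak. Estimation is REML via `nlme`; genetic fixed effects are tested
by ML likelihood-ratio tests; the adiposity rebound (interior minimum
in 2–8 y) and peak (interior maximum in 0–2.5 y) are solved
analytically from each child's fitted curve. Two-cohort results are
pooled by fixed-effect inverse-variance meta-analysis (Cochran's Q
reported) for effect sizes and Fisher's method for per-SNP LRT
p-values, against a Bonferroni threshold of 0.05/32 = 0.0016.

See the methods vignette (`vignettes/growth-modelling.Rmd`) for the
full account: basis construction, estimation choices, QC, milestone
rules, and what the synthetic generator does and does not emulate.

## Worked example

```r
library(bmigrowth)

params <- simulation_params("alspac", n = 2000, seed = 42)
cohort <- simulate_cohort(params)                    # growth + genotypes
qc     <- flag_implausible(cohort$growth, full_age_bin_scheme())
score  <- compute_allelic_score(cohort$panel)        # 32-SNP dosage sum

spec <- growth_model_spec("bmi", genetic = "score",
                          covariates = "source01", sex = "female")
fit <- fit_growth_model(qc$growth, spec, score = score)
fit
#> Growth mixed model (bmi, female): 970 individuals, 8610 observations
#>   method: REML | CAR(1) rho: 0.9021 | sigma: 1.04
#>   logLik: -7713.814 | AIC: 15471.63 | converged: TRUE

effect_at_age(fit, 15)       # per-allele BMI effect at age 15 (kg/m^2)
#>       beta         se
#> 0.12217398 0.02121725

ms <- derive_milestones(fit, "adiposity_rebound")
summary(ms$age[ms$valid])    # rebound ages (years)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   2.698   5.136   5.589   5.581   6.060   7.507

d <- merge(ms[ms$valid, ],
           data.frame(individual_id = names(score),
                      score = as.numeric(score)))
linear_assoc(d, "age", "score")[, c("term", "beta", "se", "p", "n")]
#>        term       beta          se           p   n
#> 1 age~score -0.0158513 0.006119137 0.009729401 969

fixed_effect_meta(c(-0.062, -0.047), c(0.011, 0.018))  # two cohorts
#> Fixed-effect meta-analysis (k = 2): beta = -0.05792 (SE 0.009386), p = 6.79e-10
#>   Cochran's Q = 0.5056 on 1 df, p = 0.477
```

Reading the numbers: the CAR(1) correlation of within-child residuals
one year apart is ≈ 0.90; carrying one extra BMI-increasing allele is
associated with ≈ 0.12 kg/m² higher BMI at age 15 in this replicate
(the generator's true value is 0.15); the median adiposity rebound
falls near 5.6 years; each extra allele brings the rebound earlier
(here −0.016 y per allele in one stratum of one simulated cohort — the
generator's population value is −0.036, and single-replicate stratum
estimates scatter around it); and the meta-analysis pools two cohort
estimates with no evidence of heterogeneity.

A command-line driver covering the same stages
(`simulate`, `qc`, `score`, `fit`, `milestones`, `assoc`, `meta`) is
installed as `exec/growthpipe`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "growthpipe", package = "bmigrowth"))')" \
    simulate --preset alspac --n 500 --seed 1 --out-dir demo/
```

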