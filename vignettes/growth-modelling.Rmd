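---
title: "Modelling childhood growth trajectories and their genetic determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling childhood growth trajectories and their genetic determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmigrowth)
```

## The scientific problem

Common genetic variants associated with *adult* body mass index (BMI) are
now well replicated, but when in life their effects emerge, and how they
shape the growth curve, is less clear.  Childhood BMI follows a
characteristic course: a steep rise to the **adiposity peak** around 9
months, a decline to the **adiposity rebound** around 5--6 years, then a
steady rise through adolescence.  Both milestones predict later obesity.
This package implements the analysis pipeline for studying how a fixed
panel of 32 adult-BMI-associated SNPs, combined into an **allelic score**
(the per-child sum of BMI-increasing allele dosages, range 0--64),
associates with:

* the whole BMI/weight/height trajectory from 1 to 17 years,
* the age and BMI at the adiposity peak and rebound, and
* birth weight and length,

in two birth cohorts analysed separately and combined by meta-analysis.

## The longitudinal model

For child $j$ at age $t$ the growth measure is modelled as

$$
y_{j}(t) = \beta_0 + \beta_1 a + \beta_2 a^2 + \beta_3 a^3 +
\sum_{k=1}^{3}\gamma_k\,(t-\kappa_k)_+^3 +
\boldsymbol{\delta}'\mathbf{x}_j +
s_j\,g(t) + \mathbf{z}(t)'\mathbf{b}_j + e_{j}(t),
$$

where $a = t - 8$ is age centred at 8 years (a fixed constant, so
intercepts are comparable across datasets), $(t-\kappa)_+^p$ is the
truncated power basis with knots $\kappa \in \{2, 8, 12\}$ years,
$\mathbf{x}_j$ are study covariates (measurement-source indicator,
ancestry principal components), $s_j$ is the allelic score and
$g(t)$ its age-varying per-allele effect -- parameterised as the score's
main effect plus its interaction with *every* spline column.  Random
effects $\mathbf{b}_j \sim N(0, G)$ act on a subset of the basis, and the
residuals follow a continuous-time AR(1) process,
$\mathrm{corr}(e_j(s), e_j(t)) = \rho^{|s-t|}$ with age in years.

Concretely, per measure:

* **BMI and height**: global cubic in $a$ plus cubic truncated terms at
  2, 8 and 12 y -- piecewise cubic with continuous value, slope and
  curvature everywhere ($C^2$), the minimal basis with "a cubic slope per
  segment" at three knots.
* **Weight**: segment degrees (1, 3, 3, 2) -- linear from 1--2 y, cubic
  2--8 and 8--12 y, quadratic above 12 y.  The drop from cubic to
  quadratic is enforced by a hard linear constraint absorbed into the
  design (the cubic columns at 2 and 8 y each have the 12-y cubic term
  subtracted, and no free 12-y cubic column exists), so the fitter remains
  an unconstrained mixed model.
* **Infancy (birth--5 y)**: the childhood models start at 1 year, after
  the adiposity peak, so a second BMI model is fitted from birth to 5
  years for children with more than two BMI measures in that window:
  cubic in age plus cubic truncated terms at 0.5, 1 and 2 years.  We
  originally tried the more parsimonious single-knot (1 y) version; it
  placed the population peak two months late and corrupted the residual
  correlation estimate, because the true curve rises and turns too
  quickly inside the first year for one knot to follow.  The two extra
  infancy knots remove the bias (checked against generator ground truth).

### Estimation

Fitting is restricted maximum likelihood (REML) via `nlme::lme` with
`corCAR1(form = ~ age | id)`; likelihood-ratio tests (LRTs) of the genetic
fixed effects refit both nested models by ML, with degrees of freedom 1
(main effect) + 6 (interactions with the non-constant basis columns) = 7
for the BMI/height model.  `marginal_log_lik()` re-derives the marginal
Gaussian log-likelihood per child,
$\Sigma_j = Z_j G Z_j' + \sigma^2 D_j R_j(\rho) D_j$, from first
principles as an independent check on the engine (the test suite compares
it with a dense multivariate-normal evaluation).

Two estimation choices matter and are package design decisions:

* **Random-effect columns** default to $\{1, a, a^2, (t-2)_+^3\}$ for
  BMI/height ($\{1, a, (t-2)_+^2\}$ for weight; $\{1, t, t^2\}$ for
  infancy), giving child-specific level, slope and curvature so that the
  rebound varies across children while remaining estimable from a median
  of 6--9 measures.  The covariance is diagonal by default
  (`re_structure = "general"` fits an unstructured $G$): with sparse
  per-child schedules the unstructured fit is slow and occasionally
  ill-conditioned, while the diagonal fit recovers all generator
  parameters without bias.
* **Differential measurement error.**  Parental-report measurements are
  noisier than clinic ones.  A mean shift (the source indicator as a
  fixed effect) does not capture that; the package therefore also fits a
  per-source residual *variance* (`nlme::varIdent`).  This matters: with
  inflated parental noise in the data and a homoscedastic CAR(1) model,
  the likelihood trades the residual correlation away and $\hat\rho$
  collapses toward 0; with the variance term, $\hat\rho$ is unbiased.
  Set `source_variance = FALSE` in `growth_model_spec()` to reproduce the
  mean-shift-only behaviour.

## Milestones

Each child's curve is the population fixed effects evaluated at their
covariates and score plus their predicted random effects (BLUPs),
re-expressed as an explicit piecewise polynomial.  The **rebound** is the
interior minimum of that curve in [2, 8] years: the derivative (a
quadratic per segment) is solved analytically, roots strictly inside the
window (tolerance $10^{-6}$ y) with positive curvature are kept, and the
lowest-BMI root wins (earliest age on ties).  The **peak** is the interior
maximum in [0, 2.5] years of the infancy-model curve.  Boundary roots are
never reported as milestones: they indicate the window clipped a monotone
trend, and the milestone is returned invalid with a reason
(`no_stationary_point`, `wrong_curvature`, `boundary`).

Because BLUPs are shrunken toward zero -- strongly so in the infancy model,
where a high residual correlation over a short age window absorbs much of
the between-child variation -- the spread of *estimated* milestone ages
understates the true between-child spread.  Score--milestone regressions
are unaffected (the score enters the fixed effects), but descriptive SDs
of estimated milestones should be read as properties of the estimates.

## QC

Implausible measurements are screened in two stages.  A plausibility
range per measure (BMI 5--100 kg/m$^2$, weight 0.3--300 kg, height
20--272 cm; `hard_value_limits()`) removes physically impossible values
-- unit and decimal-point recording errors -- outright.  The remaining
values are screened per (sex, age-bin, measure) cell:
values more than 4 sample SDs from the raw cell mean are recoded to
missing, in a single pass (means and SDs are not recomputed after
recoding: iterating the rule has no canonical stopping convention, and a
single pass is reproducible).  Zero-SD cells flag nothing.  The default bins are
the cohort descriptive strata (1--1.49, 1.5--2.49, ..., >16.5 years);
`full_age_bin_scheme()` prepends infancy bins so data feeding the
birth--5 y model are screened too.  Birth measures are never screened
(they are covariate-adjusted outcomes, not trajectory points).

The 4 SD rule has known structural blind spots that users should be aware
of: a gross outlier inflates its own cell's SD (masking smaller outliers,
and in cells with $n \le 16$ even itself), and the lower 4 SD bound at
adolescent ages can be near zero.  In particular, a lone gross
outlier in a cell of $n \le 16$ records always masks itself
($|x - \bar x| = (1 - 1/n)\Delta$ can never exceed
$4\,\Delta/\sqrt{n}$ there), which is exactly why the range screen
runs first: schedule-jitter spillover bins in a sparse cohort can hold
single-digit counts, and one surviving tenfold error is enough to
destabilise a whole stratum's mixed-model fit.

## Genetics

Dosages (expected effect-allele counts in [0, 2], from imputation) are
consumed as given; the packaged reference panel (`bmi_snp_panel()`)
records each SNP's effect allele, published adult-BMI effect and cohort
allele frequencies.  `harmonise_dosages()` flips dosages whose declared
alleles are swapped relative to the reference and refuses strand-ambiguous
A/T and C/G flips.  The unweighted score is the dosage row sum; the
weighted sensitivity variant multiplies by published effect sizes.
Missing dosages are SNP-wise mean-imputed (with a logged count) to
preserve the score scale.

Meta-analysis across the two cohorts uses fixed-effect inverse-variance
pooling for effect sizes (with Cochran's Q reported, never used to switch
models) and Fisher's unweighted $-2\sum\log p$ combination for per-SNP
LRT p-values, with a Bonferroni threshold of $0.05/32 = 0.0016$ (2 s.f.)
for per-SNP significance and $p < 0.05$ for the score.

## The synthetic cohort generator

Real cohort records of this kind are access-controlled, so the package
ships a generator (`simulate_cohort()`) whose defaults emulate the study
conditions end to end; every stage of the pipeline is tested against it.

**True curves.**  Each sex's population BMI curve is piecewise cubic and
$C^2$ on [0, 17.5] y, built in two glued pieces: a childhood piece on
[1, 17.5] expressed in exactly the fitted model's basis, solved from
descriptive anchors (BMI 17.75/17.30 and slope -0.45/-0.30 at 1 y for
males/females; rebound at 6.07/5.61 y with BMI 15.62/15.53; BMI
17.8/17.6 at 10 y, 19.8/19.5 at 13 y, 23.0/22.4 at 17 y), and an infancy
piece on [0, 1] (cubic plus truncated cubics at 0.5, 0.8, 0.9 y) solved
from birth BMI 13.6/13.3, a mid-rise anchor at 0.35 y, the adiposity peak
(18.03 kg/m$^2$ at 8.90 months for males, 17.45 at 9.36 for females, with
zero slope) and second-order continuity at 1 y.  Solving the two pieces
separately keeps the linear systems well conditioned; a single global
solve across 0--17.5 y is numerically singular.  The resulting curves
have exactly two stationary points (the peak and the rebound).

**Genetic effect.**  The per-allele effect
$g(t) = g_1 t + g_2 t^2 + g_3 (t-2)_+^3$ lies inside the span of the
fitted interaction terms (so recovery is well defined) and is solved per
sex from three anchors: $g(15) = 0.15$ kg/m$^2$ per allele, the effect on
BMI at the rebound (0.0332 females / 0.0364 males), and a rebound-age
shift of $-0.036$ y per allele imposed through the population curvature
at the rebound, $\Delta t_{AR} \approx -g'(t_{AR})/\mu''(t_{AR})$.  The
exact (non-linearised) population rebound shift per allele was verified
to be $-0.0360$.  Setting all three anchors to zero gives an exact null
generator for type-I-error studies.

**Individual variation and noise.**  Random effects are independent
normals on $\{1, a, a^2, (t-2)_+^3\}$ with SDs (1.0, 0.15, 0.012, 8e-4),
chosen to reproduce the cohorts' age-specific BMI SDs (about 1.5 kg/m$^2$
at age 1--3 rising to about 3 by 16).  Residuals are CAR(1) with
$\sigma = 0.7$ and $\rho = 0.9$ per year; parental-report records have
their residual scaled by 1.5 (scaling preserves the correlation
structure while inflating the variance, matching the fitted
variance-by-source model).  Heights follow a saturating-plus-logistic
curve per sex with CAR(1) noise sharing $\rho$; weight is derived as
BMI $\times$ height$^2$, so the three measures are mutually consistent
within recording precision (BMI to 0.01, weight 0.01 kg, height 0.1 cm).

**Schedules.**  The dense cohort template draws visits from 17 nominal
ages with the attendance rates and age jitter of the reference cohort's
descriptive table (median 9 BMI measures per child between 1 and 17.5 y;
high-attendance toddler and pre-teen waves flagged as parental reports)
plus five infancy visits supporting the peak model; the sparse template
has 8 clinic-only visits (median 6 measures) with essentially no data
between 3.5 and 5.5 years.  Birth weight and length (age-0 records and
covariates) are gestational-age adjusted; ancestry PCs are standard
normals with zero effect; the score has zero effect on birth measures by
default (configurable for power studies).

**Implausible values** are injected as decimal-shift recording errors
(value $\times$ 10) at rate 0.001 on post-birth records.  This choice is
deliberate: errors of that scale are always caught by the 4 SD screen,
whereas milder two-sided errors (e.g. $\times 1.5$) can survive it at
adolescent ages -- they are, arguably, not "implausible" at all -- and a
single surviving 5--10 kg/m$^2$ residual adjacent to a companion visit is
enough to collapse the CAR(1) correlation estimate.  The generator's
parental-noise inflation, not the implausible-value channel, models the
mild end of measurement error.

**What the generator does not emulate**: the strong tracking between
rebound BMI and late-adolescent BMI seen in real cohorts (independent
random effects put most adolescent BMI variance in a late-acting
curvature component, so rebound BMI explains only a few percent of final
BMI here, versus ~45% reported in cohort data -- matching it would need
correlated level/curvature random effects, deliberately mis-specified
relative to the fitted diagonal-covariance model); linkage
disequilibrium between SNPs, population-structure confounding (PCs are pure noise), genetic
effects on height, secular trends, visit-level missingness correlated
with phenotype, or pubertal-timing biology.  Passing tests on this
generator therefore demonstrate the pipeline's correctness and its
statistical calibration under the stated model, not robustness to every
failure mode of real cohort data.

## Numerical choices

* Curves are stored as piecewise polynomials in *local* segment
  coordinates $(t - \tau_j)$; evaluation and root-finding stay well
  conditioned across the full age range.
* Derivative roots use the numerically stable quadratic formula (or
  `polyroot()` above degree 2); window endpoints are excluded with a
  $10^{-6}$ y tolerance.
* Model fitting retries with a reduced random-effect set (dropping the
  last column) if a fit fails outright; a reduction is messaged and
  recorded in the fit object.  Non-converged fits are flagged and
  downstream stages refuse them.
* Exactly duplicated (child, age) records are dropped before fitting:
  zero time-lags make the CAR(1) correlation matrix singular.
* Variance-explained curves use marginal (population-level) residuals:
  the score is a fixed effect, so its contribution should be judged
  against the marginal fit; negative bin estimates are floored at zero.
  One-year bins centred on integer ages 1--16 match the per-year
  reporting convention.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run the pipeline at reduced
but statistically meaningful sizes, chosen so every check retains power:
parameter recovery uses 20 replicate cohorts of n = 2,000 children
(recovering $g(15)$, the rebound-age shift and $\rho$); null calibration
of the LRT uses 200 replicates of n = 240 clinic-template children;
Cochran's Q, Fisher combination and the Bonferroni family-wise error rate
use 200 analytic-null replicates each; the acceptance script simulates a
1,500-child dense cohort and a 500-child sparse cohort, about a fifth of
the reference study's size.

## Known limitations

* The exact random-effect structure and infancy-model specification of
  the original analyses are not recoverable from the source descriptions;
  the defaults here are declared reconstructions, and milestone
  descriptives (especially infancy BLUP spread) depend on them.
* The LRT for the score's 7 genetic parameters is mildly anticonservative
  in very small strata (under ~100 children); null calibration is
  verified at 120+ children per stratum.
* Height effect sizes are reported in cm per allele throughout; no
  attempt is made to match ambiguous published height units.
* The weighted (published-effect) score is provided as a sensitivity
  analysis only; all headline analyses use the unweighted score.
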