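---
title: "Age-specific mortality analysis of sex differences in mouse cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-specific mortality analysis of sex differences in mouse cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murihaz)
```

## The scientific problem

In genetically heterogeneous (UM-HET3) mouse colonies, females outlive males
in median lifespan, yet the sexes do not differ in "maximum" lifespan (the
age the pooled population reaches 90% mortality). These two facts together
imply that the sex difference in mortality is age-specific: the male
disadvantage is concentrated in early and middle adult life and disappears
in old age. Demonstrating that requires estimating the age-specific
mortality hazard — the instantaneous death rate conditional on survival —
separately per sex, forming their ratio as a function of age, and attaching
uncertainty to that curve. murihaz implements this analysis end to end:

1. a penalized B-spline Poisson (P-spline) smoother for the hazard from
   censored, left-truncated lifespans (`bin_exposure()`,
   `fit_smoothed_hazard()`, `select_smoothing()`);
2. the male:female hazard-ratio curve with animal-level bootstrap
   confidence bands and a peak/convergence summary (`hazard_ratio_curve()`,
   `bootstrap_hr()`, `hr_summary()`);
3. classical survival comparisons: Kaplan–Meier medians with CIs, the
   log-rank test, and the maximum-lifespan proportion test
   (`survival_summary()`, `max_lifespan_test()`);
4. Cox proportional-hazards models with a sex×site interaction
   (`cox_fit()`);
5. age-stratified OLS regressions of lifespan on bodyweight with
   standardized coefficients and interaction models
   (`weight_regression()`, `interaction_regression()`);
6. a synthetic cohort generator (`sim_config()`, `simulate_cohort()`)
   that emulates the statistical structure of such a colony, because the
   original study data are only available on request.

The numbered scripts under `analysis/` run these stages over a simulated
cohort and write their tables under `results/`.

## The hazard smoother

Lifespans are binned into 30-day age intervals from weaning (21 d; animals
contribute no person-time or events before study entry). Bin $j$ carries
the death count $d_j$ and the person-time (animal-days at risk) $R_j$. The
model is
$$d_j \sim \mathrm{Poisson}(R_j\,h_j), \qquad
  \log h_j = \sum_k B_k(t_j)\,\theta_k,$$
with $B_k$ a B-spline basis over age and $t_j$ the bin midpoint. The
penalized log-likelihood
$$\ell(\theta) - \tfrac{\lambda}{2}\,\lVert D_2\,\theta \rVert^2$$
is maximized by penalized iteratively reweighted least squares (converged
when the largest coefficient change falls below $10^{-8}$, at most 100
iterations). $D_2$ is the second-order difference operator, so infinite
smoothing collapses the fit to a log-linear — i.e. Gompertz — hazard, and
$\lambda = 0$ with a degree-0, one-basis-per-bin layout reproduces the raw
occurrence/exposure rates $d_j/R_j$ exactly. Pointwise intervals come from
the penalized-information covariance of the linear predictor,
$B(B^\top W B + \lambda D_2^\top D_2)^{-1}B^\top$, exponentiated around the
fitted log-hazard.

**Basis.** The default basis uses 31 equally spaced interior knots and
degree-1 (linear) B-splines. A rich, low-degree basis with a difference
penalty is the standard P-spline hazard arrangement: flexibility lives in
the basis, smoothness in the penalty. A sparser cubic basis (e.g. 12 knots)
visibly attenuates sharp mid-life structure at realistic cohort sizes; the
default was chosen to keep the mid-life peak of the hazard ratio
essentially unbiased. Both knot count and degree are arguments.

**Smoothing selection.** `select_smoothing()` treats the penalized
coefficients as random effects with variance $\sigma^2 = \phi/\lambda$ and
alternates (i) fitting given $\lambda$ with (ii) updating
$\sigma^2 = (\lVert D_2\hat\theta\rVert^2 +
\mathrm{tr}(D_2\,\mathrm{Cov}(\hat\theta)\,D_2^\top))/m$, until the
relative change in $\lambda$ falls below $10^{-4}$ (at most 50 iterations).
Two numerical choices matter. First, when the true log-hazard lies in the
penalty null space (exactly Gompertz data), the alternation drifts
geometrically toward $\lambda = \infty$ and never meets a relative
tolerance; the iteration therefore applies Aitken extrapolation on
$\log\lambda$ once the step ratio stabilizes, and treats
$\lambda \ge 10^8$ as boundary convergence (the fit is then the Gompertz
limit and no longer changes with $\lambda$). Second, a ridge of
$10^{-9}\times$ the data-information scale guards the IRLS solve against
numerically empty basis support in sparse bootstrap resamples; it is placed
on the information scale specifically so it cannot perturb the penalty null
space even at extreme $\lambda$. Overdispersion $\phi$ is fixed at 1 by
default (`phi = "pearson"` estimates it).

## The hazard-ratio curve and its bands

`hazard_ratio_curve()` fits the smoother to each sex with identical
settings and evaluates $\widehat{\mathrm{HR}}(t) =
\hat h_M(t)/\hat h_F(t)$ on a 5-day grid. The grid stops where either sex
drops below 10 animals at risk or below 5% of its starting risk set
(the 95% quantile of observed exit ages): at the spline's right boundary a
handful of deaths determine the fit, the point estimate wanders, bootstrap
replicates wander with it, and percentile bands undercover — the standard
reason survival displays are truncated before the extreme tail.

**Bias correction.** A penalized fit attenuates curvature extremes, and the
ratio of two penalized fits inherits that attenuation precisely at the
mid-life peak the analysis cares about; in simulations the peak was shaved
by roughly 8%, and percentile bootstrap bands inherit the bias as
undercoverage. Each sex's log-hazard therefore receives a twicing
(double-smoothing) correction by default: the smoother is refit to its own
fitted event counts, the difference estimates the self-attenuation, and it
is subtracted ($\tilde\eta = 2\hat\eta - S_\lambda\hat\eta$). The
correction is identically zero for any fit in the penalty null space, so
Gompertz-limit behaviour is untouched; `bias_correct = FALSE` disables it.

**Bootstrap.** `bootstrap_hr()` resamples animals with replacement within
each sex, recomputes the corrected HR curve per replicate — re-selecting
$\lambda$ inside every replicate so the band carries smoothing uncertainty
— and takes pointwise 2.5/97.5 percentile bands (inverse-ECDF quantiles, so
a 2-replicate band is exactly the replicate range). Replicates in which a
sex draws no events are redrawn and counted. The summary reports the peak
(argmax of the point estimate, first age on ties; flagged "no distinct
peak" if the curve's range is below 0.05) and the convergence age: the
smallest post-peak grid age from which the band contains 1 at *every* later
grid age — sustained indistinguishability, not a single touch.

## Classical comparisons

Kaplan–Meier curves, medians and the log-rank test go through the
`survival` package. Median CIs invert the log-transformed pointwise
survival band, with the cumulative-hazard variance from either the
Greenwood (default) or the Aalen/Tsiatis estimator. The maximum-lifespan
test estimates the age of pooled 90% mortality from the pooled KM curve
(censoring-consistent), excludes animals censored before that age (their
status there is unknown; a config switch could include them), and compares
the per-sex proportions still alive by a two-sided Fisher exact test with
Clopper–Pearson proportion CIs. The Cox model uses Efron tie handling with
reference levels female and TJL; the sex×site interaction block is judged
by a likelihood-ratio test, which is invariant to dummy coding.

## The synthetic cohort generator

The study's raw data are available only on request, so every stage is
exercised against a generator that emulates the colony's statistical
structure. Its defaults are the package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `gompertz_b` | 0.004 /d | female log-hazard slope |
| `gompertz_a` | solved | scale, calibrated so the female median is ≈890 d |
| `hr_peak_ratio` | 2.2 | male:female hazard ratio at the peak |
| `hr_peak_age_days` | 350 d | age of the peak |
| `hr_convergence_age_days` | 800 d | age from which the ratio is 1 |
| `sites` | TJL 1, UM 0.75, UT 1 | male-only hazard multipliers |
| `cage_censor_prob_m` | 0.06 | probability a male cage (3 animals) is censored |
| `frailty_hazard_coupling` | 0.2 / 0.2 (F/M) | log-hazard loading of the shared frailty |
| weight couplings | 0.8 / 1.5 g (F/M) | asymptote shift per frailty SD |
| `terminal_loss_fraction`, `terminal_window_days` | 0.10, 90 d | pre-death wasting |
| `measurement_noise_sd_g` | 1.5 g | weight measurement noise |

The male hazard is $m_{\text{site}}\,h_F(t)\,r(t)$ with
$\log r(t) = \log(2.2)\,B(t)$, $B$ a two-piece cubic smoothstep bump that
is 0 at weaning, 1 at 350 d, and 0 from 800 d on. Death ages are drawn by
inverse transform on the numerically integrated cumulative hazard (1-day
trapezoid grid, analytic Gompertz tail), scaled per animal by
$e^{0.2 z_i}$ with a standard-normal frailty $z_i$. The same $z_i$ shifts
the animal's adult weight asymptote, which creates the negative
weight–lifespan correlation; pre-death wasting (10% of the asymptote over
the last 90 days) makes weights taken at 24 months positively predictive
among survivors, reproducing the sign reversal. Male cages of three are
censored with probability 0.06 at an age uniform between weaning and the
cage's earliest death, mimicking whole-cage removal after fight injuries.
Site blocks use derived seeds so a site can be regenerated independently.

**Calibration choices and their limits.** The generator holds the
hazard-shape anchors (peak 2.2 at 350 d, convergence at 800 d) and the
female median (≈890 d) exactly, and accepts the consequences elsewhere;
these are worth knowing when interpreting green tests:

* *Male median.* With a Gompertz female baseline, the male excess closing
  at 800 d cannot push the pooled male median to the study's 803 d; it
  lands near 865 d (≈27 d below the female). Flattening the baseline
  enough to widen the gap floods early life with deaths and (through the
  wasting term) flips the 6-month weight–lifespan slope positive, so the
  shape anchors won.
* *Log-rank power.* Because most simulated deaths occur after the excess
  closes, the pooled log-rank is only weakly significant at the study's
  size — unlike the real study. The age-specific analyses, not the
  log-rank, carry the sex signal here, which is in fact the analysis's
  own point.
* *Site mixture.* With a male-only UM advantage, the pooled-population HR
  is a survivors-weighted mixture across sites and genuinely sits slightly
  below 1 in old age. The generator's configured bump is the pooled truth
  only when site multipliers are equal, so truth-recovery experiments run
  the preset with homogeneous sites; the UM effect is kept for the Cox and
  median analyses. The UM multiplier 0.75 was chosen so UM males
  approximately match UM females, the study's qualitative finding; a
  stronger advantage makes UM males outlive females outright.
* *Slope magnitudes.* The sex asymmetry in weight–lifespan slopes holds in
  expectation (males steeper), but per-seed slope estimates are dominated
  by a few high-leverage early deaths, so single-cohort magnitude ordering
  is unreliable and only the sign pattern (negative at 6 months, positive
  at 24, per sex and pooled) is asserted by tests. For the same reason the
  sex×weight interaction test has modest power at realistic sizes under
  this single-shared-frailty mechanism; the null calibration (type-I
  error) is unaffected.
* *Informative censoring.* Coupling the cage-censoring age to the cage's
  earliest death makes censoring mildly informative. KM medians remain
  essentially unbiased against generator truth (checked at n = 24,000),
  but raw observed-age medians are not; analyses use KM.

What passing tests show, therefore, is that the pipeline recovers the
structure this generator encodes — smooth hazards, a mid-life excess
with sustained late-life convergence, a male-only site effect, and the
weight–lifespan sign pattern — under censoring and left truncation. They
do not show that real colony data meet the generator's assumptions
(proportional frailty, Gompertz baseline, symmetric measurement noise,
non-informative scheduling of weighings).

## Problem sizes used by tests and scripts

The test suite and `scripts/acceptance.R` scale the experiments to desk
size as the package's own choice of problem sizes: smoother checks at
n = 2,000 lifespans; HR peak/convergence recovery at n ≈ 5,000 per sex with
200 bootstrap replicates; band coverage as 100 repetitions at n = 1,800 per
sex, B = 200; null calibration as 100 seeds at n ≈ 500 per sex; the
acceptance script simulates the study's own size (3,690 animals). Larger
runs change none of the qualitative conclusions, only the widths of the
bands.

## A worked example

```{r example, eval = FALSE}
library(murihaz)

sim <- simulate_cohort(paper_like_config(n_per_sex_per_site = 615, seed = 1))
ss  <- survival_summary(sim$cohort)
ss$median$F$median_days   # ~882
ss$median$M$median_days   # ~829

hb <- bootstrap_hr(sim$cohort, B = 200, seed = 2)
hr_summary(hb)            # peak ~1.7-2.1 in mid-life

cox_fit(sim$cohort)       # sexM:siteUM HR near the configured 0.75

j <- join_weights(sim$cohort, sim$weights)
weight_regression_tables(j)$pooled   # negative at 6 mo, positive at 24 mo
```

## Known limitations

Beyond the generator limits above: the smoother has no time-varying
covariates and no competing risks; the bootstrap stratifies by sex only
(site/cohort stratification would be a straightforward extension); cohort
years are pooled in all hazard analyses, so cohort heterogeneity is
absorbed into the marginal hazard; and no multiplicity correction is
applied across the four weight-measurement ages, matching the analysis
this package reproduces.
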