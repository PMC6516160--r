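# murihaz

Age-specific mortality analysis of sex differences in genetically
heterogeneous mouse cohorts.

## The problem

In UM-HET3 mouse colonies females outlive males in median lifespan, yet the
sexes reach "maximum" lifespan (the age of pooled 90% mortality) at equal
rates. Reconciling those facts requires treating age as an independent
variable: estimating the age-specific mortality hazard per sex, forming the
male:female hazard ratio as a function of age, and asking where the male
excess peaks and where the sexes become indistinguishable. murihaz is an R
package plus a scripted analysis that does this end to end, for
biostatisticians and aging researchers working with censored rodent
survival data.

At its core is a P-spline hazard smoother. Deaths `d_j` and person-time
`R_j` in 30-day age bins (left-truncated at weaning) enter a penalized
Poisson model

    d_j ~ Poisson(R_j h_j),   log h_j = B(t_j) θ,
    maximize  ℓ(θ) − (λ/2) ‖D₂θ‖²

with a rich linear B-spline basis `B`, a second-order difference penalty
(so λ → ∞ is the Gompertz limit, and λ = 0 with per-bin indicators is the
raw occurrence/exposure rate `d_j/R_j`), and λ selected by a
variance-component iteration. The male:female ratio of two such fits, with
a twicing bias correction and animal-level bootstrap percentile bands
(λ re-selected per replicate), yields the hazard-ratio curve, its mid-life
peak, and its convergence age — the first age from which the band contains
1 ever after. Around this sit Kaplan–Meier medians with CIs, the log-rank
test, a maximum-lifespan Fisher test, Cox models with a sex×site
interaction, and age-stratified weight–lifespan regressions. A synthetic
cohort generator with a shared per-animal frailty linking mortality and
bodyweight makes everything testable without the restricted colony data.

## Worked example

```r
library(murihaz)

sim <- simulate_cohort(paper_like_config(n_per_sex_per_site = 615, seed = 1))
ss  <- survival_summary(sim$cohort)
```

gives (seed 1) a cohort of 3,690 animals with

```
median lifespan F: 882 d (95% CI 868-898)
median lifespan M: 829 d (95% CI 810-850)
90%-mortality age: 1196 d; alive beyond it: F 0.100, M 0.099; fisher p = 0.911
```

— a clear female median advantage but no sex difference in reaching extreme
age, which is exactly the tension the age-specific analysis resolves:

```r
hb <- bootstrap_hr(sim$cohort, B = 200, seed = 2)
hr_summary(hb)
#> $peak_age_days  411
#> $peak_hr        1.72
#> HR at 350 d: 1.70 [1.45, 2.12]
```

The male excess peaks in mid-life and the band closes onto 1 in late life
(promptly on site-homogeneous cohorts — there the recovered convergence age
is ~720 d against a configured 800 d; with the male-only UM site advantage
the pooled old-age ratio sits slightly below 1 and convergence is detected
late — see the vignette). The Cox model recovers the male-only site
effect:

```r
cox_fit(sim$cohort)
#>         name coefficient     se hazard_ratio       p
#>  sexM:siteUM    -0.24620 0.0823       0.7817 0.00276
#> Interaction LRT: chi2 = 9.535 on 2 df, p = 0.0085
```

and the weight regressions show the sign reversal with age of measurement
(pooled slope −5.1 days/g at 6 months, +3.7 at 24, this seed).

The numbered scripts under `analysis/` run these stages in order
(`Rscript analysis/01_simulate_cohort.R`, ...) and write their tables under
`results/`; `run_pipeline()` does the same through one configured call with
a checksummed run manifest.

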