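# dietjm

Joint models for longitudinal childhood food consumption and an
interval-censored disease endpoint.

## The problem

Prospective birth cohorts that follow children at genetic risk of type 1
diabetes measure food consumption repeatedly (3-day food records at
scheduled ages from 3 months to 6 years) and screen for islet
autoantibodies at 3- to 12-month visit intervals, so the endpoint —
advanced islet autoimmunity, or type 1 diabetes itself — is known only up
to a visit interval. Relating a noisy, irregularly observed exposure
trajectory to such an endpoint with a last-value-carried-forward Cox model
attenuates associations toward the null; joint models that treat the
smooth underlying trajectory as the hazard covariate do not. `dietjm`
implements the full model battery for this design, plus a synthetic cohort
generator with known ground truth so every estimator can be validated by
parameter recovery:

- **CRM** — Cox regression with the last recorded 3-day mean carried
  forward as a piecewise-constant time-dependent covariate
  (counting-process rows, midpoint event times, energy adjustment,
  Rubin-pooled multiple imputation for partially observed records);
- **JM** — a shared-random-effects joint model: a cubic B-spline mixed
  model for the trajectory, `y_i(t) = β0 + b0i + Σk (βk + bki) Bk(t) +
  ε_i(t)`, linked to a relative-risk model `h_i(t) = h0(t) exp(γ'w_i +
  α m_i(t))` with a piecewise-constant baseline hazard (knots 1.99 and
  3.99 years) through the current smoothed value `m_i(t)`, estimated by
  maximizing the joint marginal likelihood with pseudo-adaptive
  Gauss-Hermite quadrature (compiled likelihood and analytic score);
- **JLCMM** — a joint latent class mixed model: class-specific spline
  trajectories and class-specific piecewise baseline hazards (extra knot
  at 5.99 years, follow-up to 15 years) linked only through class
  membership, estimated by EM with quasi-Newton polishing; delta-method
  piecewise hazard ratios, an overall proportional-hazards class ratio,
  BIC-guided class-number selection;
- supporting machinery: BIC-driven interior-knot search for the
  trajectory basis, Kaplan-Meier curves, a baseline-factor Cox table,
  Fisher's exact test, delete-5 jackknife standard errors,
  multiple imputation for the interval-censored event times, and
  equal-event-count baseline-hazard knot sensitivity refits.

Hazard ratios are reported per 10 g/day of consumption, or per 1 g/MJ
after energy adjustment.

## A worked example

```r
library(dietjm)
co <- simulate_cohort(cohort_config(n_subjects = 800, seed = 20190523,
                                    followup_max = 6))
jm <- fit_jm(co$long, co$endpoints, co$baseline, spline_spec())
print(jm)

ep  <- truncate_endpoints(co$endpoints, 6)
cp  <- build_counting_process(occasion_means(co$long), ep, co$baseline)
crm <- fit_cox_td(cp, covariates = c("sex", "genetic_risk",
                                     "familial_diabetes"))
print(crm)
```

which prints (800 children, 12,843 daily food records, 38 detected
events by 6 years):

```
Joint model fit: 800 subjects, 38 events, loglik -58714.81
association: HR 1.093 (0.926, 1.289) per 10-unit increment, P = 0.2924
baseline covariates:
                             term    coef       se       hr    lo    hi        p
girl                         girl  -0.643    0.349 5.26e-01 0.265  1.04 6.53e-02
high_risk               high_risk   0.432    0.371 1.54e+00 0.745  3.18 2.44e-01
familial_yes         familial_yes   1.609    0.399 5.00e+00 2.285 10.92 5.58e-05
familial_missing familial_missing -16.653 3107.917 5.86e-08 0.000   Inf 9.96e-01

Step-function Cox fit (breslow ties): HR 1.021 (0.883, 1.181) per 10-unit increment, P = 0.7786
```

The generating truth here is an HR of 1.06 per 10 g/day: the joint model
estimate (1.093) brackets it inside a wide interval at this sample size,
while the step-function Cox estimate (1.021) sits closer to the null —
the attenuation the joint model exists to avoid. The `familial_missing`
stratum has no events in this replicate, so its log hazard ratio
diverges and is reported with an effectively infinite standard error.
The latent-class side works the same way from
`simulate_latent_class_cohort()`, `fit_jlcmm()`, `piecewise_hr()` and
`overall_hr_proportional()`; the methods vignette
(`vignettes/dietjm-methods.Rmd`) documents the models, the estimation
and numerical choices, and what the synthetic cohorts do and do not
emulate.

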