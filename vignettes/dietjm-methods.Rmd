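---
title: "Models and methods in dietjm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dietjm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dietjm` relates longitudinal childhood food consumption to an
interval-censored disease endpoint (advanced islet autoimmunity, or type 1
diabetes as a secondary endpoint) with three complementary models, and
ships a synthetic cohort generator with known ground truth so that every
stage of the pipeline can be validated by parameter recovery. This
vignette explains the models, the estimation choices, the generator's
design, and what the package's tests do and do not establish.

## The three models

**Step-function Cox model (CRM).** The naive comparator: each child's
last recorded 3-day mean intake is carried forward as a piecewise-constant
time-dependent covariate in a Cox model on counting-process rows, with
events placed at the midpoint of the interval between the last negative
and first positive antibody visit, and administrative censoring at 6 years
(the end of the food-record schedule). Hazard ratios are reported per
10 g/day, or per 1 g/MJ after energy adjustment. Estimation is delegated
to `survival::coxph` (Breslow ties by default, Efron by flag); the
counting-process construction, inclusion accounting and reporting are the
package's own. Because the observed 3-day means carry substantial
within-person day-to-day noise, this estimator is attenuated toward the
null — reproducing that attenuation against the joint model is one of the
package's acceptance checks.

**Shared-random-effects joint model (JM).** The child's smooth
consumption trajectory is

y_i(t) = m_i(t) + e_i(t),  m_i(t) = b0 + b0_i + sum_k (b_k + b_ki) B_k(t),

a cubic B-spline (two interior knots, intercept + 5 basis columns) with a
subject-specific random intercept and random spline coefficients, diagonal
random-effect covariance D and independent Gaussian residuals. The hazard
is

h_i(t) = h_0(t) exp(gamma' w_i + alpha m_i(t)),

a current-value association on a piecewise-constant baseline hazard with
knots at 1.99 and 3.99 years, follow-up to 6 years. Both submodels are
estimated simultaneously by maximizing the joint marginal likelihood,
integrating the 6-dimensional random effect numerically. The reported food
hazard ratio is exp(10 alpha).

**Joint latent class mixed model (JLCMM).** G latent classes carry
class-specific fixed spline trajectories and class-specific piecewise
baseline hazards (an extra knot at 5.99 years, follow-up to 15 years);
the two submodels are linked only through class membership, whose prior
probabilities come from an intercept-only multinomial logit — so classes
are defined by the consumption profiles alone. Baseline-covariate effects
are shared across classes. Random effects integrate analytically here, so
the mixture likelihood is closed-form. Class-2-vs-class-1 baseline-hazard
ratios are reported per age interval with delta-method intervals, and an
overall ratio comes from a refit constraining the class hazards to be
proportional.

## Estimation choices

**Trajectory mixed model.** Maximum likelihood throughout (not REML):
the joint models and BIC comparisons across different fixed-effect
structures require comparable likelihoods. Fixed effects are profiled out
by GLS; the seven variance parameters are optimized on the log scale with
an analytic gradient (envelope theorem at the GLS optimum). A log-variance
reaching the floor of -12 is reported as a boundary (hard zero) fit. BIC
uses the number of subjects as the sample size, the convention of the
latent-class literature this package sits in. Subjects sharing a visit
pattern share one covariance factorization, which keeps cohort-scale fits
fast. The fit is verified in the test suite against an independent
implementation (`nlme::lme` with a diagonal positive-definite structure)
to likelihood equality.

**Knot search.** Candidate interior knots are the four equispaced points
inside every gap of the nominal record schedule {0.25, 0.5, 1, 2, 3, 4,
5, 6}; a pair (k1, k2) is admissible when at least two scheduled ages fall
before k1, between the knots, and after k2. Every admissible pair is fit
by ML and the BIC minimizer returned, ties broken toward the smaller first
knot. The nominal schedule, rather than each child's own ages, defines the
candidates: knot placement is a population-level modelling choice and the
schedule is what defines the design.

**Joint-model integration.** The random-effect integral uses
pseudo-adaptive Gauss-Hermite quadrature: nodes are centred and scaled at
each child's empirical-Bayes posterior from the longitudinal-only fit and
held fixed during optimization, with 3 nodes per dimension (729 tensor
nodes) by default. All contractions of the node positions with the design
matrices are precomputed once per fit, and the likelihood and its analytic
score are evaluated in compiled code. Two properties of this scheme
deserve emphasis:

- *It is exact at the centring parameters.* When the evaluated
  longitudinal parameters equal the centring ones, the Gaussian
  longitudinal factor integrates exactly for any node count; only the
  (mild, slowly varying) survival factor is approximated. The test suite
  verifies 3-node vs 5-node stability and agreement with brute-force
  integration in a random-intercept-only configuration.
- *It degrades away from the centring point, and an unconstrained
  optimizer will exploit that.* Driving a random-effect variance far below
  the centring scale makes the fixed rule overestimate the integral, and
  the optimizer can "gain" hundreds of spurious log-likelihood units that
  way. The fit therefore constrains the trajectory block to a generous
  trust region around its longitudinal estimates (default 6 standard
  errors; on the log-variance scale never tighter than 0.5 and never wider
  than 1.0, since weakly identified variance directions would otherwise
  re-open the gap) — the
  neighbourhood where the rule is provably accurate and where the joint
  estimate must lie anyway, since the survival data add little information
  about the trajectory block. After a warm-start chain through 1-node and
  2-node rules, the nodes are re-centred once at the current trajectory
  estimates before the final 3-node stage.

Optimization is L-BFGS-B with block-wise parameter scaling (trajectory
coefficients, log variances, log hazard ratios and log heights live on
very different scales) and restarts until the likelihood stops improving;
restarting resets the quasi-Newton memory, which reliably escapes
line-search stalls in the long narrow valley that couples alpha with the
baseline-hazard heights. Standard errors come from central finite
differences of the analytic score (relative step 1e-5). Starting values:
longitudinal block from the LMM fit; gamma and alpha jointly from a
two-stage Cox fit in which the empirical-Bayes fitted trajectory values
enter as a carried-forward time-dependent covariate (slightly shrunken but
far better than starting the association at zero); log heights from
occurrence/exposure rates.

**Cumulative hazards.** Within each baseline-hazard interval the
integrand exp(alpha m(s)) is the exponential of a cubic spline, integrated
with a fixed 7-node Gauss-Legendre rule. Intervals are split at the basis
boundary (where the trajectory is clamped to a constant and has a kink);
the standalone integrator additionally splits at the interior spline knots
(where the curve is only C2), giving agreement with dense Simpson
integration to better than 1e-8. Below the first record age (3 months) the
trajectory is extended as a constant at its boundary value, consistently
in the generator and all fitters.

**JLCMM estimation.** EM with closed-form M-steps — posterior class
probabilities; class-probability update; weighted GLS for class-specific
fixed effects; posterior-moment updates for the shared variance
components; occurrence/exposure updates for the class hazards with a
Newton step for gamma — from a k-means start on per-subject mean intake in
three age bands plus random starts (10 by default, short runs triaged by
likelihood), followed by quasi-Newton polishing with the analytic mixture
score. Classes are relabelled to descending size for deterministic
reporting. BIC again uses the subject count. The proportional-hazards
variant reparameterizes the non-reference class heights as a shared shape
times one ratio per class.

**Piecewise hazard ratios.** The log ratio of class heights per interval
is linear in the parameters, so the delta method is exact given the
observed-information covariance (computed by finite differences of the
analytic score). The full mixture covariance is used, not a
modal-assignment refit: posterior class uncertainty then propagates into
the intervals. When a class has essentially no posterior events in an
interval its height sits on the zero boundary; the ratio is then
unidentified and is reported with an infinite standard error rather than a
spuriously tight Wald interval — sparse-interval ratios are exactly where
naive standard errors mislead.

**Sensitivity machinery.** The delete-5 jackknife uses random 5-subject
deletions (200 by default; complete enumeration is astronomically large)
with the delete-d variance scaling (n-d)/d. Interval-censored times can be
multiply imputed from a piecewise-exponential fit conditioned to each
(L, R] interval — estimated from the midpoint data, refined once on a
completed draw — and pooled by Rubin's rules; this is a deliberately
simple, clearly labelled stand-in for a full interval-censoring MI
chain, as is the day-level normal completion used for partially observed
3-day records. Baseline-hazard knot robustness refits with one knot
removed or added, new knots at event-time quantiles so intervals hold
equal event counts.

## The synthetic cohort generator

The generator emulates the design of a Finnish birth-cohort nutrition
study and is the package's test bed; its defaults are fixed study
conditions, not tuning knobs.

- **Schedule.** Food records at 0.25, 0.5, 1, 2, 3, 4 and 6 years (an
  optional 5-year record with probability 0.3; per-occasion attendance
  0.85, approximating the observed median of about 5 records per child),
  three daily values per occasion. Antibody visits every 3 months to age
  2, every 6 months to age 6, then yearly to 15.
- **Baseline covariates.** 53.2% boys, 19.6% high genetic risk, 5.9%
  familial diabetes with 3.9% missing — the reference cohort's margins —
  with log hazard ratios log(0.72) (girl), log(1.95) (high risk),
  log(2.13) (familial), log(0.30) (missing).
- **Dropout.** Independent exponential with rate 0.075/year, truncated to
  the visit grid, matching the reference retention profile (92/84/68/33%
  at 1/2/6/15 years). Independence is an assumption; the study reports
  only marginal retention.
- **Single-population truth ("meat-like").** Mean intake rises from 0
  g/day at 3 months (the curve is pinned at zero there) to ~75 g/day at 6
  years; random-effect scales give a smooth-trajectory SD of 15-20 g/day
  at preschool ages (a 25-30% CV); daily residual SD 20 g/day, so
  within-person noise is on the order of the between-person signal — the
  regime in which the step-function Cox model attenuates. alpha =
  log(1.06)/10; baseline-hazard heights (0.0075, 0.0065, 0.0052)/year
  give a detected 6-year incidence near 4.4%.
- **Two-class truth ("fish-like").** Low consumers (5/6 of the cohort)
  plateau at ~5 g/day from age 1; high consumers (1/6) climb to ~25 g/day
  at 6 years (about 5 residual SDs apart at age 6); class-2 baseline
  hazard is 0.68 times class 1 in every interval; heights give ~6.3%
  cumulative incidence by 15 years.
- **Event times** are drawn by inverting the subject-specific cumulative
  hazard — trapezoidal accumulation on a 2001-point grid with monotone
  interpolation — sharing the random effects with the trajectory;
  interval censoring then comes from the attended visit grid, midpoints
  from the bracketing visits. Records after the detection visit are
  dropped.
- **Negative intakes.** Gaussian noise can produce small negative daily
  values; the generator is model-faithful by default and leaves them in
  place (the fitted models assume exactly this), with an optional
  floor-at-zero switch for realism experiments — off by default because
  flooring breaks exact parameter recovery.

What the generator does *not* emulate: zero-inflation and skewness of real
intake data, seasonally varying diets, informative dropout, assay-level
misclassification of the endpoint, or the food-composition calculation
chain behind the records. Passing recovery tests therefore shows the
estimators are correct under their own assumptions at realistic size and
censoring — not that those assumptions hold in any real cohort.

## Problem sizes used by the test suite

Validation experiments run at reduced study scale, chosen to keep the
full suite in the tens of minutes on one core while leaving the
acceptance bands meaningful: association recovery with 16 cohorts of
2000 children (true HR 1.06 per 10 g; the mean estimate must fall in
[1.03, 1.09]); two-class recovery at n = 2000 (modal accuracy at least
95%); 20-cohort coverage of the proportional class hazard ratio 0.68 at
n = 800 (at least 18 of 20 nominal-95% intervals must cover);
attenuation over 16 paired CRM/JM fits at n = 500; Wald calibration over
400 null Cox replicates at n = 250 and 200 null proportionality
replicates at n = 350 (empirical levels within [0.03, 0.07]).
Oracle-equivalence checks (de Boor recursion, exhaustive risk-set
products, exact-test enumeration, brute-force 1-D integration) run at
toy sizes. A caveat the calibration experiment itself exposes: with only
a handful of events in the smaller latent class, the Wald test of the
class-hazard proportionality ratio is not well approximated by its
asymptotics — replicates whose ratio collapses onto the zero boundary
are reported as unidentified rather than as rejections, and among the
identified replicates the estimate and its standard error are strongly
positively correlated, which deflates the nominal level. At full
reference-cohort scale this smallness effect fades, but it is a genuine
property of the statistic at desk scale, not an implementation artifact.

## Known limitations

- The current-value association is the only one implemented (no slope,
  cumulative or lagged structures).
- Random-effect covariances are diagonal, and shared across latent
  classes (class-specific fixed effects only); both match the estimating
  conventions this package follows, and the sharing is exposed as the
  model's definition rather than a switch.
- The Wald machinery for piecewise class-hazard ratios is honest about
  boundary intervals but offers no profile-likelihood or bootstrap
  alternative in-package; at reference-study event counts the sparse
  intervals genuinely carry very little information.
- No more than 4 latent classes are entertained by default, and
  covariate-dependent class membership is deliberately not implemented.
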