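---
title: "Critical-speed models, weighted fitting, and what the synthetic cohorts do and do not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical-speed models, weighted fitting, and what the synthetic cohorts do and do not show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critspeed)
```

## The problem

Critical speed (CS) is the asymptote of the speed–duration relationship: the
fastest running speed that is, in the model's idealisation, sustainable
indefinitely. It marks the boundary between the heavy and severe
exercise-intensity domains, which is why coaches and physiologists want it
estimated accurately from a small number of exhaustive constant-speed trials
(typically four, at 90–120% of incremental-test peak speed). The companion
parameter *d′* is the finite distance a runner can cover above CS before
exhaustion, and the three-parameter families add *s*~max~, the maximal
instantaneous running speed.

`critspeed` fits three model families, each in two mathematically
equivalent formulations, and quantifies how much the *choice of model* (as
opposed to the choice of fitting procedure) moves the estimates.

## The models

With *t* time to exhaustion (s), *s* running speed (m/s), and *d* = *st*
distance (m):

* **Two-parameter hyperbola**: $t(s) = d'/(s - CS)$. Time diverges as
  *s* approaches CS from above and is finite for any faster speed — the
  model allows unbounded speed for vanishing durations, its main criticism.
* **Three-parameter**: $t(s) = d'(s_{max} - s)\,/\,[(s - CS)(s_{max} - CS)]$.
  The extra parameter caps speed at $s_{max}$, where predicted time is
  exactly zero, and implies *d′* is only partly expendable at speeds below
  $s_{max}$.
* **Three-parameter exponential**:
  $t(s) = \tau \log\!\big((s_{max} - CS)/(s - CS)\big)$ (natural log, as the
  inverse-exponential derivation requires). Here *d′* is not a parameter;
  the distance runnable above CS is time-dependent,
  $d'(t) = t(s_{max} - CS)e^{-t/\tau}$, maximal at $t = \tau$ with closed
  form $d'_{max} = \tau(s_{max} - CS)/e$. Whenever models are compared on
  *d′*, the package reports $d'_{max}$ for this family and exposes the
  transient $d'(t)$ separately (`dprime_transient()`).

Each family is fitted either with time as the dependent variable
(`time_of_speed`, *t(s)*) or distance (`distance_of_speed`, *d(s) = s·t(s)*).
These are the only statistically defensible choices for this design: speed
is set by the experimenter and carries no error, while the *d(t)* and
*t(d)* variants would regress one error-carrying variable on another whose
errors are perfectly correlated with its own (distance = speed × time), an
endogenous setup no regression method resolves. They are deliberately not
implemented.

## Weighting and estimation

Time to exhaustion is heteroscedastic: longer trials are more variable.
The package adopts the standard assumption that the variance of the
dependent variable is proportional to its value, giving inverse-variance
weights $w_i \propto 1/y_i$ (`observation_weights()`), normalised to sum to
the number of observations so the objective is scale-free. Weights are
computed from the *observed* dependent values by default — reproducible and
faithful to the stated rule — with an iteratively-reweighted variant
(`weight_source = "iterative_fitted"`) and an unweighted variant
(`"none"`) available.

Minimisation uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`). The
box constraints are not cosmetic: CS at or above the slowest trial speed
makes the model undefined at a data point, so CS is constrained below it,
and $s_{max}$ above the fastest trial speed. A solution on a bound is
flagged rather than silently reported. Starting values come from the
ordinary regression of distance on time (exact for noise-free
two-parameter data, since $d = d' + CS\,t$), with $s_{max}$ started at
1.5× (three-parameter) or 1.4× (exponential) the fastest observed speed and
$\tau$ at the time observed at the second-fastest speed. Four-point,
three-parameter fits are fragile, so a failed or bound-hitting default
start triggers up to five ±20%-jittered restarts (seeded, restored-RNG);
the best converged interior solution wins. Convergence tolerances default
to 1e-10 (step and gradient) with 500 iterations.

Standard errors come from the weighted Gauss–Newton covariance
$s^2 (J^T W J)^{-1}$, $s^2 = RSS_w/(n-p)$. With *n* = *p* the estimates are
returned with standard errors marked unavailable; `fit_battery()`
additionally flags any cell with fewer than *p* + 1 observations as
under-determined, since no confidence interval is possible.

## Fit quality

* **Confidence intervals** (`parameter_intervals()`): Student-*t* on the
  asymptotic SEs, df = *n* − *p*, at the conventional 90% level.
  Back-computing the SE from a published two-parameter CS interval
  (0.10/2.92 ≈ 0.034 on CS 4.39, i.e. 0.78%) reproduces the corresponding
  published per-parameter SEE to rounding, which corroborates this
  convention.
* **Combined %SEE** (`combined_percent_see()`): the sum of per-parameter
  SEs as percentages of their estimates. For the exponential family the
  fitted parameters (CS, τ, *s*~max~) are summed; a delta-method variant
  substitutes the derived $d'_{max}$ term for τ
  (`dprime_max_variant = TRUE`) for comparability with families fitting
  *d′* directly.
* **AIC** (`fit_aic()`): $n\log(RSS_w/n) + 2p$. The residual units differ
  between formulations (seconds vs metres), so AIC is comparable across
  families only *within* one formulation — the package documents and tests
  this, and does not offer cross-formulation comparisons. A perfect fit
  (zero RSS) returns `NA` rather than −∞. No small-sample correction is
  applied; the within-formulation differences the package asserts are
  unaffected by the additive constant that any such convention shifts.
* **Heteroscedasticity diagnostic** (`residual_heteroscedasticity()`):
  pairs predictions with absolute weighted residuals
  $|\sqrt{w_i}(y_i - \hat y_i)|$ and summarises their association with a
  Spearman rank correlation. A caveat discovered while validating it: with
  only 4–6 observations the hyperbola's steep asymptote gives the
  slowest-speed point near-unit leverage, so its fitted residual is nearly
  zero however noisy the observation — per-fit indices are dominated by
  this geometry, not the noise law. The diagnostic therefore (a) accepts an
  external weight vector so unweighted fits can be examined under the same
  assumed error model, and (b) should be interpreted on profiles pooled
  across participants. On pooled profiles, matching inverse-variance
  weighting moves the index toward zero relative to unweighted fitting;
  against the *true* curve (no fitting step) the weighted index is ~0 and
  the unweighted one clearly positive, confirming the generator's noise
  law and the diagnostic itself.

## Mapping CS onto incremental-test physiology

The default incremental protocol (warm-up 2.78 m/s, +0.28 m/s every 2 min)
implies the line $s = 2.78 + 0.14\,t$ with *t* in minutes — the increment
per minute, with the time unit inferred from the protocol. Peak speed
credits the uncompleted final stage fractionally:
$PS = s_{\dot VO_2max} + \alpha\,\Delta s$, α ∈ [0, 1). A CS estimate maps
to the test time at which that speed occurred and then, through the
participant's V̇O~2~-vs-time regression, to an oxygen-uptake value
(`vo2_at_cs()`); because the mapping is affine in CS, any between-model
pattern in CS reappears identically in V̇O~2~ at CS. Group summaries of
ratio quantities (%V̇O~2~max, %s~V̇O₂max~) are means of per-participant
ratios, not ratios of group means. A CS above the participant's peak speed
is extrapolation beyond the test and is returned flagged.

## Cohort statistics

`mixed_model_effects()` fits, by REML, the random-intercept model
`value ~ family * formulation + (1 | participant)` per outcome. Fixed-effect
p-values use Satterthwaite type-III tests (lmerTest) — the approximation is
an implementation choice, recorded in the result metadata, since several
conventions exist. Variance is decomposed into fixed (variance of the
fixed-effect linear predictor), random-intercept, and residual components,
giving marginal $R^2$ (fixed over total), conditional $R^2$ (fixed + random
over total) and the ICC (random over random + residual); the identities
$R^2_{marginal} \le R^2_{conditional} \le 1$ and ICC ∈ [0, 1] are asserted
on every fit. When the family effect is significant, Holm-adjusted pairwise
family contrasts (estimated marginal means averaged over formulations) are
attached.

`log_scale_association()` computes Pearson correlations after natural-log
transforming both variables, with Fisher-z 90% intervals. The standard
error of estimate in percent is $100(e^{s_{res}} - 1)$ from the residual SD
of the log–log regression. The systematic difference Δ% is defined as the
back-transformed *leave-one-out* mean log prediction error: the in-sample
mean log residual is identically zero, so an out-of-sample definition is
the only non-degenerate reading; it is one consistent interpretation of a
quantity whose published definition is not stated.

Conventional strength labels are pure, boundary-tested functions:
ICC poor/moderate/good/excellent at 0.5/0.75/0.9, correlation
negligible/low/moderate/high/very high at 0.3/0.5/0.7/0.9 (each threshold
belonging to the stronger class).

## The synthetic-cohort generator

`synthetic_config()` encodes the study conditions as defaults: 16
participants; CS ~ N(4.4, 0.4) m/s; *d′* ~ N(225, 55) m; *s*~max~ ~
N(7.5, 0.8) truncated above CS + 1; τ ~ N(250, 50) s truncated positive;
trials at 90/100/110/120% of peak speed. Peak speed is tied to CS through
a ratio draw CS/PS ~ N(0.85, 0.03) truncated to (0.7, 0.95), echoing
CS ≈ 85 %PS in trained runners, with two rejection rules: the slowest trial
speed must exceed CS (otherwise the trial could not be exhaustive), and the
slowest noise-free time may not exceed 40 min (a speed that close to CS is
not a usable severe-domain trial; without this rule the ratio draw's upper
tail produces arbitrarily long trials). Under the defaults the cohort-mean
time at 90 %PS lands near 15 min and at 120 %PS near 1.7 min, matching
published group behaviour.

Noise is multiplicative lognormal, keeping times positive at any scale.
The default law (`variance_prop_t`) gives each time a factor with mean 1
and variance $\sigma^2/t$, so the observed-time variance is proportional
to *t* — exactly the law the inverse-variance weights assume. The scale
default 1.5 (in $\sqrt{s}$ units of effect: CV ≈ 5% on a 900 s trial, 15%
on a 100 s trial) was chosen once as realistic time-to-exhaustion
variability; it yields combined %SEE near 10% and empirical 90% CI
coverage of 0.90 ± 0.02 for the generating family. A fixed-CV law and a
noise-free mode are available. V̇O~2~max is drawn *conditionally on CS*
(marginal correlation ≈ 0.9), with VT and RCP as noisy fractions of it
(74.8% and 89.3% on average), because CS expresses aerobic capacity and
the correlation analyses are only meaningful on cohorts where that
coupling exists.

What the generator does **not** emulate: day-to-day within-participant
variability, pacing or motivation effects, V̇O~2~ kinetics, or any
dependence of *d′* on training status. Passing recovery tests on these
cohorts therefore demonstrates that the estimation machinery is unbiased
and correctly calibrated *under the model's own assumptions* — it does not
validate the physiological models against real runners.

`recovery_experiment()` closes the loop: repeated cohorts, full six-cell
battery per participant, bias/RMSE/CI-coverage scored against the retained
truth, flagged fits excluded and counted.

## Numerical conventions and degenerate inputs

* Speeds at or below CS raise immediately (time undefined/infinite);
  speed exactly $s_{max}$ returns time 0 (a well-defined model value);
  evaluation just above CS is left to caller tolerance — no silent clipping.
* Zero-variance, non-positive, or duplicated-speed trial data are rejected
  at container construction.
* All internal units are SI (s, m/s, m); minute-valued and
  percent-of-peak-speed CSV dialects are converted at the I/O boundary.
* Report CSVs round at serialisation only: speeds 0.01, distances 0.1,
  percents 0.1.
* Problem sizes in the shipped tests: 512 scored fits for coverage, 200
  replicates for mixed-model detection rates, 300 participants pooled for
  the residual diagnostic — sizes at which the asserted brackets are
  stable across seeds.

## Known limitations

* Three-parameter fits on four points have df = 1: intervals are wide and
  occasionally a fit lands on a bound and is excluded; this is inherent to
  the design, and mirrors the published pattern of much larger CIs for the
  three-parameter families.
* The AIC constant is convention-dependent (weight normalisation shifts
  it); only within-formulation comparisons are meaningful here.
* Group-mean refits are a convenient fixture but a fit to group means is
  not the mean of individual fits; individual-level published tables can
  be bracketed, not reproduced.
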