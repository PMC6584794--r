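---
title: "Modelling e-cigarette emissions and per-session yield from puff topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling e-cigarette emissions and per-session yield from puff topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffyield)
```

## The problem

How much aerosol mass — and how much nicotine — does an electronic
cigarette actually deliver to a user's mouth?  The answer depends jointly
on the product (device air path, coil, e-liquid) and on the user's puffing
*topography*: the flow rate, duration, volume and spacing of each puff.
Machine-smoking standards puff at one fixed regime; real users do not, and
for devices whose emissions depend on flow rate the fixed-regime yield can
be a poor estimate of what any individual receives.

`puffyield` implements an empirical separation of those two influences.
The cumulative yield of an aerosol constituent over a use session is

$$Y_{AC} = \int_{t_0}^{t_1} f_{AC}(t)\, C_{TPM}(t)\, \dot v(t)\, dt,$$

where $C_{TPM}$ is the total-particulate-matter concentration of the drawn
aerosol (mg/mL), $f_{AC}$ is the constituent's mass ratio to TPM (mg/mg),
and $\dot v$ is the volumetric flow rate at the mouth (mL/s).  With both
emissions functions characterised per puff, the integral discretises to a
sum over the $N$ puffs of a session:

$$\hat Y_{TPM} = \sum_{n=1}^{N} \hat C_{TPM}(q_n, d_n)\, v_n,
\qquad
\hat Y_{NIC} = \sum_{n=1}^{N} \hat f_{NIC}(q_n)\, \hat C_{TPM}(q_n, d_n)\, v_n,$$

with $q_n$ the puff's mean flow rate, $d_n$ its duration and
$v_n = q_n d_n$ its volume.

## The two emissions models

**TPM concentration** is modelled as a log-quadratic surface in flow rate
and duration,

$$\ln \hat C_{TPM} = b_1 + b_2 \ln q + b_3 d + b_4 (\ln q)^2
  + b_5 \ln(d/1000) + b_6\, q d,$$

fitted by ordinary least squares to machine-puffed trials, each of which
contributes one observed concentration (pad mass over cumulative trial
volume) at its observed $(q, d)$.  Two numerical points deserve note:

* The $\ln(d/1000)$ term is implemented literally — duration in seconds
  divided by 1000 — although it differs from $\ln d$ only by a constant.
  It is a pure reparameterization (the package tests this identity
  explicitly), but the packaged reference intercept $b_1$ is only
  meaningful under this convention, so the literal form is kept.
* The basis $\{\ln q, (\ln q)^2, qd\}$ is strongly correlated, so the OLS
  solve goes through QR factorisation (base R's `lm.fit`); the naive
  normal-equations solve appears only as an independent oracle in the test
  suite.

**Nicotine mass ratio** is modelled as a line in flow rate,
$\hat f_{NIC} = \beta_1 + \beta_2 q$, fitted to the subset of trials whose
filter pads received constituent analysis.  For the packaged reference
device the fitted slope is statistically indistinguishable from zero:
nicotine shares the particulate matter's flow dependence rather than
adding its own, and the mass ratio sits near 0.0098 mg/mg — below the
0.0140 mg/mg nicotine fraction of the un-puffed e-liquid, as it must be
(a property test covers $q \in [0, 100]$ mL/s).

Both fits report per-coefficient standard errors, $t$ statistics
($t = \hat\theta / \mathrm{se}$, two-sided $p$ from the $t$ distribution
on $n - p$ degrees of freedom), $R^2$, adjusted $R^2$ and RMSE.  For the
TPM model the primary RMSE is on the regression's response scale
($\ln$ mg/mL); a back-transformed residual RMSE on the mg/mL scale is
reported alongside, because published diagnostics for this model family
carry natural-scale units and the two are not interchangeable.

## Topography processing

Flow traces are read from CSV (`time_s,flow_ml_s`, `#` comment lines),
with negative flows clipped to zero and counted.  Puff detection is a
thresholding rule: a puff is a maximal run of samples at or above the
threshold; runs separated by sub-threshold gaps shorter than `min_gap`
are merged; merged runs shorter than `min_duration` are dropped.  Defaults
are threshold 1 mL/s, `min_duration` 0.1 s, `min_gap` 0.3 s — there is no
published standard for this rule, so the defaults are deliberately
permissive and every CLI run logs the values used.

Per-puff volume is the trapezoidal integral of flow over the puff window
(dense sampling makes the order-2 rule ample), and the puff's flow rate is
the *volume-weighted* mean $q = v/d$, not the arithmetic mean of samples.
That choice makes $v = qd$ an identity, so the per-puff yield sum conserves
volume exactly and the trace path (`integrate_yield_trace()`) and the
session path (`predict_session_yield()`) agree up to sampling resolution.

Predictions at $(q, d)$ outside the fitted design's ranges are evaluated
but flagged per puff as extrapolations; silent extrapolation outside the
characterised envelope would be unsafe, and the model surface is
empirical, not mechanistic.

## The synthetic-data generator

No raw emissions or playback measurements are published for this model
family, so the package generates every input it needs:

* **Design grid** (`generate_design()`): 34 flow conditions — 10
  "screening" conditions in which $q$ and $d$ vary inversely at nominally
  constant puff volume, plus 24 conditions tiling the $(q, d)$ ranges on a
  log-spaced grid — each replicated 6 times for 204 trials.  Puff counts
  are set so each trial's cumulative volume is as close to 740 mL as an
  integer count allows, inside a 522–1000 mL window.  Default ranges are
  $q \in [10, 100]$ mL/s and $d \in [1, 5]$ s, an envelope of the
  natural-environment session means in the packaged playback profiles
  ($\bar q$ 16.1–62.6 mL/s, $\bar d$ 1.2–4.4 s).
* **Emissions trials** (`simulate_emissions()`): inverts the models —
  $\ln C$ drawn Normal about the surface with SD `noise_ln_sd` (default
  0.15), mass ratio drawn Normal about the line with SD `noise_f_sd`
  (default 0.0025, the reference fit's residual scale) truncated to (0,1)
  by redraw (inert at $f \approx 0.01$), nicotine assays confined to the
  screening arm by default.  Observed $(q, d)$ get a 2% lognormal jitter
  about the nominal condition, emulating machine flow control reporting
  actual rather than commanded conditions.
* **Sessions** (`simulate_session()`): puff durations and flows drawn from
  lognormals (a positive, right-skewed stand-in — the empirical family of
  natural-environment topography is not settled), rendered as smoothed
  trapezoid pulses (0.1 s rise/fall, plateau set so pulse area equals
  $qd$ exactly) at 100 Hz, with ground truth returned alongside the trace.
  `playback_profiles()` provides seven reference session profiles
  (transcribed from a published summary whose typography runs columns
  together; treat them as fixtures) and `session_spec_from_profile()`
  targets their summary statistics.
* **Observed yields** (`simulate_observed_yields()`): multiplicative
  lognormal measurement error around the predicted yield, default
  `obs_noise_cv` 0.2 — the playback measurement scatter is not published,
  so agreement statistics computed on synthetic data characterise the
  pipeline, not the laboratory.

A single root seed fans out through `substream_seed()` to per-component
streams, so the full pipeline is bit-reproducible yet each stage can be
re-run independently.

### What the generator does and does not emulate

The generator reproduces the *statistical structure* the analysis assumes:
the design geometry, homoscedastic ln-scale concentration noise, a flat
mass-ratio line, independent session heterogeneity.  It does not emulate
device aging, coil-resistance drift, battery depletion, inter-puff vapor
losses, or any respiratory deposition beyond the mouth.  Passing tests
therefore demonstrate that the estimators recover the data-generating
process they assume — not that the functional form is correct for any
particular real device.

One calibration mismatch is worth stating plainly: with the reference
surface and any design spanning natural-environment puffing, the
ln-concentration signal SD exceeds 0.8, so at `noise_ln_sd = 0.15` a refit
$R^2$ lands near 0.99 rather than the ≈0.9 a laboratory fit of this model
family reports.  Matching that $R^2$ would require either several-fold
larger noise or an implausibly narrow design.  The suite therefore checks
the refit $R^2$ against the variance-decomposition identity
$R^2 \approx V_s/(V_s + \sigma^2)$ computed from the generated design,
rather than against any published value.

## Validation statistics

`compare_yields()` reports agreement between predicted and observed yields
over repeated playback trials.  Because "the slope" of such a comparison
is ambiguous, both are computed: the through-origin slope
$m = \sum \hat y y / \sum \hat y^2$ is the headline (agreement is judged
against the ideal 1:1 line, so a no-intercept slope is the natural
summary), with the interceptful OLS slope and intercept alongside.
`r_squared` is the squared Pearson correlation (the $R^2$ of the OLS line
with intercept); `r_squared_identity` is the coefficient of determination
about the 1:1 line itself, which can be negative for biased predictions —
published values of "$R^2$" in this setting do not always distinguish the
two, so both are available and neither is asserted against the other.
`run_validation()` computes each session's prediction once and pairs it
with every observed replicate (7 sessions × 6 replicates = 42 pairs in
the default playback layout).

## Problem sizes and runtime choices

The test suite and the acceptance script run the full design (204 trials)
and complete in seconds; Monte-Carlo parameter-recovery summaries use 200
replicates, enough to put the Monte-Carlo standard error of the mean
recovered coefficient an order of magnitude below the coefficient's own
standard error.  Session renderings use 100 Hz sampling and 2–40 puffs per
session, matching the playback profiles' implied puff counts.

## Known limitations

* The reference coefficients are specific to one pen-style device and one
  e-liquid; the functional form travels, the numbers do not, and the
  package flags (rather than refuses) extrapolation beyond the fitted
  envelope.
* The nicotine model is the only constituent instantiated; the yield
  machinery is generic in the mass-ratio model, but no other constituent
  models ship.
* OLS assumes homoscedastic ln-scale errors; no weighted fit is provided.
* Puff detection is threshold-based and deterministic; noisy low-flow
  traces near the threshold will be sensitive to the chosen threshold.
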