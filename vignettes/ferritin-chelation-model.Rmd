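---
title: "Modelling serum-ferritin dynamics under deferoxamine chelation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serum-ferritin dynamics under deferoxamine chelation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferridyn)
```

## The problem

Patients with beta-thalassaemia major survive on chronic red-blood-cell
transfusions, and every transfusion adds iron the body cannot excrete. Serum
ferritin (ug/L) is the routine biomarker of the resulting iron burden;
keeping it below about 2500 ug/L separates moderate from severe overload and
is a standard therapeutic goal. Deferoxamine, given as an 8-h subcutaneous
infusion on 5 of 7 nights, chelates the excess iron, but the burdensome
administration makes imperfect adherence the norm. `ferridyn` implements a
drug-disease model of this system: it simulates ferritin trajectories under
arbitrary dosing and adherence patterns, estimates the drug effect from
longitudinal ferritin data by nonlinear mixed-effects, and runs the
decision-support question clinicians actually ask — *how long until this
patient reaches 2500 ug/L, and what does missing doses cost?*

## The model

Ferritin follows a turnover (indirect-response) equation with a
transfusion-driven production term and a drug effect on elimination:

$$\frac{dF}{dt} = K_{in} + CRT(F) - K_{out}\,F\,(1 + SLP \cdot C_{ss}^{av}),
\qquad CRT(F) = SCL_i\, e^{-SHP_i F}.$$

* $K_{in}$ (2e-4 ug/L/h) and $K_{out}$ (4.5e-6 1/h) are the basal ferritin
  turnover; alone they give a negligible baseline $K_{in}/K_{out} \approx
  44$ ug/L — in these patients ferritin is dominated by the transfusion
  term.
* $CRT$ is the conversion of transfused iron into circulating ferritin:
  largest at low ferritin and exponentially damped as stores saturate
  ($SCL$ = 0.383 ug/L/h, $SHP$ = 2.6e-4 L/ug at the population median).
* Disease-status scaling: $SCL_i$ and $SHP_i$ are power functions of
  ferritin relative to the population median (2260 ug/L), with exponents
  0.845 and 1.29. By default the *current* (state-dependent) ferritin enters
  these power laws; a variant frozen at a reference level is available via
  `statusFerritin` because the published description admits both readings.
  The choice matters: the untreated steady state is ~4.9e3 ug/L
  state-dependent and ~8.8e3 ug/L when the scaling is frozen at the median.
* The drug effect is linear in exposure, $DFO = SLP \cdot C_{ss}^{av}$ with
  $SLP$ = 4.81 per mg/L, multiplying $K_{out}$.

Exposure is the weekly average steady-state concentration of a
two-compartment infusion model (adult CL 19.3 L/h, Q 17.6 L/h, V1 77.4 L,
V2 238 L) with fixed allometric scaling (0.75 on clearances, 1.0 on
volumes; reference weight 70 kg — the literature profile behind the PK
parameters is adult, and 70 kg is the conventional adult reference). For a
45-kg patient on 45 mg/kg/day, 5 days/week:

```{r}
cssAverage(pkParameters(), infusionRegimen(45, 45))
```

The 168-h window smooths the 5-on/2-off schedule into one number; the 24-h
`per = "dosing-day"` variant (6.09 mg/L here) is what the calendar engine
assigns to days with a taken dose. Because the drug effect is linear in
concentration and ferritin moves on a time scale of months, sub-day PK shape
is irrelevant — only the daily average matters.

## Adherence

Two observable patterns are generated on a dosing calendar of 50 dosing
weeks per year (5 doses/week = exactly 250 scheduled doses/year, the
arithmetic used throughout):

* **poor execution** — single doses missed uniformly at random
  (`applyRandomMissing`), exactly `round(fraction * 250)` per year;
* **drug holidays** — consecutive missed doses at the start of each
  stratification block (`applyDrugHolidays`). Blocks are 50 / 25 / 10 / 5
  dosing weeks ("1 year", "6 months", "2 months", "1 month"), i.e.
  250 / 125 / 50 / 25 scheduled doses; these block sizes reproduce the
  published missed-dose grid exactly (the labels imply a 25-dose "month",
  one tenth of the dosing year).

For estimation, where no dosing diary exists, adherence enters through the
observational proxy CMPL — the fraction of a patient's ferritin observations
above 2500 ug/L — which scales exposure as $TC_{ss} = C_{ss}(1 -
\mathrm{CMPL})$.

## Estimation

`fitPopulation()` maximises a Laplace-approximate marginal likelihood.
Random effects are log-normal: $\eta$ per subject on the slope and a
per-occasion effect $\kappa$ multiplying $CRT$ (occasions are consecutive
1-year windows; the window length is configurable since the original
analysis never defines it). Residuals are proportional, $Y = F(1 +
\varepsilon)$, reported as a magnitude because the source tool's sign is
arbitrary. Per subject the inner mode over $(\eta, \kappa_1..\kappa_K)$ is
found by BFGS (warm-started across outer iterations) and the curvature at
the mode is the Gauss-Newton expansion $J^T \Sigma^{-1} J + D^{-1}$ — the
standard first-order practice of conditional-estimation pharmacometric
software; the test suite verifies the approximation against adaptive
quadrature in one dimension (agreement to 1e-4 at small variance, where
Laplace is asymptotically exact). The outer optimiser is Nelder-Mead on
log-transformed parameters (the warm-started inner modes make the objective
very slightly history-dependent, which derivative-based outer optimisers
misread as noise), with up to three deterministic starts. By default the
disease turnover constants, the status exponents and the IOV variance stay
fixed and (slope, IIV variance, residual SD) are estimated — mirroring an
analysis in which the disease submodel was characterised beforehand.
`bootstrapFit()` resamples subjects with replacement; `visualPredictiveCheck()`
compares observed percentile bands with simulation bands at the design
points. The first observation of each subject serves as the initial
condition and is excluded from the likelihood.

## The synthetic cohort

No patient data ship with the package; `simulateCohort()` emulates the study
population so every pipeline stage is testable: 27 patients, age 6.8–19.9 y,
weight log-normal around a 46-kg median truncated to 17.5–71 kg, baseline
ferritin log-normal around 2260 ug/L truncated to 393–8500 (the published
summaries give medians and ranges but no distributional form; log-normal is
the conventional choice for both), ferritin sampled every 60–90 days for up
to 10 years, 40 mg/kg on 5 days/week. A latent per-patient non-adherence
fraction ~ Beta(0.45, 1) (median 0.21, mean 0.31, matching the reported
adherence-proxy location) scales exposure; the dataset's CMPL column is then
*recomputed* from the simulated observations, so proxy and latent trait
agree only as far as the model makes them — a tested property (Spearman
correlation > 0.5), deliberately not an identity. Per-subject observation
counts come from a truncated-normal parent (mean 41.5, SD 19, range 10–58)
calibrated once so that the cohort grand mean is the reported 40.2
observations/patient; under the hard 10-year cap and the 60–90-day gaps the
attainable count SD is ~14, short of the reported 17 — the cap binds, and we
prefer honouring the cap and the gap distribution over the dispersion. The
60–90-day gap bound automatically guarantees the reported minimum of 4
samples per covered year. Age is sampled for realism but unused (weight
drives allometry).

What the generator does *not* emulate: dose adjustments over time,
transfusion-event logs, assay floors/ceilings, dropout correlated with
severity. Passing tests therefore demonstrate internal consistency of the
method under the stated design, not performance on real clinical data.

## Numerical choices

* Default trajectory engine: deSolve's implicit BDF with integrator restarts
  at every exposure breakpoint (rtol 1e-8, atol 1e-6 ug/L). The system is
  only mildly stiff (elimination time constants of months even under drug),
  so the scenario grids, estimation and cohort simulation use a compiled
  adaptive Cash–Karp RK45 with the same interface; the two engines agree to
  <1e-5 relative in the tests and the linear-limit closed form to <1e-6.
  Estimation uses coarser tolerances (rtol 1e-6).
* Ferritin is floored at 1e-6 ug/L inside the power laws so 0^negative
  cannot occur; steady states are bracketed on [1e-3, 1e6] and polished to a
  rate residual below 1e-10.
* Threshold crossings are located on a daily output grid by sign change plus
  linear interpolation, reported in years (8760 h) to 3 decimals, censored
  at 5 years.
* Missed-dose counts round half away from zero, reproducing the printed
  integer grid exactly; random-pattern cells in the scenario grid average
  over 20 seeds by default (the original count of random draws is unstated).
* Inner random effects are barred beyond |b| = 6 (an e^6-fold parameter
  change, > 8 prior SDs for every variance in play) to keep the ODE
  integrable when the optimiser's line search overshoots.

## Exposure scale and what the package reproduces

The published analysis prints the disposition parameters and the dosing
regimens but not the exposure values driving its figures. The weekly-average
convention adopted here (4.35 mg/L for the 45-kg reference patient) is the
natural reading, but tracing the published 60%-missed effectiveness boundary
backwards implies a full-adherence exposure near 8.7 mg/L — about twice the
weekly average. Three consequences, all visible in the test suite and all
sharing this single root cause:

* the effectiveness boundary computed here falls at 10–30% missed doses
  rather than 60% (still *within* the published bound, which is how it is
  checked);
* with treated steady states sitting near 2500 ug/L, the simulated CMPL
  proxy saturates high (its median exceeds 0.5 versus the reported 0.21), so
  fits that use the recomputed proxy overestimate the slope by roughly a
  factor of two — substituting the latent trait recovers the generating
  slope to within 15% and the residual SD to within 10% on the study-sized
  cohort (both asserted in the test suite), which isolates the bias to the
  proxy's miscalibration, not the estimator;
* the adherence-pattern orderings reverse: at this exposure scale a
  start-of-block holiday is *faster* to the threshold than random misses,
  because the effect multiplies $K_{out} F$ — chelation removes more
  ferritin per hour at elevated levels, so concentrating the misses early
  lets every subsequent dose act on elevated ferritin, and the crossing
  happens during a clean stretch. At roughly double the exposure the initial
  holiday delay dominates instead and the published orderings re-emerge.
  The residual-error recovery and the design statistics are insensitive to
  the exposure scale and reproduce well.

## Problem sizes

The shipped checks use the study-sized design throughout: the
adherence grid runs 9 missed-dose deciles x (20 random seeds + 4 holiday
stratifications) at baseline 3000 ug/L; recovery fits 10 replicate
27-subject cohorts (single start, initialised at the configured defaults);
design calibration uses 50 replicate cohorts; VPC self-calibration uses 150
simulation replicates. On one CPU the whole suite runs in roughly ten
minutes, dominated by the replicate fits.

## Known limitations

* Transfusions are lumped into the continuous $CRT$ term; there are no
  discrete transfusion events and no organ-level (cardiac/liver) iron
  compartments.
* The adherence proxy conflates "ferritin above threshold" with
  non-adherence by construction; any disease-driven elevation inflates it.
* The Laplace/Gauss-Newton objective is an approximation; its error grows
  with the random-effect variances (quantified against quadrature only in
  one dimension).
* Occasions are calendar-year windows, not visit-defined periods.
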