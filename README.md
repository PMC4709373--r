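# ferridyn

Drug–disease modelling of transfusional iron overload under deferoxamine
chelation, for pharmacometricians and clinical-pharmacology modellers working
with beta-thalassaemia major and related transfusion-dependent
haemoglobinopathies.

Chronically transfused patients accumulate iron; serum ferritin (ug/L)
tracks the burden, and holding it below 2500 ug/L is a standard therapeutic
goal. `ferridyn` implements a serum-ferritin turnover model with
transfusion-driven production and a proportional chelator effect on
elimination,

    dF/dt = Kin + CRT(F) − Kout · F · (1 + SLP · Css_av)
    CRT(F) = SCL_i · exp(−SHP_i · F)

where the conversion-rate scale and shape (`SCL_i`, `SHP_i`) are power
functions of ferritin relative to the population median (disease-status
scaling), and exposure `Css_av` is the weekly average steady-state
concentration of a two-compartment infusion PK model with fixed allometric
scaling (exponent 0.75 on clearances, 1.0 on volumes). Imperfect adherence
enters two ways: forward simulations miss doses on an explicit dosing
calendar (single doses at random, or consecutive "drug holidays" per
stratification block), while estimation scales exposure by the observational
proxy CMPL (fraction of a patient's ferritin observations above 2500 ug/L)
as `TCss = Css · (1 − CMPL)`.

The package provides:

* `simulateFerritin()`, `steadyStateFerritin()` — trajectory and equilibrium
  under piecewise-constant exposure (deSolve BDF by default, compiled RK45
  for the high-volume paths);
* `buildCalendar()`, `applyRandomMissing()`, `applyDrugHolidays()`,
  `exposureFromCalendar()` — dosing calendars and adherence patterns
  (250 scheduled doses per 50-week dosing year at 5 days/week);
* `timeToThreshold()`, `doseGrid()`, `complianceGrid()` — decision-support
  grids of the time to reach 2500 ug/L, censored at 5 years;
* `fitPopulation()`, `bootstrapFit()`, `visualPredictiveCheck()` — Laplace
  nonlinear mixed-effects estimation (log-normal IIV on the slope,
  per-occasion IOV on the conversion rate, proportional residual);
* `simulateCohort()`, `sampleDemographics()`, `sampleDesign()` — a synthetic
  27-patient cohort emulating the study design (weights 17.5–71 kg,
  baselines 393–8500 ug/L, ferritin every 60–90 days for up to 10 years,
  40 mg/kg 5 days/week, latent Beta(0.45, 1) non-adherence);
* `readDataset()`, `loadConfig()`, `cliMain()` — NONMEM-style CSV datasets,
  YAML configuration over documented defaults, and a thin command line
  (`inst/cli/ferridyn`) with `simulate | synthesize | fit | scenarios | vpc`.

## Worked example

A 45-kg patient on 45 mg/kg/day, 5 days a week:

```r
library(ferridyn)

css <- cssAverage(pkParameters(), infusionRegimen(45, 45))
css
#> Css(av) = 4.35 mg/L over a 168-h window

exposure <- cssAv(css)
steadyStateFerritin(diseaseParameters(), drugEffectParameters(), exposure)
#> [1] 2190.291

tt <- timeToThreshold(3000, exposure, checkBaseline = FALSE)
round(as.numeric(tt), 2)
#> [1] 0.68
```

Fully adherent, this patient's ferritin equilibrates near 2190 ug/L and
falls from a 3000 ug/L baseline to the 2500 ug/L threshold in about 0.68
years. Missing doses stretches that out and eventually defeats the therapy:

```r
grid <- complianceGrid(fractions = c(0.2, 0.4), baselines = 3000, nSeeds = 5)
grid[, c("pattern", "stratification", "fraction_missed", "time_years", "censored")]
#>        pattern stratification fraction_missed time_years censored
#> 1       random         1 year             0.2      2.185    FALSE
#> 2  consecutive         1 year             0.2      1.659    FALSE
#> 3  consecutive       6 months             0.2      1.830    FALSE
#> 4  consecutive       2 months             0.2      2.099    FALSE
#> 5  consecutive        1 month             0.2      2.390    FALSE
#> 6       random         1 year             0.4         NA     TRUE
#> 7  consecutive         1 year             0.4         NA     TRUE
#> 8  consecutive       6 months             0.4         NA     TRUE
#> 9  consecutive       2 months             0.4         NA     TRUE
#> 10 consecutive        1 month             0.4         NA     TRUE
```

At 20% missed doses the threshold is still reached within 1.7–2.4 years
depending on the pattern; at 40% missed it is not reached within the 5-year
cap under any pattern (`censored`). The methods vignette
(`vignettes/ferritin-chelation-model.Rmd`) discusses the exposure scale and
why, at these published parameter values, the effectiveness boundary sits
below the published 60% bound and a front-loaded drug holiday can outpace
randomly scattered misses.

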