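#' @useDynLib ferridyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats integrate median optim nlminb optimHess quantile rnorm
#'   runif sd setNames uniroot cor
#' @importFrom utils read.csv write.csv
NULL

# Internal time conventions: hours everywhere; a calendar/reporting year is
# 8760 h; a dosing year is 50 dosing weeks (350 days) so that 5 doses/week
# gives exactly 250 scheduled doses per year.
.HOURS_PER_YEAR <- 8760
.DOSING_WEEKS_PER_YEAR <- 50

#' Two-compartment disposition parameters of deferoxamine
#'
#' Apparent clearance, intercompartmental clearance and the central and
#' peripheral volumes of an adult reference subject, together with the
#' reference body weight used for allometric scaling. Defaults are the
#' literature adult values for deferoxamine given as an 8-h subcutaneous
#' infusion.
#'
#' @slot cl apparent clearance, L/h
#' @slot q intercompartmental clearance, L/h
#' @slot v1 apparent central volume, L
#' @slot v2 apparent peripheral volume, L
#' @slot refWeight body weight the parameters refer to, kg
#' @export
setClass("PKParameters",
  representation(cl = "numeric", q = "numeric", v1 = "numeric",
                 v2 = "numeric", refWeight = "numeric"),
  prototype(cl = 19.3, q = 17.6, v1 = 77.4, v2 = 238.0, refWeight = 70))

setValidity("PKParameters", function(object) {
  v <- c(cl = object@cl, q = object@q, v1 = object@v1, v2 = object@v2,
         refWeight = object@refWeight)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all disposition parameters and refWeight must be finite and > 0")
  TRUE
})

#' @describeIn PKParameters constructor
#' @param cl,q,v1,v2,refWeight see slots
#' @export
pkParameters <- function(cl = 19.3, q = 17.6, v1 = 77.4, v2 = 238.0,
                         refWeight = 70) {
  new("PKParameters", cl = cl, q = q, v1 = v1, v2 = v2,
      refWeight = refWeight)
}

#' Subcutaneous infusion regimen
#'
#' @slot dosePerKg daily dose on dosing days, mg/kg
#' @slot bodyWeight patient body weight, kg
#' @slot infusionDuration length of the infusion, h
#' @slot dosingDaysPerWeek number of consecutive dosing days per week (1-7)
#' @export
setClass("InfusionRegimen",
  representation(dosePerKg = "numeric", bodyWeight = "numeric",
                 infusionDuration = "numeric",
                 dosingDaysPerWeek = "integer"),
  prototype(dosePerKg = 40, bodyWeight = 70, infusionDuration = 8,
            dosingDaysPerWeek = 5L))

setValidity("InfusionRegimen", function(object) {
  if (object@dosePerKg < 0) return("dosePerKg must be >= 0")
  if (object@bodyWeight <= 0) return("bodyWeight must be > 0")
  if (object@infusionDuration <= 0 || object@infusionDuration > 24)
    return("infusionDuration must be in (0, 24] h")
  if (object@dosingDaysPerWeek < 1L || object@dosingDaysPerWeek > 7L)
    return("dosingDaysPerWeek must be in 1..7")
  TRUE
})

#' @describeIn InfusionRegimen constructor
#' @param dosePerKg,bodyWeight,infusionDuration,dosingDaysPerWeek see slots
#' @export
infusionRegimen <- function(dosePerKg, bodyWeight, infusionDuration = 8,
                            dosingDaysPerWeek = 5) {
  new("InfusionRegimen", dosePerKg = dosePerKg, bodyWeight = bodyWeight,
      infusionDuration = infusionDuration,
      dosingDaysPerWeek = as.integer(dosingDaysPerWeek))
}

#' Average steady-state exposure summary
#'
#' @slot cssAv average steady-state concentration, mg/L
#' @slot window averaging window, h
#' @export
setClass("ExposureSummary",
  representation(cssAv = "numeric", window = "numeric"))

setValidity("ExposureSummary", function(object) {
  if (object@cssAv < 0) return("cssAv must be >= 0")
  if (object@window <= 0) return("window must be > 0")
  TRUE
})

#' @rdname cssAv
#' @export
setGeneric("cssAv", function(object) standardGeneric("cssAv"))

#' Extract the average steady-state concentration (mg/L)
#'
#' @param object an \code{ExposureSummary}
#' @export
setMethod("cssAv", "ExposureSummary", function(object) object@cssAv)

#' Piecewise-constant exposure timeline
#'
#' Level \code{levels[i]} applies on \code{[breaks[i], breaks[i+1])} (hours),
#' the last level extending indefinitely.
#'
#' @slot breaks left endpoints, h; strictly increasing, first is 0
#' @slot levels non-negative levels, one per break
#' @export
setClass("ExposureTimeline",
  representation(breaks = "numeric", levels = "numeric"))

setValidity("ExposureTimeline", function(object) {
  b <- object@breaks; l <- object@levels
  if (length(b) != length(l)) return("breaks and levels differ in length")
  if (length(b) < 1L) return("at least one segment required")
  if (b[1] != 0) return("first break must be 0")
  if (length(b) > 1L && any(diff(b) <= 0))
    return("breaks must be strictly increasing")
  if (any(!is.finite(l)) || any(l < 0))
    return("levels must be finite and >= 0")
  TRUE
})

#' @describeIn ExposureTimeline constructor
#' @param levels,breaks see slots
#' @export
exposureTimeline <- function(levels, breaks = 0) {
  new("ExposureTimeline", breaks = as.numeric(breaks),
      levels = as.numeric(levels))
}

#' @describeIn ExposureTimeline evaluate the timeline at times \code{t} (h)
#' @param tl an \code{ExposureTimeline}
#' @param t times, h
#' @export
timelineAt <- function(tl, t) {
  tl@levels[pmax(1L, findInterval(t, tl@breaks))]
}

# Coerce a constant or an ExposureTimeline to a timeline.
.asTimeline <- function(x) {
  if (is(x, "ExposureTimeline")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(exposureTimeline(x))
  stop("exposure must be a single non-negative number or an ExposureTimeline")
}

#' Ferritin turnover (disease) parameters
#'
#' Parameters of the indirect-response model of serum ferritin with
#' transfusion-driven production: zero-order production \code{kin}, first-order
#' elimination \code{kout}, and a conversion-rate term
#' \code{CRT = SCL_i * exp(-SHP_i * F)} whose scale and shape are power
#' functions of the disease status (ferritin relative to the population
#' median). Defaults are the fitted population values with ferritin in ug/L
#' and time in hours.
#'
#' @slot kin production rate, ug/L per h
#' @slot kout elimination rate constant, 1/h
#' @slot sclRef conversion-rate scale at the median ferritin, ug/L per h
#' @slot shpRef conversion-rate shape at the median ferritin, L/ug
#' @slot thetaScl disease-status exponent on the scale
#' @slot thetaShp disease-status exponent on the shape
#' @slot ferritinMed population median ferritin, ug/L
#' @export
setClass("DiseaseParameters",
  representation(kin = "numeric", kout = "numeric", sclRef = "numeric",
                 shpRef = "numeric", thetaScl = "numeric",
                 thetaShp = "numeric", ferritinMed = "numeric"),
  prototype(kin = 2e-4, kout = 4.5e-6, sclRef = 0.383, shpRef = 2.6e-4,
            thetaScl = 0.845, thetaShp = 1.29, ferritinMed = 2260))

setValidity("DiseaseParameters", function(object) {
  if (object@kin < 0) return("kin must be >= 0")
  if (object@kout <= 0) return("kout must be > 0")
  if (object@sclRef < 0) return("sclRef must be >= 0")
  if (object@shpRef < 0) return("shpRef must be >= 0")
  if (object@ferritinMed <= 0) return("ferritinMed must be > 0")
  TRUE
})

#' @describeIn DiseaseParameters constructor
#' @param kin,kout,sclRef,shpRef,thetaScl,thetaShp,ferritinMed see slots
#' @export
diseaseParameters <- function(kin = 2e-4, kout = 4.5e-6, sclRef = 0.383,
                              shpRef = 2.6e-4, thetaScl = 0.845,
                              thetaShp = 1.29, ferritinMed = 2260) {
  new("DiseaseParameters", kin = kin, kout = kout, sclRef = sclRef,
      shpRef = shpRef, thetaScl = thetaScl, thetaShp = thetaShp,
      ferritinMed = ferritinMed)
}

#' Concentration-effect parameters of the chelator
#'
#' The drug effect is linear in exposure: \code{DFO = slope * Css}, acting
#' multiplicatively on the ferritin elimination rate,
#' \code{kout * (1 + DFO)}.
#'
#' @slot slope effect per unit concentration, (mg/L)^-1
#' @export
setClass("DrugEffectParameters",
  representation(slope = "numeric"), prototype(slope = 4.81))

setValidity("DrugEffectParameters", function(object) {
  if (object@slope < 0) return("slope must be >= 0")
  TRUE
})

#' @describeIn DrugEffectParameters constructor
#' @param slope see slots
#' @export
drugEffectParameters <- function(slope = 4.81) {
  new("DrugEffectParameters", slope = slope)
}

#' Dosing calendar
#'
#' Scheduled dose days (calendar day index from treatment start, day 1 is the
#' first treatment day) with taken/missed indicators. The calendar follows a
#' k-consecutive-dosing-days-then-rest weekly pattern over a 50-week dosing
#' year, so 5 days/week gives exactly 250 scheduled doses per year.
#'
#' @slot day scheduled dose days (1-based calendar day index)
#' @slot taken logical, dose taken
#' @slot dosingDaysPerWeek dosing days per week
#' @slot years number of dosing years covered
#' @export
setClass("DosingCalendar",
  representation(day = "integer", taken = "logical",
                 dosingDaysPerWeek = "integer", years = "numeric"))

setValidity("DosingCalendar", function(object) {
  if (length(object@day) != length(object@taken))
    return("day and taken differ in length")
  if (length(object@day) && any(diff(object@day) <= 0))
    return("schedule must be strictly increasing")
  TRUE
})

#' Virtual cohort specification
#'
#' Sampling rules for a synthetic cohort emulating the study population:
#' 27 transfusion-dependent patients aged 6.8-19.9 y, weight 17.5-71 kg
#' (median 46), baseline ferritin 393-8500 ug/L (median 2260), ferritin
#' sampled every 60-90 days for up to 10 years, prevalent dose 40 mg/kg as an
#' 8-h infusion 5 days/week, and a latent per-patient non-adherence trait
#' distributed Beta(0.45, 1).
#'
#' @slot nSubjects number of patients
#' @slot ageRange age range, years
#' @slot weightMedian,weightSdLog,weightRange log-normal weight model, kg
#' @slot baselineMedian,baselineSdLog,baselineRange log-normal baseline
#'   ferritin model, ug/L
#' @slot gapRangeDays sampling-interval range, days
#' @slot maxFollowupYears follow-up cap, years
#' @slot obsParentMean,obsParentSd,obsCountRange truncated-normal parent of
#'   the per-subject observation count (calibrated so the cohort mean matches
#'   the reported 40.2 observations/patient under the follow-up cap)
#' @slot dosePerKg daily dose, mg/kg
#' @slot dosingDaysPerWeek dosing days per week
#' @slot infusionDuration infusion length, h
#' @slot nonadherenceShape Beta shape parameters of the latent
#'   non-adherence trait
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", ageRange = "numeric",
                 weightMedian = "numeric", weightSdLog = "numeric",
                 weightRange = "numeric", baselineMedian = "numeric",
                 baselineSdLog = "numeric", baselineRange = "numeric",
                 gapRangeDays = "numeric", maxFollowupYears = "numeric",
                 obsParentMean = "numeric", obsParentSd = "numeric",
                 obsCountRange = "numeric", dosePerKg = "numeric",
                 dosingDaysPerWeek = "integer",
                 infusionDuration = "numeric",
                 nonadherenceShape = "numeric"),
  prototype(nSubjects = 27L, ageRange = c(6.8, 19.9), weightMedian = 46,
            weightSdLog = 0.3, weightRange = c(17.5, 71),
            baselineMedian = 2260, baselineSdLog = 0.8,
            baselineRange = c(393, 8500), gapRangeDays = c(60, 90),
            maxFollowupYears = 10, obsParentMean = 41.5, obsParentSd = 19,
            obsCountRange = c(10, 58), dosePerKg = 40,
            dosingDaysPerWeek = 5L, infusionDuration = 8,
            nonadherenceShape = c(0.45, 1.0)))

setValidity("CohortSpec", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  if (object@weightRange[1] < 17.5 - 1e-9 || object@weightRange[2] > 71 + 1e-9)
    return("weightRange must lie within 17.5-71 kg")
  if (object@baselineRange[1] < 393 - 1e-9 ||
      object@baselineRange[2] > 8500 + 1e-9)
    return("baselineRange must lie within 393-8500 ug/L")
  if (object@gapRangeDays[1] >= object@gapRangeDays[2])
    return("gapRangeDays must be an increasing pair")
  if (object@maxFollowupYears <= 0) return("maxFollowupYears must be > 0")
  TRUE
})

#' @describeIn CohortSpec constructor; arguments override the study defaults
#' @param ... slot values to override
#' @export
cohortSpec <- function(...) {
  args <- list(...)
  if ("nSubjects" %in% names(args))
    args$nSubjects <- as.integer(args$nSubjects)
  if ("dosingDaysPerWeek" %in% names(args))
    args$dosingDaysPerWeek <- as.integer(args$dosingDaysPerWeek)
  do.call(new, c(list(Class = "CohortSpec"), args))
}

#' Population (mixed-effects) model of the drug-disease system
#'
#' Typical values plus random-effect variances: log-normal inter-individual
#' variability on the slope, log-normal inter-occasion variability on the
#' conversion rate, and a proportional residual error. Exposure within
#' estimation is the compliance-adjusted constant
#' \code{TCss = Css * (1 - CMPL)}.
#'
#' @slot pk \code{PKParameters} used to derive exposure
#' @slot disease \code{DiseaseParameters}
#' @slot slope typical concentration-effect slope, (mg/L)^-1
#' @slot omegaIIV variance of eta on the slope
#' @slot omegaIOV variance of the per-occasion effect on CRT
#' @slot sigma proportional residual SD (magnitude)
#' @slot occasionYears occasion window length, years
#' @slot statusFerritin fixed disease-status reference ferritin (ug/L), or
#'   \code{NA} for state-dependent scaling (default)
#' @export
setClass("PopulationModel",
  representation(pk = "PKParameters", disease = "DiseaseParameters",
                 slope = "numeric", omegaIIV = "numeric",
                 omegaIOV = "numeric", sigma = "numeric",
                 occasionYears = "numeric", statusFerritin = "numeric"),
  prototype(slope = 4.81, omegaIIV = 0.082, omegaIOV = 0.252,
            sigma = 0.173, occasionYears = 1, statusFerritin = NA_real_))

setValidity("PopulationModel", function(object) {
  if (object@omegaIIV < 0 || object@omegaIOV < 0)
    return("random-effect variances must be >= 0")
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@slope < 0) return("slope must be >= 0")
  if (object@occasionYears <= 0) return("occasionYears must be > 0")
  TRUE
})

#' @describeIn PopulationModel constructor
#' @param pk,disease,slope,omegaIIV,omegaIOV,sigma,occasionYears,statusFerritin
#'   see slots
#' @export
populationModel <- function(pk = pkParameters(),
                            disease = diseaseParameters(), slope = 4.81,
                            omegaIIV = 0.082, omegaIOV = 0.252,
                            sigma = 0.173, occasionYears = 1,
                            statusFerritin = NA_real_) {
  new("PopulationModel", pk = pk, disease = disease, slope = slope,
      omegaIIV = omegaIIV, omegaIOV = omegaIOV, sigma = sigma,
      occasionYears = occasionYears, statusFerritin = statusFerritin)
}

#' Population fit result
#'
#' @slot estimates named vector of final parameter values (natural scale)
#' @slot se named vector of asymptotic standard errors (NA for fixed)
#' @slot ofv objective function value (-2 log marginal likelihood, Laplace)
#' @slot estimated names of the estimated parameters
#' @slot ebe empirical-Bayes random effects per subject
#' @slot convergence optimiser convergence code (0 = success)
#' @slot message optimiser message
#' @slot starts per-start objective values
#' @slot model the fitted \code{PopulationModel}
#' @export
setClass("FitResult",
  representation(estimates = "numeric", se = "numeric", ofv = "numeric",
                 estimated = "character", ebe = "list",
                 convergence = "integer", message = "character",
                 starts = "data.frame", model = "PopulationModel"))

#' @rdname FitResult-accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' Accessors for \code{FitResult}
#'
#' @param object a \code{FitResult}
#' @name FitResult-accessors
#' @export
setMethod("estimates", "FitResult", function(object) object@estimates)

#' @rdname FitResult-accessors
#' @export
setGeneric("ofv", function(object) standardGeneric("ofv"))

#' @rdname FitResult-accessors
#' @export
setMethod("ofv", "FitResult", function(object) object@ofv)

#' @rdname FitResult-accessors
#' @export
setGeneric("randomEffects", function(object) standardGeneric("randomEffects"))

#' @rdname FitResult-accessors
#' @export
setMethod("randomEffects", "FitResult", function(object) object@ebe)

setMethod("show", "PKParameters", function(object) {
  cat("Two-compartment PK parameters (reference weight",
      object@refWeight, "kg)\n")
  cat(sprintf("  CL %.3g L/h, Q %.3g L/h, V1 %.3g L, V2 %.3g L\n",
              object@cl, object@q, object@v1, object@v2))
})

setMethod("show", "DiseaseParameters", function(object) {
  cat("Ferritin turnover parameters (time in h, ferritin in ug/L)\n")
  cat(sprintf("  kin %.3g, kout %.3g, SCL %.3g, SHP %.3g\n",
              object@kin, object@kout, object@sclRef, object@shpRef))
  cat(sprintf("  status exponents: SCL %.3g, SHP %.3g; median ferritin %.0f\n",
              object@thetaScl, object@thetaShp, object@ferritinMed))
})

setMethod("show", "ExposureSummary", function(object) {
  cat(sprintf("Css(av) = %.4g mg/L over a %g-h window\n", object@cssAv,
              object@window))
})

setMethod("show", "DosingCalendar", function(object) {
  cat(sprintf(
    "Dosing calendar: %d scheduled doses over %.3g dosing year(s), %d taken\n",
    length(object@day), object@years, sum(object@taken)))
})

setMethod("show", "ExposureTimeline", function(object) {
  cat(sprintf("Exposure timeline with %d segment(s), range %.3g-%.3g mg/L\n",
              length(object@levels), min(object@levels),
              max(object@levels)))
})

setMethod("show", "PopulationModel", function(object) {
  cat("Population drug-disease model\n")
  cat(sprintf("  slope %.4g (mg/L)^-1, omega2(IIV) %.4g, omega2(IOV) %.4g, sigma %.4g\n",
              object@slope, object@omegaIIV, object@omegaIOV, object@sigma))
  cat(sprintf("  occasion window %g year(s), disease-status scaling %s\n",
              object@occasionYears,
              if (is.na(object@statusFerritin)) "state-dependent"
              else sprintf("fixed at %.0f ug/L", object@statusFerritin)))
})

setMethod("show", "FitResult", function(object) {
  cat("Population fit (Laplace)\n")
  cat(sprintf("  -2LL = %.4f, convergence = %d\n", object@ofv,
              object@convergence))
  est <- object@estimates
  se <- object@se
  for (nm in names(est)) {
    tag <- if (nm %in% object@estimated) {
      if (is.finite(se[nm])) sprintf(" (SE %.3g)", se[nm]) else ""
    } else " (fixed)"
    cat(sprintf("  %-9s %.4g%s\n", nm, est[nm], tag))
  }
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "Cohort spec: %d subjects, dose %g mg/kg %d d/wk, follow-up <= %g y\n",
    object@nSubjects, object@dosePerKg, object@dosingDaysPerWeek,
    object@maxFollowupYears))
})
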