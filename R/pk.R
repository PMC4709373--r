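# Two-compartment PK of deferoxamine: allometric scaling, closed-form
# concentration under repeated zero-order infusions, and the average
# steady-state concentration used as the exposure metric of the drug effect.

#' Allometric scaling of disposition parameters
#'
#' Clearances scale with (weight/refWeight)^0.75, volumes with
#' (weight/refWeight)^1; the scaled parameter set refers to \code{weight}.
#'
#' @param params a \code{\link{pkParameters}} object
#' @param weight target body weight, kg
#' @param expCl,expV allometric exponents on clearances and volumes
#' @return a \code{PKParameters} object at \code{weight}
#' @export
allometricScale <- function(params, weight, expCl = 0.75, expV = 1.0) {
  stopifnot(is(params, "PKParameters"))
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0)
    stop("weight must be a single positive number")
  r <- weight / params@refWeight
  pkParameters(cl = params@cl * r^expCl, q = params@q * r^expCl,
               v1 = params@v1 * r^expV, v2 = params@v2 * r^expV,
               refWeight = weight)
}

# Micro-constants of the scaled two-compartment model.
.microConstants <- function(pk) {
  k10 <- pk@cl / pk@v1
  k12 <- pk@q / pk@v1
  k21 <- pk@q / pk@v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

# Central concentration at times t (h) for a single zero-order infusion of
# rate r0 (mg/h) over tau (h) starting at t = 0; closed-form biexponential.
.singleInfusionConc <- function(pk, r0, tau, t) {
  mc <- .microConstants(pk)
  a <- mc$alpha; b <- mc$beta; k21 <- mc$k21
  ca <- (a - k21) / (a * (a - b))
  cb <- (k21 - b) / (b * (a - b))
  conc <- numeric(length(t))
  during <- t >= 0 & t <= tau
  after <- t > tau
  if (any(during)) {
    td <- t[during]
    conc[during] <- (r0 / pk@v1) *
      (ca * (1 - exp(-a * td)) + cb * (1 - exp(-b * td)))
  }
  if (any(after)) {
    ta <- t[after]
    conc[after] <- (r0 / pk@v1) *
      (ca * (exp(-a * (ta - tau)) - exp(-a * ta)) +
       cb * (exp(-b * (ta - tau)) - exp(-b * ta)))
  }
  conc
}

# Scheduled infusion start times (h) under the weekly pattern: dosing on the
# first dosingDaysPerWeek days of each 7-day week, infusion starting at the
# top of each dosing day.
.infusionStarts <- function(dosingDaysPerWeek, horizon) {
  nWeeks <- ceiling((horizon + 1e-9) / 168) + 1L
  wk <- rep(seq_len(nWeeks) - 1L, each = dosingDaysPerWeek)
  day <- rep(seq_len(dosingDaysPerWeek) - 1L, nWeeks)
  starts <- (wk * 7 + day) * 24
  starts[starts <= horizon]
}

#' Plasma concentration under repeated subcutaneous infusions
#'
#' Closed-form superposition of the biexponential solution of the
#' two-compartment model with zero-order input. Parameters are allometrically
#' scaled to the regimen's body weight before evaluation.
#'
#' @param params \code{\link{pkParameters}}
#' @param regimen \code{\link{infusionRegimen}}
#' @param times non-negative, strictly increasing time grid, h
#' @param nDoses number of infusions to administer; \code{NULL} (default)
#'   administers every scheduled infusion up to \code{max(times)}
#' @return data.frame with columns \code{time_h}, \code{conc_mg_per_L}
#' @export
simulateConcentration <- function(params, regimen, times, nDoses = NULL) {
  stopifnot(is(params, "PKParameters"), is(regimen, "InfusionRegimen"))
  if (length(times) == 0L) stop("time grid must not be empty")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be non-negative and finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  pk <- allometricScale(params, regimen@bodyWeight)
  amount <- regimen@dosePerKg * regimen@bodyWeight
  conc <- numeric(length(times))
  if (amount > 0) {
    tau <- regimen@infusionDuration
    r0 <- amount / tau
    starts <- .infusionStarts(regimen@dosingDaysPerWeek, max(times))
    if (!is.null(nDoses)) starts <- starts[seq_len(min(nDoses, length(starts)))]
    for (s in starts) {
      idx <- times >= s
      if (any(idx))
        conc[idx] <- conc[idx] + .singleInfusionConc(pk, r0, tau, times[idx] - s)
    }
  }
  data.frame(time_h = times, conc_mg_per_L = conc)
}

#' Average steady-state concentration
#'
#' The exposure metric driving the drug effect: total dose over the averaging
#' window divided by clearance times window length. The default one-week
#' window smooths the 5-on/2-off schedule into a single number; the
#' \code{"dosing-day"} variant returns the 24-h average on a dosing day (used
#' by the calendar-to-exposure conversion).
#'
#' @param params \code{\link{pkParameters}}
#' @param regimen \code{\link{infusionRegimen}}
#' @param per averaging window: \code{"week"} (168 h, default) or
#'   \code{"dosing-day"} (24 h containing one dose)
#' @return an \code{\link{ExposureSummary-class}} object
#' @export
cssAverage <- function(params, regimen, per = c("week", "dosing-day")) {
  stopifnot(is(params, "PKParameters"), is(regimen, "InfusionRegimen"))
  per <- match.arg(per)
  pk <- allometricScale(params, regimen@bodyWeight)
  amount <- regimen@dosePerKg * regimen@bodyWeight
  if (per == "week") {
    window <- 168
    total <- amount * regimen@dosingDaysPerWeek
  } else {
    window <- 24
    total <- amount
  }
  new("ExposureSummary", cssAv = total / (pk@cl * window), window = window)
}
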