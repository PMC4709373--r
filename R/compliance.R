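# Dosing calendars, adherence-pattern generators (random missed doses and
# drug holidays), calendar-to-exposure conversion, and the observational
# adherence proxy CMPL.
#
# Calendar arithmetic follows the 50-week dosing year: 5 doses/week gives
# exactly 250 scheduled doses per year, and the drug-holiday stratification
# blocks are 50 / 25 / 10 / 5 dosing weeks ("1 year", "6 months", "2 months",
# "1 month"), i.e. 250 / 125 / 50 / 25 scheduled doses per block at the
# default pattern.

.STRAT_WEEKS <- c("1 year" = 50, "6 months" = 25, "2 months" = 10,
                  "1 month" = 5)

# round half away from zero (for non-negative x), so the printed
# missed-dose grid is reproduced exactly
.roundHalfUp <- function(x) floor(x + 0.5)

#' Build a fully adherent dosing calendar
#'
#' Doses are scheduled on the first \code{dosingDaysPerWeek} days of each
#' 7-day week, for 50 dosing weeks per year, all marked taken.
#'
#' @param dosingDaysPerWeek dosing days per week (1-7)
#' @param years number of dosing years (positive; fractional allowed,
#'   rounded to whole weeks)
#' @return a \code{\link{DosingCalendar-class}} object
#' @export
buildCalendar <- function(dosingDaysPerWeek = 5, years = 1) {
  d <- as.integer(dosingDaysPerWeek)
  if (is.na(d) || d < 1L || d > 7L)
    stop("dosingDaysPerWeek must be in 1..7")
  if (!is.finite(years) || years <= 0) stop("years must be > 0")
  nWeeks <- round(.DOSING_WEEKS_PER_YEAR * years)
  wk <- rep(seq_len(nWeeks) - 1L, each = d)
  dayInWeek <- rep(seq_len(d), nWeeks)
  day <- as.integer(wk * 7L + dayInWeek)
  new("DosingCalendar", day = day, taken = rep(TRUE, length(day)),
      dosingDaysPerWeek = d, years = years)
}

#' @describeIn buildCalendar number of scheduled doses
#' @param cal a \code{DosingCalendar}
#' @export
scheduledDoses <- function(cal) length(cal@day)

#' @describeIn buildCalendar number of missed doses
#' @export
missedDoses <- function(cal) sum(!cal@taken)

#' Miss single doses at random (poor quality of execution)
#'
#' Within each dosing year, exactly \code{round(fraction * doses-per-year)}
#' doses are flipped to missed, chosen uniformly without replacement.
#' Deterministic for a given seed.
#'
#' @param cal a \code{\link{DosingCalendar-class}}
#' @param fraction proportion of doses missed, in [0, 1]
#' @param seed integer seed
#' @return the modified calendar
#' @export
applyRandomMissing <- function(cal, fraction, seed = 1) {
  stopifnot(is(cal, "DosingCalendar"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  perYear <- .DOSING_WEEKS_PER_YEAR * cal@dosingDaysPerWeek
  n <- length(cal@day)
  yearOf <- (seq_len(n) - 1L) %/% perYear
  taken <- cal@taken
  set.seed(as.integer(seed))
  for (yr in unique(yearOf)) {
    idx <- which(yearOf == yr)
    k <- .roundHalfUp(fraction * length(idx))
    if (k > 0) taken[sample(idx, k)] <- FALSE
  }
  initialize(cal, taken = taken)
}

#' Miss consecutive doses (drug holidays)
#'
#' The dose sequence is partitioned into consecutive stratification blocks;
#' within each block the first \code{round(fraction * block size)} scheduled
#' doses are missed (an end-of-block variant is available). A partial
#' trailing block is handled pro rata. Deterministic.
#'
#' @inheritParams applyRandomMissing
#' @param stratification block length: \code{"1 year"}, \code{"6 months"},
#'   \code{"2 months"} or \code{"1 month"} (50/25/10/5 dosing weeks)
#' @param placement place the holiday at the \code{"start"} (default) or
#'   \code{"end"} of each block
#' @return the modified calendar
#' @export
applyDrugHolidays <- function(cal, fraction,
                              stratification = c("1 year", "6 months",
                                                 "2 months", "1 month"),
                              placement = c("start", "end")) {
  stopifnot(is(cal, "DosingCalendar"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  stratification <- match.arg(stratification)
  placement <- match.arg(placement)
  blockDoses <- .STRAT_WEEKS[[stratification]] * cal@dosingDaysPerWeek
  n <- length(cal@day)
  blockOf <- (seq_len(n) - 1L) %/% blockDoses
  taken <- cal@taken
  for (bl in unique(blockOf)) {
    idx <- which(blockOf == bl)
    k <- .roundHalfUp(fraction * length(idx))
    if (k > 0) {
      miss <- if (placement == "start") idx[seq_len(k)]
              else idx[seq.int(length(idx) - k + 1L, length(idx))]
      taken[miss] <- FALSE
    }
  }
  initialize(cal, taken = taken)
}

#' Convert a dosing calendar to a daily exposure timeline
#'
#' On a day with a taken dose the exposure level is the 24-h average
#' steady-state concentration of one dose (\code{dose / (CL * 24)}, with
#' allometrically scaled clearance); on missed and off days it is zero. Under
#' full adherence the weekly time-average equals
#' \code{\link{cssAverage}(..., per = "week")}.
#'
#' @param cal a \code{\link{DosingCalendar-class}}
#' @param regimen \code{\link{infusionRegimen}}
#' @param pk \code{\link{pkParameters}}
#' @return an \code{\link{exposureTimeline}} (time in h from treatment start)
#' @export
exposureFromCalendar <- function(cal, regimen, pk = pkParameters()) {
  stopifnot(is(cal, "DosingCalendar"), is(regimen, "InfusionRegimen"))
  dayLevel <- cssAverage(pk, regimen, per = "dosing-day")@cssAv
  lastDay <- max(cal@day)
  levels <- numeric(lastDay + 1L)  # trailing zero beyond the calendar
  levels[cal@day[cal@taken]] <- dayLevel
  # compress runs of equal daily levels into segments
  chg <- c(TRUE, diff(levels) != 0)
  exposureTimeline(levels = levels[chg], breaks = (which(chg) - 1L) * 24)
}

#' Observational adherence proxy CMPL
#'
#' The fraction of a patient's ferritin observations above the 2500 ug/L
#' threshold, used as a non-adherence proxy.
#'
#' @param ferritin observed ferritin values, ug/L
#' @param threshold threshold, ug/L (default 2500)
#' @return fraction in [0, 1]
#' @export
deriveCmpl <- function(ferritin, threshold = 2500) {
  ferritin <- ferritin[!is.na(ferritin)]
  if (length(ferritin) == 0L) stop("at least one observation is required")
  sum(ferritin > threshold) / length(ferritin)
}

#' Compliance-adjusted exposure
#'
#' \code{TCss = Css * (1 - CMPL)}: the "true" average steady-state
#' concentration after accounting for treatment compliance.
#'
#' @param cssAv average steady-state concentration, mg/L
#' @param cmpl adherence proxy in [0, 1]
#' @return adjusted exposure, mg/L
#' @export
complianceAdjustedExposure <- function(cssAv, cmpl) {
  if (any(cmpl < 0 | cmpl > 1)) stop("cmpl must be in [0, 1]")
  if (any(cssAv < 0)) stop("cssAv must be >= 0")
  cssAv * (1 - cmpl)
}
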