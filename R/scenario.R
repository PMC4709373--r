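# Decision-support simulations: time to reach the 2500 ug/L ferritin
# threshold under dose/weight/baseline grids and under adherence-pattern
# scenarios, with the 5-year censoring rule.

#' Time to reach the ferritin threshold
#'
#' Simulates the ferritin trajectory from \code{f0} on a dense output grid
#' and locates the first downward crossing of \code{threshold} by
#' sign-change bracketing with linear interpolation. If the trajectory never
#' reaches the threshold within \code{capYears}, the result is censored
#' (\code{NA} with attribute \code{censored = TRUE}). If \code{f0} is at or
#' below the threshold the time is 0 by convention. When \code{f0} exceeds
#' the drug-free steady state a warning is emitted (the trajectory then falls
#' even without treatment).
#'
#' @param f0 starting ferritin, ug/L
#' @param exposure constant (mg/L) or \code{\link{exposureTimeline}}
#' @param disease,drug model parameters
#' @param threshold target ferritin, ug/L
#' @param capYears censoring horizon, years
#' @param gridHours dense output grid spacing, h
#' @param statusFerritin see \code{\link{simulateFerritin}}
#' @param engine integration engine; the compiled solver is the default here
#'   because scenario grids run thousands of trajectories
#' @param rtol,atol integration tolerances
#' @param checkBaseline warn if \code{f0} exceeds the drug-free steady state
#' @return time in years (\code{NA} if censored, with attribute
#'   \code{censored})
#' @export
timeToThreshold <- function(f0, exposure, disease = diseaseParameters(),
                            drug = drugEffectParameters(), threshold = 2500,
                            capYears = 5, gridHours = 24,
                            statusFerritin = NA,
                            engine = c("rk45", "bdf"), rtol = 1e-8,
                            atol = 1e-6, checkBaseline = TRUE) {
  engine <- match.arg(engine)
  if (f0 <= threshold) {
    out <- 0
    attr(out, "censored") <- FALSE
    return(out)
  }
  if (checkBaseline) {
    ss0 <- tryCatch(
      steadyStateFerritin(disease, drug, 0, statusFerritin),
      error = function(e) NA_real_)
    if (is.finite(ss0) && f0 > ss0)
      warning(sprintf(
        "baseline %.0f exceeds the drug-free steady state %.0f ug/L", f0,
        ss0))
  }
  capH <- capYears * .HOURS_PER_YEAR
  grid <- seq(0, capH, by = gridHours)
  if (grid[length(grid)] < capH) grid <- c(grid, capH)
  traj <- simulateFerritin(f0, grid, exposure, disease, drug,
                           statusFerritin = statusFerritin, engine = engine,
                           rtol = rtol, atol = atol)$ferritin_ug_per_L
  below <- which(traj <= threshold)
  if (length(below) == 0L) {
    out <- NA_real_
    attr(out, "censored") <- TRUE
    return(out)
  }
  i <- below[1]
  tCross <- if (i == 1L) 0 else {
    f1 <- traj[i - 1]; f2 <- traj[i]
    grid[i - 1] + (f1 - threshold) / (f1 - f2) * (grid[i] - grid[i - 1])
  }
  out <- tCross / .HOURS_PER_YEAR
  attr(out, "censored") <- FALSE
  out
}

#' Dose / body-weight / baseline scenario grid
#'
#' Full factorial grid of constant-exposure simulations: for each dose and
#' body weight the weekly average steady-state concentration is computed
#' (allometrically scaled clearance), and the time to reach the threshold is
#' simulated from each starting baseline.
#'
#' @param doses daily doses, mg/kg
#' @param weights body weights, kg
#' @param baselines starting ferritin levels, ug/L
#' @param pk,disease,drug model parameters
#' @param dosingDaysPerWeek dosing days per week
#' @param threshold,capYears,gridHours see \code{\link{timeToThreshold}}
#' @param statusFerritin see \code{\link{simulateFerritin}}
#' @return data.frame with columns \code{dose_mg_per_kg}, \code{weight_kg},
#'   \code{baseline}, \code{css_mg_per_L}, \code{time_years} (3 decimals,
#'   NA when censored), \code{censored}
#' @export
doseGrid <- function(doses = c(30, 45, 60), weights = seq(15, 75, by = 10),
                     baselines = seq(3000, 12000, by = 1000),
                     pk = pkParameters(), disease = diseaseParameters(),
                     drug = drugEffectParameters(), dosingDaysPerWeek = 5,
                     threshold = 2500, capYears = 5, gridHours = 24,
                     statusFerritin = NA) {
  .warnHighBaselines(baselines, disease, drug, statusFerritin)
  cells <- expand.grid(dose_mg_per_kg = doses, weight_kg = weights,
                       baseline = baselines, KEEP.OUT.ATTRS = FALSE)
  css <- mapply(function(d, w) {
    cssAv(cssAverage(pk, infusionRegimen(d, w,
                                         dosingDaysPerWeek = dosingDaysPerWeek)))
  }, cells$dose_mg_per_kg, cells$weight_kg)
  tt <- vapply(seq_len(nrow(cells)), function(i) {
    as.numeric(timeToThreshold(cells$baseline[i], css[i], disease, drug,
                               threshold, capYears, gridHours,
                               statusFerritin, checkBaseline = FALSE))
  }, numeric(1))
  cells$css_mg_per_L <- css
  cells$time_years <- round(tt, 3)
  cells$censored <- is.na(tt)
  cells
}

.warnHighBaselines <- function(baselines, disease, drug, statusFerritin) {
  ss0 <- tryCatch(steadyStateFerritin(disease, drug, 0, statusFerritin),
                  error = function(e) NA_real_)
  if (is.finite(ss0) && any(baselines > ss0))
    warning(sprintf(
      "%d baseline(s) exceed the drug-free steady state (%.0f ug/L); such trajectories fall even without drug",
      sum(baselines > ss0), ss0))
  invisible(ss0)
}

#' Adherence-pattern scenario grid
#'
#' For a reference patient (45 kg, 45 mg/kg/day, 5 days/week by default),
#' simulates the time to reach the ferritin threshold for every combination
#' of missed-dose fraction, adherence pattern (single doses missed at random,
#' averaged over seeds; or drug holidays at each stratification), and
#' starting baseline. Compliance enters through the dosing calendar only (the
#' CMPL exposure correction is not applied on top).
#'
#' @param fractions missed-dose fractions
#' @param baselines starting ferritin levels, ug/L
#' @param weight,dosePerKg,dosingDaysPerWeek reference patient and regimen
#' @param nSeeds number of random-pattern replicates per cell
#' @param seed base seed; replicate s uses \code{seed * 1000 + s}
#' @param stratifications drug-holiday stratification periods
#' @param pk,disease,drug model parameters
#' @param threshold,capYears,gridHours see \code{\link{timeToThreshold}}
#' @param statusFerritin see \code{\link{simulateFerritin}}
#' @return data.frame with one row per (pattern, stratification, fraction,
#'   baseline): \code{time_years} is the mean over non-censored replicates (3
#'   decimals; NA when censored), \code{censored} is TRUE when at least half
#'   the replicates fail to reach the threshold, \code{n_censored} counts
#'   censored replicates
#' @export
complianceGrid <- function(fractions = seq(0.1, 0.9, by = 0.1),
                           baselines = seq(3000, 12000, by = 1000),
                           weight = 45, dosePerKg = 45,
                           dosingDaysPerWeek = 5, nSeeds = 20, seed = 1,
                           stratifications = c("1 year", "6 months",
                                               "2 months", "1 month"),
                           pk = pkParameters(),
                           disease = diseaseParameters(),
                           drug = drugEffectParameters(), threshold = 2500,
                           capYears = 5, gridHours = 24,
                           statusFerritin = NA) {
  .warnHighBaselines(baselines, disease, drug, statusFerritin)
  regimen <- infusionRegimen(dosePerKg, weight,
                             dosingDaysPerWeek = dosingDaysPerWeek)
  # a dosing year spans 350 days; cover the full censoring horizon
  calYears <- ceiling(capYears * .HOURS_PER_YEAR / (350 * 24))
  cal <- buildCalendar(dosingDaysPerWeek, years = calYears)
  oneCell <- function(calMod, baseline) {
    as.numeric(timeToThreshold(baseline, exposureFromCalendar(calMod,
                                                              regimen, pk),
                               disease, drug, threshold, capYears,
                               gridHours, statusFerritin,
                               checkBaseline = FALSE))
  }
  rows <- list()
  for (f in fractions) {
    randomCals <- lapply(seq_len(nSeeds), function(s)
      applyRandomMissing(cal, f, seed = seed * 1000 + s))
    for (b in baselines) {
      tt <- vapply(randomCals, oneCell, numeric(1), baseline = b)
      nc <- sum(is.na(tt))
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = "random", stratification = "1 year", fraction_missed = f,
        baseline = b,
        time_years = if (all(is.na(tt))) NA_real_
                     else round(mean(tt, na.rm = TRUE), 3),
        censored = nc >= nSeeds / 2, n_censored = nc)
      for (st in stratifications) {
        th <- oneCell(applyDrugHolidays(cal, f, st), b)
        rows[[length(rows) + 1L]] <- data.frame(
          pattern = "consecutive", stratification = st,
          fraction_missed = f, baseline = b, time_years = round(th, 3),
          censored = is.na(th), n_censored = as.integer(is.na(th)))
      }
    }
  }
  do.call(rbind, rows)
}

#' Largest effective missed-dose fraction
#'
#' Convenience summary of a \code{\link{complianceGrid}} result: the largest
#' missed-dose fraction at which the threshold is still reached (cell not
#' censored) under any pattern, for a given baseline.
#'
#' @param grid result of \code{\link{complianceGrid}}
#' @param baseline baseline to summarise (default: smallest in the grid)
#' @return fraction (0 if no cell reaches the threshold)
#' @export
largestEffectiveFraction <- function(grid, baseline = min(grid$baseline)) {
  g <- grid[grid$baseline == baseline & !grid$censored, ]
  if (nrow(g) == 0L) return(0)
  max(g$fraction_missed)
}
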