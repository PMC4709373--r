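# Ferritin turnover model: disease-status scaling, conversion rate, drug
# effect, right-hand side, steady state, and trajectory simulation.

.diseasePars <- function(disease) {
  c(disease@kin, disease@kout, disease@sclRef, disease@shpRef,
    disease@thetaScl, disease@thetaShp, disease@ferritinMed)
}

# statusFerritin = NA -> state-dependent scaling (encoded <= 0 for C++).
.statusF <- function(statusFerritin) {
  if (is.null(statusFerritin) || is.na(statusFerritin)) -1.0
  else as.numeric(statusFerritin)
}

#' Disease-status scaling of the conversion-rate parameters
#'
#' The conversion-rate scale and shape are power functions of ferritin
#' relative to the population median:
#' \code{SCL_i = sclRef * (F/Fmed)^thetaScl},
#' \code{SHP_i = shpRef * (F/Fmed)^thetaShp}.
#'
#' @param ferritin ferritin level(s), ug/L; floored at 1e-6 so zero with a
#'   negative exponent cannot occur
#' @param disease \code{\link{diseaseParameters}}
#' @return list with vectors \code{scl} and \code{shp}
#' @export
diseaseStatusScaling <- function(ferritin, disease) {
  stopifnot(is(disease, "DiseaseParameters"))
  if (any(ferritin < 0)) stop("ferritin must be >= 0")
  r <- pmax(ferritin, 1e-6) / disease@ferritinMed
  list(scl = disease@sclRef * r^disease@thetaScl,
       shp = disease@shpRef * r^disease@thetaShp)
}

#' Transfusion-driven conversion rate CRT
#'
#' \code{CRT = SCL_i * exp(-SHP_i * F)}: the additive ferritin production due
#' to the chronic transfusion regimen, exponentially damped by the current
#' ferritin level.
#'
#' @inheritParams diseaseStatusScaling
#' @param statusFerritin fixed reference ferritin for the status scaling, or
#'   \code{NA} (default) for state-dependent scaling
#' @return rate, ug/L per h
#' @export
conversionRate <- function(ferritin, disease, statusFerritin = NA) {
  base <- if (is.na(.na1(statusFerritin))) ferritin else
    rep(statusFerritin, length.out = length(ferritin))
  sc <- diseaseStatusScaling(base, disease)
  sc$scl * exp(-sc$shp * pmax(ferritin, 1e-6))
}

.na1 <- function(x) if (is.null(x)) NA_real_ else x[1]

#' Drug effect multiplier
#'
#' \code{DFO = slope * exposure}; multiplies the ferritin elimination rate as
#' \code{kout * (1 + DFO)}.
#'
#' @param exposure average steady-state concentration(s), mg/L
#' @param drug \code{\link{drugEffectParameters}}
#' @return dimensionless effect
#' @export
drugEffect <- function(exposure, drug) {
  stopifnot(is(drug, "DrugEffectParameters"))
  if (any(exposure < 0)) stop("exposure must be >= 0")
  drug@slope * exposure
}

#' Ferritin turnover right-hand side
#'
#' \code{dF/dt = kin + CRT(F) - kout * F * (1 + DFO)}.
#'
#' @inheritParams conversionRate
#' @param drug \code{\link{drugEffectParameters}}
#' @param exposure drug exposure, mg/L
#' @param crtMultiplier multiplier on CRT (occasion effect), default 1
#' @return derivative, ug/L per h
#' @export
ferritinRhs <- function(ferritin, exposure, disease, drug,
                        statusFerritin = NA, crtMultiplier = 1) {
  crt <- crtMultiplier * conversionRate(ferritin, disease, statusFerritin)
  disease@kin + crt -
    disease@kout * ferritin * (1 + drugEffect(exposure, drug))
}

#' Steady-state ferritin under constant exposure
#'
#' Root of \code{kin + CRT(F) = kout * F * (1 + DFO)}, bracketed on
#' \code{interval} and solved by \code{\link[stats]{uniroot}} to a residual
#' below \code{tol}.
#'
#' @inheritParams ferritinRhs
#' @param interval bracketing interval, ug/L
#' @param tol absolute residual tolerance on the right-hand side
#' @return steady-state ferritin, ug/L
#' @export
steadyStateFerritin <- function(disease, drug, exposure = 0,
                                statusFerritin = NA,
                                interval = c(1e-3, 1e6), tol = 1e-10) {
  f <- function(x) ferritinRhs(x, exposure, disease, drug, statusFerritin)
  lo <- f(interval[1]); hi <- f(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop(sprintf(
      "no sign change of dF/dt on [%g, %g]: f(lo) = %g, f(hi) = %g",
      interval[1], interval[2], lo, hi))
  root <- uniroot(f, interval, tol = 1e-12,
                  maxiter = 10000)$root
  # polish by bisection until the rate residual is below tol
  a <- interval[1]; b <- interval[2]
  x <- root
  for (i in 1:200) {
    if (abs(f(x)) < tol) break
    if (f(a) * f(x) <= 0) b <- x else a <- x
    x <- (a + b) / 2
  }
  x
}

#' Simulate a ferritin trajectory
#'
#' Numerical solution of the turnover model under a piecewise-constant
#' exposure timeline (and optionally a piecewise-constant multiplier on CRT,
#' used for inter-occasion variability). The default engine is deSolve's
#' implicit BDF integrator with restarts at every exposure breakpoint; the
#' \code{"rk45"} engine is the package's compiled adaptive Cash-Karp solver,
#' used by the scenario and estimation machinery for speed (the system is
#' only mildly stiff on the simulated horizon) and cross-checked against the
#' BDF path in the test suite.
#'
#' @param f0 initial ferritin, ug/L (> 0)
#' @param times output time grid, h; non-negative, strictly increasing
#' @param exposure a single constant (mg/L) or an
#'   \code{\link{exposureTimeline}}
#' @param disease \code{\link{diseaseParameters}}
#' @param drug \code{\link{drugEffectParameters}}
#' @param crtScale optional \code{ExposureTimeline} multiplying CRT
#' @param statusFerritin fixed status-scaling reference, or \code{NA} for
#'   state-dependent (default)
#' @param engine \code{"bdf"} (deSolve, default) or \code{"rk45"} (compiled)
#' @param rtol,atol integration tolerances
#' @return data.frame with columns \code{time_h}, \code{ferritin_ug_per_L},
#'   \code{exposure_mg_per_L}
#' @export
simulateFerritin <- function(f0, times, exposure = 0,
                             disease = diseaseParameters(),
                             drug = drugEffectParameters(), crtScale = NULL,
                             statusFerritin = NA,
                             engine = c("bdf", "rk45"), rtol = 1e-8,
                             atol = 1e-6) {
  engine <- match.arg(engine)
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be a positive number")
  if (length(times) == 0L) stop("time grid must not be empty")
  if (any(times < 0) || (length(times) > 1L && any(diff(times) <= 0)))
    stop("times must be non-negative and strictly increasing")
  tl <- .asTimeline(exposure)
  cs <- if (is.null(crtScale)) exposureTimeline(1) else .asTimeline(crtScale)
  ferr <- if (engine == "rk45") {
    .ferritinTrajCpp(f0, times, tl@breaks, tl@levels, cs@breaks, cs@levels,
                     .diseasePars(disease), drug@slope,
                     .statusF(.na1(statusFerritin)), rtol, atol)
  } else {
    .trajBdf(f0, times, tl, cs, disease, drug, .na1(statusFerritin), rtol,
             atol)
  }
  data.frame(time_h = times, ferritin_ug_per_L = ferr,
             exposure_mg_per_L = timelineAt(tl, times))
}

# deSolve BDF path with integrator restarts at timeline breakpoints.
.trajBdf <- function(f0, times, tl, cs, disease, drug, statusFerritin, rtol,
                     atol) {
  brks <- sort(unique(c(tl@breaks, cs@breaks)))
  brks <- brks[brks > 0 & brks < max(times)]
  segEnds <- c(brks, max(times))
  out <- numeric(length(times))
  if (times[1] == 0) out[1] <- f0
  t0 <- 0
  y <- f0
  rhsFun <- function(t, y, parms) {
    list(ferritinRhs(y, parms$e, disease, drug, statusFerritin, parms$m))
  }
  for (tEnd in segEnds) {
    if (tEnd <= t0) next
    inner <- times[times > t0 & times <= tEnd]
    grid <- sort(unique(c(t0, inner, tEnd)))
    parms <- list(e = timelineAt(tl, t0), m = timelineAt(cs, t0))
    sol <- deSolve::ode(y = c(F = y), times = grid, func = rhsFun,
                        parms = parms, method = "bdf", rtol = rtol,
                        atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("stiff integrator failed: ",
           paste(attr(sol, "istate"), collapse = " "))
    solt <- sol[, 1]
    soly <- pmax(sol[, 2], 0)
    if (length(inner))
      out[match(inner, times)] <- soly[match(inner, solt)]
    y <- soly[length(soly)]
    t0 <- tEnd
  }
  out
}
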