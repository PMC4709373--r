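# Shared fixtures: small, fast cohort settings for estimation tests and a
# deSolve oracle for the two-compartment infusion model.

smallCohortSpec <- function(n = 5) {
  cohortSpec(nSubjects = n, obsParentMean = 12, obsParentSd = 2,
             obsCountRange = c(8, 16), maxFollowupYears = 4)
}

# deSolve integration of the two-compartment model with zero-order infusions
# on the first `dosingDays` days of each week (amounts parameterisation);
# independent of the closed-form implementation.
odeConcOracle <- function(pk, regimen, times, nDoses = Inf) {
  k10 <- pk@cl / pk@v1
  k12 <- pk@q / pk@v1
  k21 <- pk@q / pk@v2
  amount <- regimen@dosePerKg * regimen@bodyWeight
  tau <- regimen@infusionDuration
  r0 <- amount / tau
  starts <- ferridyn:::.infusionStarts(regimen@dosingDaysPerWeek, max(times))
  starts <- starts[seq_len(min(nDoses, length(starts)))]
  edges <- sort(unique(c(0, starts, starts + tau, times, max(times))))
  rhs <- function(t, y, p) {
    inFus <- any(t >= starts - 1e-9 & t < starts + tau - 1e-9)
    rate <- if (inFus) r0 else 0
    list(c(rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  y <- c(0, 0)
  out <- numeric(length(times))
  if (any(times == 0)) out[times == 0] <- 0
  for (i in seq_len(length(edges) - 1)) {
    seg <- c(edges[i], times[times > edges[i] & times < edges[i + 1]],
             edges[i + 1])
    seg <- sort(unique(seg))
    sol <- deSolve::ode(y, seg, rhs, NULL, method = "lsoda", rtol = 1e-10,
                        atol = 1e-12)
    hit <- match(times, sol[, 1])
    out[!is.na(hit)] <- sol[hit[!is.na(hit)], 2]
    y <- sol[nrow(sol), 2:3]
  }
  out / pk@v1
}

# exact solution of the turnover model in the linear limit (sclRef = 0,
# constant exposure)
linearDecayOracle <- function(f0, times, exposure, disease, drug) {
  k <- disease@kout * (1 + drug@slope * exposure)
  a <- disease@kin / k
  a + (f0 - a) * exp(-k * times)
}

# per-block missed-dose counts of a calendar
missedPerBlock <- function(cal, blockDoses) {
  n <- length(cal@day)
  blockOf <- (seq_len(n) - 1L) %/% blockDoses
  as.integer(tapply(!cal@taken, blockOf, sum))
}
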