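# Nonlinear mixed-effects estimation of the drug model from longitudinal
# ferritin data: Laplace approximation of the marginal likelihood (inner
# modes by quasi-Newton, curvature by Gauss-Newton), bootstrap, and visual
# predictive checks.
#
# Random-effects structure: theta_i = theta_TV * exp(eta + IOV), with eta on
# the concentration-effect slope per subject and a per-occasion effect
# multiplying the conversion rate; residual Y = F * (1 + eps), eps ~ N(0,
# sigma^2) (proportional weighting W = F). Exposure within estimation is the
# compliance-adjusted constant TCss = Css * (1 - CMPL) of each subject.

# Decompose a dataset into per-subject records. The first observation is
# taken as the initial ferritin (the trajectory starts there); remaining
# observations enter the likelihood. Occasions are consecutive windows of
# pop@occasionYears from the first observation.
.splitSubjects <- function(data, pop, dosingDaysPerWeek = 5) {
  .validateDataset(data)
  ids <- unique(data$ID)
  occH <- pop@occasionYears * .HOURS_PER_YEAR
  lapply(ids, function(id) {
    d <- data[data$ID == id, , drop = FALSE]
    obs <- d[d$EVID == 0 & d$MDV == 0, , drop = FALSE]
    if (nrow(obs) < 1L)
      stop("subject ", id, " has no observations")
    doseRows <- d[d$EVID == 1, , drop = FALSE]
    dailyDose <- if (nrow(doseRows)) doseRows$AMT[1] else NA_real_
    wt <- d$WT[1]
    cmpl <- d$CMPL[1]
    t0 <- obs$TIME[1]
    f0 <- obs$DV[1]
    tObs <- obs$TIME[-1] - t0
    y <- obs$DV[-1]
    span <- if (length(tObs)) max(tObs) else 0
    nOcc <- max(1L, as.integer(floor(span / occH - 1e-9)) + 1L)
    regimen <- infusionRegimen(dailyDose / wt, wt,
                               dosingDaysPerWeek = dosingDaysPerWeek)
    css <- cssAv(cssAverage(pop@pk, regimen))
    list(id = id, wt = wt, cmpl = cmpl, dailyDose = dailyDose, f0 = f0,
         t = tObs, y = y, nOcc = nOcc,
         occBreaks = (seq_len(nOcc) - 1) * occH,
         css = css, exposure = complianceAdjustedExposure(css, cmpl))
  })
}

# Random-effect layout for one subject under the current variances.
.reLayout <- function(sub, pop) {
  useEta <- pop@omegaIIV > 0
  nOcc <- if (pop@omegaIOV > 0) sub$nOcc else 0L
  list(useEta = useEta, nOcc = nOcc, d = as.integer(useEta) + nOcc)
}

.subjectNllFun <- function(sub, pop, lay, rtol, atol) {
  pars <- .diseasePars(pop@disease)
  sF <- .statusF(pop@statusFerritin)
  ob <- if (lay$nOcc > 0) sub$occBreaks else numeric(0)
  function(b) {
    .subjectNllCpp(b, lay$useEta, lay$nOcc, sub$y, sub$t, ob, sub$exposure,
                   sub$f0, pars, pop@slope, sF, pop@omegaIIV, pop@omegaIOV,
                   pop@sigma, rtol, atol)
  }
}

# Laplace contribution of one subject: -2 log of the approximate marginal
# likelihood, plus the posterior mode (empirical-Bayes estimate).
.subjectLaplace <- function(sub, pop, bStart = NULL, rtol = 1e-6,
                            atol = 1e-3) {
  lay <- .reLayout(sub, pop)
  fn <- .subjectNllFun(sub, pop, lay, rtol, atol)
  if (lay$d == 0L) {
    g <- fn(numeric(0))
    if (g >= 1e9)
      stop("non-finite likelihood for subject ", sub$id)
    return(list(ofv = 2 * g, mode = numeric(0)))
  }
  b0 <- if (!is.null(bStart) && length(bStart) == lay$d) bStart
        else numeric(lay$d)
  opt <- optim(b0, fn, method = "BFGS",
               control = list(maxit = 150, reltol = 1e-9,
                              ndeps = rep(1e-4, lay$d)))
  mode <- opt$par
  g <- opt$value
  if (g >= 1e9)
    stop("non-finite likelihood for subject ", sub$id,
         " (predicted ferritin not positive at the posterior mode)")
  gn <- .subjectGnCpp(mode, lay$useEta, lay$nOcc, sub$t,
                      if (lay$nOcc > 0) sub$occBreaks else numeric(0),
                      sub$exposure, sub$f0, .diseasePars(pop@disease),
                      pop@slope, .statusF(pop@statusFerritin), rtol, atol)
  w <- 1 / (pop@sigma * gn$F)^2
  H <- crossprod(gn$J * w, gn$J)
  prec <- c(if (lay$useEta) 1 / pop@omegaIIV,
            rep(1 / pop@omegaIOV, lay$nOcc))
  diag(H) <- diag(H) + prec
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    diag(H) <- diag(H) * (1 + 1e-8) + 1e-10
    ch <- chol(H)
  }
  logdet <- 2 * sum(log(diag(ch)))
  list(ofv = 2 * g + logdet - lay$d * log(2 * pi), mode = mode)
}

#' Approximate marginal -2 log-likelihood of a population model
#'
#' Laplace approximation: per subject, the joint density over the random
#' effects (eta on the slope, per-occasion effects on the conversion rate) is
#' maximised by quasi-Newton, and the curvature at the mode is approximated
#' by the Gauss-Newton (first-order) expansion, the standard practice of
#' conditional-estimation pharmacometric software. With both variances at
#' zero the value collapses to the fixed-effects weighted least-squares
#' objective.
#'
#' @param data dataset in the layout of \code{\link{readDataset}}
#' @param pop a \code{\link{populationModel}}
#' @param rtol,atol ODE tolerances used inside estimation (deliberately
#'   coarser than the simulation defaults)
#' @param dosingDaysPerWeek dosing days per week assumed for exposure
#' @return -2 log marginal likelihood
#' @export
marginalLoglik <- function(data, pop, rtol = 1e-6, atol = 1e-3,
                           dosingDaysPerWeek = 5) {
  subs <- .splitSubjects(data, pop, dosingDaysPerWeek)
  sum(vapply(subs, function(s)
    .subjectLaplace(s, pop, rtol = rtol, atol = atol)$ofv, numeric(1)))
}

#' Individual prediction at the observation times
#'
#' Prediction of one subject's ferritin time course for given random effects;
#' \code{eta = 0} and \code{kappa = 0} give the population prediction (PRED).
#' The subject's slope is \code{slope * exp(eta)} and the conversion rate is
#' multiplied by \code{exp(kappa[k])} within occasion k.
#'
#' @inheritParams marginalLoglik
#' @param id subject to predict; defaults to the only/first subject
#' @param eta random effect on the slope
#' @param kappa per-occasion effects on CRT (recycled/zero-padded)
#' @return data.frame with columns \code{time_h}, \code{pred}
#' @export
individualPrediction <- function(data, pop, id = NULL, eta = 0,
                                 kappa = NULL, rtol = 1e-8, atol = 1e-6,
                                 dosingDaysPerWeek = 5) {
  if (!all(is.finite(c(eta, kappa)))) stop("random effects must be finite")
  subs <- .splitSubjects(data, pop, dosingDaysPerWeek)
  ids <- vapply(subs, `[[`, numeric(1) , "id")
  sub <- if (is.null(id)) subs[[1]] else subs[[match(id, ids)]]
  if (is.null(kappa)) kappa <- numeric(sub$nOcc)
  kappa <- rep_len(kappa, sub$nOcc)
  pred <- .subjectCurve(sub, pop, eta, kappa, rtol, atol)
  data.frame(time_h = c(0, sub$t), pred = c(sub$f0, pred))
}

# trajectory at the subject's post-baseline observation times
.subjectCurve <- function(sub, pop, eta, kappa, rtol = 1e-6, atol = 1e-3) {
  if (length(sub$t) == 0L) return(numeric(0))
  .ferritinTrajCpp(sub$f0, sub$t, 0, sub$exposure,
                   sub$occBreaks, exp(rep_len(kappa, sub$nOcc)),
                   .diseasePars(pop@disease), pop@slope * exp(eta),
                   .statusF(pop@statusFerritin), rtol, atol)
}

.POP_PARS <- c("slope", "omegaIIV", "omegaIOV", "sigma")

.setPop <- function(pop, values) {
  for (nm in names(values)) slot(pop, nm) <- unname(values[nm])
  validObject(pop)
  pop
}

.popValues <- function(pop) {
  setNames(c(pop@slope, pop@omegaIIV, pop@omegaIOV, pop@sigma), .POP_PARS)
}

#' Fit the population model by maximum (approximate) likelihood
#'
#' Minimises the Laplace objective of \code{\link{marginalLoglik}} over the
#' selected parameters on the log scale (guaranteeing positivity) with
#' \code{\link[stats]{nlminb}}, using up to three deterministic starts to
#' guard against local minima. Inner posterior modes are warm-started across
#' outer iterations. Standard errors come from the observed information
#' (finite-difference Hessian of the objective). Parameters not listed in
#' \code{estimate} are kept fixed at their \code{init} values; by default the
#' disease turnover constants, the disease-status exponents and the IOV
#' variance stay fixed, mirroring a fit where the disease submodel has been
#' characterised beforehand.
#'
#' @param data dataset (see \code{\link{readDataset}})
#' @param init initial/fixed \code{\link{populationModel}}
#' @param estimate subset of \code{c("slope", "omegaIIV", "omegaIOV",
#'   "sigma")} to estimate
#' @param nStarts number of starts (1-3)
#' @param rtol,atol ODE tolerances inside estimation
#' @param dosingDaysPerWeek dosing days per week assumed for exposure
#' @param maxit outer iteration cap
#' @return a \code{\link{FitResult-class}} object
#' @export
fitPopulation <- function(data, init = populationModel(),
                          estimate = c("slope", "omegaIIV", "sigma"),
                          nStarts = 3, rtol = 1e-6, atol = 1e-3,
                          dosingDaysPerWeek = 5, maxit = 150) {
  estimate <- match.arg(estimate, .POP_PARS, several.ok = TRUE)
  v0 <- .popValues(init)[estimate]
  if (any(v0 <= 0))
    stop("initial values of estimated parameters must be > 0")
  subs <- .splitSubjects(data, init, dosingDaysPerWeek)
  modes <- new.env(parent = emptyenv())
  objective <- function(p) {
    pop <- .setPop(init, setNames(exp(p), estimate))
    tot <- 0
    for (s in subs) {
      key <- as.character(s$id)
      res <- .subjectLaplace(s, pop, bStart = modes[[key]], rtol = rtol,
                             atol = atol)
      modes[[key]] <- res$mode
      tot <- tot + res$ofv
    }
    if (!is.finite(tot)) 1e10 else tot
  }
  startFactors <- list(
    setNames(rep(1, 4), .POP_PARS),
    c(slope = 0.3, omegaIIV = 2, omegaIOV = 2, sigma = 2),
    c(slope = 3, omegaIIV = 0.5, omegaIOV = 0.5, sigma = 0.5))
  nStarts <- max(1L, min(as.integer(nStarts), length(startFactors)))
  best <- NULL
  startLog <- data.frame(start = integer(0), ofv = numeric(0),
                         convergence = integer(0))
  for (s in seq_len(nStarts)) {
    p0 <- log(v0 * startFactors[[s]][estimate])
    rm(list = ls(modes), envir = modes)
    # Nelder-Mead: robust to the small history dependence the warm-started
    # inner modes introduce into the objective (Brent in one dimension)
    fit <- if (length(p0) == 1L) {
      optim(p0, objective, method = "Brent", lower = p0 - log(1000),
            upper = p0 + log(1000))
    } else {
      optim(p0, objective, method = "Nelder-Mead",
            control = list(maxit = 10 * maxit, reltol = 1e-7))
    }
    startLog <- rbind(startLog,
                      data.frame(start = s, ofv = fit$value,
                                 convergence = fit$convergence))
    if (is.null(best) || fit$value < best$objective)
      best <- list(par = fit$par, objective = fit$value,
                   convergence = fit$convergence,
                   message = if (is.null(fit$message)) "" else fit$message)
  }
  pHat <- best$par
  estNat <- setNames(exp(pHat), estimate)
  popHat <- .setPop(init, estNat)
  # observed-information standard errors (delta method from the log scale)
  seNat <- setNames(rep(NA_real_, length(estimate)), estimate)
  H <- tryCatch(optimHess(pHat, objective,
                          control = list(ndeps = rep(1e-3, length(pHat)))),
                error = function(e) NULL)
  if (!is.null(H)) {
    covLog <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(covLog)) {
      dg <- diag(covLog)
      ok <- is.finite(dg) & dg > 0
      seNat[ok] <- estNat[ok] * sqrt(dg[ok])
    }
  }
  # empirical-Bayes estimates at the optimum
  objective(pHat)
  ebe <- lapply(subs, function(s) {
    lay <- .reLayout(s, popHat)
    m <- modes[[as.character(s$id)]]
    list(id = s$id, eta = if (lay$useEta) m[1] else 0,
         kappa = if (lay$nOcc > 0) m[(1 + as.integer(lay$useEta)):length(m)]
                 else numeric(0))
  })
  estimatesAll <- .popValues(popHat)
  seAll <- setNames(rep(NA_real_, length(.POP_PARS)), .POP_PARS)
  seAll[estimate] <- seNat
  new("FitResult", estimates = estimatesAll, se = seAll,
      ofv = best$objective, estimated = estimate, ebe = ebe,
      convergence = as.integer(best$convergence),
      message = as.character(best$message), starts = startLog,
      model = popHat)
}

#' Nonparametric bootstrap of the population fit
#'
#' Samples subjects with replacement, refits the model to each replicate
#' dataset and summarises the estimates (mean, SD, CV\%). Replicates that do
#' not converge are excluded and counted. Deterministic for a given seed.
#'
#' @inheritParams fitPopulation
#' @param nSamples number of bootstrap replicates
#' @param seed integer seed
#' @param indices optional list of ID vectors overriding the resampling (one
#'   vector per replicate), e.g. the identity permutation
#' @return list with elements \code{summary} (data.frame: parameter, mean,
#'   sd, cv_pct), \code{estimates} (matrix), \code{nFailed}
#' @export
bootstrapFit <- function(data, init = populationModel(),
                         estimate = c("slope", "omegaIIV", "sigma"),
                         nSamples = 20, seed = 1, indices = NULL,
                         nStarts = 1, rtol = 1e-6, atol = 1e-3) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  ids <- unique(data$ID)
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(nSamples), function(r) {
    if (!is.null(indices)) indices[[r]] else sample(ids, replace = TRUE)
  })
  res <- matrix(NA_real_, nSamples, length(estimate),
                dimnames = list(NULL, estimate))
  failed <- 0L
  for (r in seq_len(nSamples)) {
    pieces <- lapply(seq_along(draws[[r]]), function(i) {
      d <- data[data$ID == draws[[r]][i], , drop = FALSE]
      d$ID <- i
      d
    })
    boot <- do.call(rbind, pieces)
    fit <- tryCatch(fitPopulation(boot, init, estimate, nStarts = nStarts,
                                  rtol = rtol, atol = atol),
                    error = function(e) NULL)
    if (is.null(fit) || fit@convergence != 0L) {
      failed <- failed + 1L
    } else {
      res[r, ] <- estimates(fit)[estimate]
    }
  }
  ok <- stats::complete.cases(res)
  mu <- colMeans(res[ok, , drop = FALSE])
  sdv <- apply(res[ok, , drop = FALSE], 2, sd)
  list(summary = data.frame(parameter = estimate, mean = mu, sd = sdv,
                            cv_pct = 100 * sdv / mu, row.names = NULL),
       estimates = res, nFailed = failed)
}

#' Visual predictive check
#'
#' Simulates replicate datasets at the observed design points (same subjects,
#' exposures, baselines and sampling times), then compares the observed
#' percentiles of ferritin per time bin with the percentile-method confidence
#' bands of the simulated percentiles.
#'
#' @inheritParams fitPopulation
#' @param pop the \code{\link{populationModel}} to simulate from
#' @param nSim number of simulated replicates (>= 100 recommended)
#' @param seed integer seed
#' @param probs percentiles to track
#' @param nBins number of time bins (quantile-spaced)
#' @param ci confidence level of the simulation bands
#' @return data.frame with one row per (bin, percentile): \code{t_mid_h},
#'   \code{prob}, \code{observed}, \code{sim_lo}, \code{sim_med},
#'   \code{sim_hi}; attribute \code{coverage} gives the fraction of
#'   observed percentiles inside their band
#' @export
visualPredictiveCheck <- function(data, pop, nSim = 200, seed = 1,
                                  probs = c(0.05, 0.5, 0.95), nBins = 8,
                                  ci = 0.95, rtol = 1e-6, atol = 1e-3,
                                  dosingDaysPerWeek = 5) {
  if (nSim < 2) stop("nSim must be at least 2")
  subs <- .splitSubjects(data, pop, dosingDaysPerWeek)
  obsT <- unlist(lapply(subs, function(s) c(0, s$t)))
  obsY <- unlist(lapply(subs, function(s) c(s$f0, s$y)))
  edges <- unique(quantile(obsT, seq(0, 1, length.out = nBins + 1)))
  bin <- pmin(pmax(findInterval(obsT, edges, rightmost.closed = TRUE), 1L),
              length(edges) - 1L)
  tMid <- tapply(obsT, bin, median)
  set.seed(as.integer(seed))
  simPct <- array(NA_real_, c(nSim, length(tMid), length(probs)))
  for (r in seq_len(nSim)) {
    ysim <- unlist(lapply(subs, function(s) {
      eta <- if (pop@omegaIIV > 0) rnorm(1, 0, sqrt(pop@omegaIIV)) else 0
      kap <- if (pop@omegaIOV > 0) rnorm(s$nOcc, 0, sqrt(pop@omegaIOV))
             else numeric(s$nOcc)
      f <- c(s$f0, .subjectCurve(s, pop, eta, kap, rtol, atol))
      f * (1 + rnorm(length(f), 0, pop@sigma))
    }))
    for (b in seq_along(tMid)) {
      sel <- bin == as.integer(names(tMid))[b]
      simPct[r, b, ] <- quantile(ysim[sel], probs)
    }
  }
  alpha <- (1 - ci) / 2
  rows <- list()
  for (b in seq_along(tMid)) {
    sel <- bin == as.integer(names(tMid))[b]
    for (k in seq_along(probs)) {
      qs <- quantile(simPct[, b, k], c(alpha, 0.5, 1 - alpha))
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, t_mid_h = unname(tMid[b]), prob = probs[k],
        observed = unname(quantile(obsY[sel], probs[k])),
        sim_lo = unname(qs[1]), sim_med = unname(qs[2]),
        sim_hi = unname(qs[3]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "coverage") <-
    mean(out$observed >= out$sim_lo & out$observed <= out$sim_hi)
  out
}
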