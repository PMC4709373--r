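#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scalar ferritin turnover ODE
//   dF/dt = Kin + CRT(F) * m(t) - Kout * F * (1 + SLP * C(t))
// with CRT(F) = SCL_i * exp(-SHP_i * F) and disease-status scaling
//   SCL_i = SCL_ref * (B/F_med)^thScl, SHP_i = SHP_ref * (B/F_med)^thShp,
// where B is the current ferritin (state-dependent, default) or a fixed
// reference level (statusF > 0). C(t) (drug exposure, mg/L) and m(t)
// (occasion multiplier on CRT, e.g. exp(kappa)) are piecewise constant.
// Units: time h, ferritin ug/L.

struct FerritinModel {
  double kin, kout, sclRef, shpRef, thScl, thShp, fmed, slope, statusF;

  inline double rhs(double F, double expo, double crtMult) const {
    double Fb = F < 1e-6 ? 1e-6 : F;
    double base = statusF > 0.0 ? statusF : Fb;
    double r = base / fmed;
    double crt = 0.0;
    if (sclRef > 0.0 && crtMult != 0.0) {
      double scl = sclRef * std::pow(r, thScl);
      double shp = shpRef * std::pow(r, thShp);
      crt = crtMult * scl * std::exp(-shp * Fb);
    }
    return kin + crt - kout * F * (1.0 + slope * expo);
  }
};

// One embedded Cash-Karp RK4(5) step; returns 5th-order estimate, err = raw
// local error estimate.
static inline double ckStep(const FerritinModel& m, double F, double h,
                            double expo, double mult, double& err) {
  const double b21 = 0.2;
  const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
  const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
               b54 = 35.0 / 27.0;
  const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
               b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
               b65 = 253.0 / 4096.0;
  const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
               c6 = 512.0 / 1771.0;
  const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
               dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
               dc6 = c6 - 0.25;
  double k1 = m.rhs(F, expo, mult);
  double k2 = m.rhs(F + h * b21 * k1, expo, mult);
  double k3 = m.rhs(F + h * (b31 * k1 + b32 * k2), expo, mult);
  double k4 = m.rhs(F + h * (b41 * k1 + b42 * k2 + b43 * k3), expo, mult);
  double k5 = m.rhs(F + h * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4),
                    expo, mult);
  double k6 = m.rhs(F + h * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 +
                             b65 * k5), expo, mult);
  double F5 = F + h * (c1 * k1 + c3 * k3 + c4 * k4 + c6 * k6);
  err = h * (dc1 * k1 + dc3 * k3 + dc4 * k4 + dc5 * k5 + dc6 * k6);
  return F5;
}

// Integrate over [t0, t1] with constant forcing; F updated in place, h is
// the persisted trial step size.
static void integrateConst(const FerritinModel& m, double& F, double t0,
                           double t1, double expo, double mult, double rtol,
                           double atol, double& h) {
  double t = t0;
  double span = t1 - t0;
  if (span <= 0.0) return;
  if (!std::isfinite(F)) { F = NA_REAL; return; }
  if (h <= 0.0 || h > span) h = span;
  long steps = 0;
  while (t < t1 - 1e-9 * (1.0 + std::fabs(t1))) {
    double hh = h;
    if (hh > t1 - t) hh = t1 - t;
    double hmin = 1e-6 * (1.0 + std::fabs(t));
    double err;
    double Fn = ckStep(m, F, hh, expo, mult, err);
    if (!std::isfinite(Fn) || !std::isfinite(err)) {
      if (hh <= hmin) { F = NA_REAL; return; }  // hopeless: propagate NA
      h = hh * 0.1;
      continue;
    }
    double sc = atol + rtol * std::max(std::fabs(F), std::fabs(Fn));
    double e = std::fabs(err) / sc;
    if (e <= 1.0 || hh <= hmin) {
      t += hh;
      F = Fn < 0.0 ? 0.0 : Fn;
      double fac = e > 1e-12 ? 0.9 * std::pow(e, -0.2) : 5.0;
      h = hh * std::min(5.0, std::max(0.2, fac));
    } else {
      h = hh * std::max(0.1, 0.9 * std::pow(e, -0.25));
    }
    if (++steps > 5000000L)
      stop("ferritin integrator exceeded the step limit (t = %f h)", t);
  }
}

static inline int advanceIdx(const NumericVector& brk, double t, int idx) {
  int n = brk.size();
  while (idx + 1 < n && brk[idx + 1] <= t + 1e-9) ++idx;
  return idx;
}

static NumericVector trajCore(double f0, const NumericVector& times,
                              const NumericVector& expBreaks,
                              const NumericVector& expLevels,
                              const NumericVector& crtBreaks,
                              const NumericVector& crtLevels,
                              const FerritinModel& m, double rtol,
                              double atol) {
  int nt = times.size();
  NumericVector out(nt);
  double t = 0.0, F = f0, h = 0.0;
  int ie = 0, ic = 0;
  for (int it = 0; it < nt; ++it) {
    double target = times[it];
    while (t < target - 1e-9 * (1.0 + target)) {
      ie = advanceIdx(expBreaks, t, ie);
      ic = advanceIdx(crtBreaks, t, ic);
      double tnext = target;
      if (ie + 1 < expBreaks.size() && expBreaks[ie + 1] < tnext)
        tnext = expBreaks[ie + 1];
      if (ic + 1 < crtBreaks.size() && crtBreaks[ic + 1] < tnext)
        tnext = crtBreaks[ic + 1];
      integrateConst(m, F, t, tnext, expLevels[ie], crtLevels[ic], rtol,
                     atol, h);
      t = tnext;
      if (!std::isfinite(F)) {  // fill the rest with NA and stop
        for (int k = it; k < nt; ++k) out[k] = NA_REAL;
        return out;
      }
    }
    out[it] = F;
  }
  return out;
}

static FerritinModel makeModel(const NumericVector& pars, double slope,
                               double statusF) {
  if (pars.size() != 7) stop("pars must have length 7");
  FerritinModel m;
  m.kin = pars[0];
  m.kout = pars[1];
  m.sclRef = pars[2];
  m.shpRef = pars[3];
  m.thScl = pars[4];
  m.thShp = pars[5];
  m.fmed = pars[6];
  m.slope = slope;
  m.statusF = statusF;
  return m;
}

// pars = c(kin, kout, sclRef, shpRef, thetaScl, thetaShp, ferritinMed);
// statusF <= 0 means state-dependent disease-status scaling.
// [[Rcpp::export(name = ".ferritinTrajCpp")]]
NumericVector ferritin_traj_cpp(double f0, NumericVector times,
                                NumericVector expBreaks,
                                NumericVector expLevels,
                                NumericVector crtBreaks,
                                NumericVector crtLevels, NumericVector pars,
                                double slope, double statusF, double rtol,
                                double atol) {
  FerritinModel m = makeModel(pars, slope, statusF);
  return trajCore(f0, times, expBreaks, expLevels, crtBreaks, crtLevels, m,
                  rtol, atol);
}

// Individual predictions at observation times for random-effect vector b.
// Layout of b: [eta (if useEta)] then nOcc kappas (if nOcc > 0).
static NumericVector subjectPred(const NumericVector& b, bool useEta,
                                 int nOcc, const NumericVector& t,
                                 const NumericVector& occBreaks,
                                 double exposure, double f0,
                                 const NumericVector& pars, double slopeTv,
                                 double statusF, double rtol, double atol) {
  int off = useEta ? 1 : 0;
  double eta = useEta ? b[0] : 0.0;
  double slope_i = slopeTv * std::exp(eta);
  NumericVector crtBreaks, crtLevels;
  if (nOcc > 0) {
    crtBreaks = occBreaks;
    crtLevels = NumericVector(nOcc);
    for (int k = 0; k < nOcc; ++k) crtLevels[k] = std::exp(b[off + k]);
  } else {
    crtBreaks = NumericVector::create(0.0);
    crtLevels = NumericVector::create(1.0);
  }
  NumericVector expBreaks = NumericVector::create(0.0);
  NumericVector expLevels = NumericVector::create(exposure);
  FerritinModel m = makeModel(pars, slope_i, statusF);
  return trajCore(f0, t, expBreaks, expLevels, crtBreaks, crtLevels, m, rtol,
                  atol);
}

// Negative log joint density (observations + random-effect priors) for one
// subject; the inner objective of the Laplace approximation.
// [[Rcpp::export(name = ".subjectNllCpp")]]
double subject_nll_cpp(NumericVector b, bool useEta, int nOcc,
                       NumericVector y, NumericVector t,
                       NumericVector occBreaks, double exposure, double f0,
                       NumericVector pars, double slopeTv, double statusF,
                       double omega2Iiv, double omega2Iov, double sigma,
                       double rtol, double atol) {
  const double LOG2PI = 1.8378770664093453;
  // smooth barrier against absurd random effects: |b| = 6 is an e^6-fold
  // (400x) parameter change, > 8 prior SDs for every variance in play, and
  // keeps the ODE comfortably integrable when the optimiser's line search
  // overshoots
  double bnorm2 = 0.0;
  double bmax = 0.0;
  for (int i = 0; i < b.size(); ++i) {
    if (!std::isfinite(b[i])) return 1e10;
    bnorm2 += b[i] * b[i];
    if (std::fabs(b[i]) > bmax) bmax = std::fabs(b[i]);
  }
  if (bmax > 6.0) return 1e8 * (1.0 + bnorm2);
  NumericVector F = subjectPred(b, useEta, nOcc, t, occBreaks, exposure, f0,
                                pars, slopeTv, statusF, rtol, atol);
  double g = 0.0;
  int n = y.size();
  for (int j = 0; j < n; ++j) {
    double Fj = F[j];
    if (!std::isfinite(Fj) || Fj <= 0.0) return 1e9 * (1.0 + bnorm2);
    double v = sigma * Fj;
    double r = (y[j] - Fj) / v;
    g += 0.5 * r * r + std::log(v) + 0.5 * LOG2PI;
  }
  int off = useEta ? 1 : 0;
  if (useEta)
    g += 0.5 * b[0] * b[0] / omega2Iiv + 0.5 * std::log(omega2Iiv) +
         0.5 * LOG2PI;
  for (int k = 0; k < nOcc; ++k)
    g += 0.5 * b[off + k] * b[off + k] / omega2Iov +
         0.5 * std::log(omega2Iov) + 0.5 * LOG2PI;
  return g;
}

// Predictions and forward-difference Jacobian dF/db at b, for the
// Gauss-Newton curvature of the Laplace approximation.
// [[Rcpp::export(name = ".subjectGnCpp")]]
List subject_gn_cpp(NumericVector b, bool useEta, int nOcc, NumericVector t,
                    NumericVector occBreaks, double exposure, double f0,
                    NumericVector pars, double slopeTv, double statusF,
                    double rtol, double atol) {
  int d = b.size();
  int n = t.size();
  NumericVector F = subjectPred(b, useEta, nOcc, t, occBreaks, exposure, f0,
                                pars, slopeTv, statusF, rtol, atol);
  NumericMatrix J(n, d);
  for (int j = 0; j < d; ++j) {
    double hstep = 1e-5 * (1.0 + std::fabs(b[j]));
    NumericVector bp = clone(b);
    bp[j] += hstep;
    NumericVector Fp = subjectPred(bp, useEta, nOcc, t, occBreaks, exposure,
                                   f0, pars, slopeTv, statusF, rtol, atol);
    for (int i = 0; i < n; ++i) J(i, j) = (Fp[i] - F[i]) / hstep;
  }
  return List::create(_["F"] = F, _["J"] = J);
}
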