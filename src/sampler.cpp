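#include <Rcpp.h>
using namespace Rcpp;

// Adaptive random-walk Metropolis sampler for the three-context observer
// model.  The likelihood is evaluated on trials aggregated to binomial
// counts per (condition, stimulus) cell, so its cost is independent of the
// number of trials; this is what makes trial-by-trial online refits cheap.
//
// Parameter vector (length 12), all on unconstrained scales:
//   0  P_L   (tied mode) or B_L (untied mode)            [deg]
//   1  P_R   (tied)      or B_R (untied)                 [deg]
//   2  D     (tied)      or B_N (untied)                 [deg]
//   3..5   log S_L, log S_N, log S_R                     [log deg]
//   6..8   logit lambda1_{L,N,R}  (lower lapse)
//   9..11  logit lambda2_{L,N,R}  (upper lapse)
//
// Conditions are coded 0 = L, 1 = N, 2 = R throughout.

static const int NPAR = 12;

static inline double inv_logit(double x) {
  return R::plogis(x, 0.0, 1.0, 1, 0);
}

// Empirical bias of condition k given the current parameter vector.
static inline double bias_of(const double *x, int k, bool tied) {
  if (tied) {
    if (k == 0) return x[0] + x[2];      // B_L = P_L + D
    if (k == 1) return x[2];             // B_N = D
    return x[1] + x[2];                  // B_R = P_R + D
  } else {
    if (k == 0) return x[0];
    if (k == 1) return x[2];
    return x[1];
  }
}

// Binomial log likelihood restricted to one condition's cells.
static double cond_loglik(const double *x, int k, bool tied,
                          const std::vector<int> &cellCond,
                          const std::vector<double> &cellOm,
                          const std::vector<double> &cellN,
                          const std::vector<double> &cellR) {
  const double B = bias_of(x, k, tied);
  const double S = std::exp(x[3 + k]);
  const double l1 = inv_logit(x[6 + k]);
  const double l2 = inv_logit(x[9 + k]);
  const double span = 1.0 - l1 - l2;
  double ll = 0.0;
  for (size_t j = 0; j < cellCond.size(); ++j) {
    if (cellCond[j] != k) continue;
    double th = l1 + span * R::pnorm((cellOm[j] - B) / S, 0.0, 1.0, 1, 0);
    if (th < 1e-12) th = 1e-12;
    if (th > 1.0 - 1e-12) th = 1.0 - 1e-12;
    ll += cellR[j] * std::log(th) + (cellN[j] - cellR[j]) * std::log1p(-th);
  }
  return ll;
}

// Log prior contribution of parameter i, including the Jacobian of the
// transform to the unconstrained scale.
static double par_logprior(const double *x, int i,
                           const std::vector<double> &biasMean,
                           const std::vector<double> &biasSd,
                           bool biasFlat, double flatLo, double flatHi,
                           const std::vector<double> &gShape,
                           const std::vector<double> &gRate,
                           double betaA, double betaB) {
  if (i < 3) {
    if (biasFlat) {
      return (x[i] >= flatLo && x[i] <= flatHi) ? 0.0 : R_NegInf;
    }
    const double z = (x[i] - biasMean[i]) / biasSd[i];
    return -0.5 * z * z;
  }
  if (i < 6) {                       // log S_k, Gamma(shape, rate) on S
    const int k = i - 3;
    return gShape[k] * x[i] - gRate[k] * std::exp(x[i]);
  }
  // logit lambda, Beta(a, b) on lambda, Jacobian lambda (1 - lambda)
  const double lam = inv_logit(x[i]);
  return betaA * std::log(lam) + betaB * std::log1p(-lam);
}

// Conditions whose likelihood depends on parameter i.
static void affected_conds(int i, bool tied, int *out, int *nOut) {
  if (i == 2 && tied) {              // D enters every condition
    out[0] = 0; out[1] = 1; out[2] = 2; *nOut = 3;
    return;
  }
  int k;
  if (i == 0) k = 0;                 // P_L / B_L
  else if (i == 1) k = 2;            // P_R / B_R
  else if (i == 2) k = 1;            // B_N (untied)
  else k = (i - 3) % 3;              // S, lambda blocks are ordered L,N,R
  out[0] = k; *nOut = 1;
}

// [[Rcpp::export]]
List mh_psychofit(IntegerVector cond, NumericVector omega,
                  NumericVector n_tot, NumericVector n_right,
                  List prior, bool tied,
                  int n_draws, int burn_in,
                  NumericVector init, NumericVector scales,
                  LogicalVector fixed, bool adapt) {
  if (init.size() != NPAR || scales.size() != NPAR || fixed.size() != NPAR)
    stop("init, scales and fixed must have length 12");
  if (burn_in < 0 || burn_in >= n_draws)
    stop("need 0 <= burn_in < n_draws");

  const size_t ncell = cond.size();
  std::vector<int> cellCond(ncell);
  std::vector<double> cellOm(ncell), cellN(ncell), cellR(ncell);
  for (size_t j = 0; j < ncell; ++j) {
    cellCond[j] = cond[j];
    cellOm[j] = omega[j];
    cellN[j] = n_tot[j];
    cellR[j] = n_right[j];
  }

  std::vector<double> biasMean = as<std::vector<double> >(prior["bias_mean"]);
  std::vector<double> biasSd   = as<std::vector<double> >(prior["bias_sd"]);
  bool biasFlat = as<bool>(prior["bias_flat"]);
  double flatLo = as<double>(prior["flat_lo"]);
  double flatHi = as<double>(prior["flat_hi"]);
  std::vector<double> gShape = as<std::vector<double> >(prior["gamma_shape"]);
  std::vector<double> gRate  = as<std::vector<double> >(prior["gamma_rate"]);
  double betaA = as<double>(prior["beta_a"]);
  double betaB = as<double>(prior["beta_b"]);

  double x[NPAR];
  double lsc[NPAR];
  for (int i = 0; i < NPAR; ++i) {
    x[i] = init[i];
    lsc[i] = std::log(scales[i]);
  }

  // cached per-condition log likelihoods and per-parameter log priors
  double cll[3];
  for (int k = 0; k < 3; ++k)
    cll[k] = cond_loglik(x, k, tied, cellCond, cellOm, cellN, cellR);
  double lpr[NPAR];
  for (int i = 0; i < NPAR; ++i)
    lpr[i] = par_logprior(x, i, biasMean, biasSd, biasFlat, flatLo, flatHi,
                          gShape, gRate, betaA, betaB);

  const int n_keep = n_draws - burn_in;
  NumericMatrix draws(n_keep, NPAR);
  NumericVector accCount(NPAR), propCount(NPAR);
  const double target = 0.44;

  RNGScope scope;
  int affected[3], nAff;

  for (int it = 0; it < n_draws; ++it) {
    for (int i = 0; i < NPAR; ++i) {
      if (fixed[i]) continue;
      propCount[i] += 1.0;
      const double oldVal = x[i];
      const double cand = oldVal + std::exp(lsc[i]) * R::norm_rand();
      x[i] = cand;
      const double lprNew = par_logprior(x, i, biasMean, biasSd, biasFlat,
                                         flatLo, flatHi, gShape, gRate,
                                         betaA, betaB);
      double logAlpha = lprNew - lpr[i];
      double newCll[3];
      affected_conds(i, tied, affected, &nAff);
      if (R_finite(logAlpha)) {
        for (int a = 0; a < nAff; ++a) {
          const int k = affected[a];
          newCll[a] = cond_loglik(x, k, tied, cellCond, cellOm, cellN, cellR);
          logAlpha += newCll[a] - cll[k];
        }
      }
      bool accepted = R_finite(logAlpha) &&
        (logAlpha >= 0.0 || std::log(R::unif_rand()) < logAlpha);
      if (accepted) {
        lpr[i] = lprNew;
        for (int a = 0; a < nAff; ++a) cll[affected[a]] = newCll[a];
        accCount[i] += 1.0;
      } else {
        x[i] = oldVal;
      }
      if (adapt && it < burn_in) {
        const double gamma = std::pow((double)(it + 1), -0.6);
        lsc[i] += gamma * ((accepted ? 1.0 : 0.0) - target);
        if (lsc[i] < -10.0) lsc[i] = -10.0;
        if (lsc[i] > 5.0) lsc[i] = 5.0;
      }
    }
    if (it >= burn_in) {
      for (int i = 0; i < NPAR; ++i) draws(it - burn_in, i) = x[i];
    }
  }

  NumericVector finalX(NPAR), finalScales(NPAR), accRate(NPAR);
  for (int i = 0; i < NPAR; ++i) {
    finalX[i] = x[i];
    finalScales[i] = std::exp(lsc[i]);
    accRate[i] = propCount[i] > 0 ? accCount[i] / propCount[i] : NA_REAL;
  }
  return List::create(_["draws"] = draws,
                      _["final_x"] = finalX,
                      _["final_scales"] = finalScales,
                      _["accept_rate"] = accRate);
}
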