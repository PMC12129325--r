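#include <Rcpp.h>
using namespace Rcpp;

// One session of the criterion-learning agent.  The agent perceives the
// stimulus with a context-dependent perceptual bias and Gaussian internal
// noise, chooses by MAP relative to its decision criterion, receives a
// reward according to the requested strategy, and nudges the criterion by
// the sign-simplified temporal-difference rule
//   psi_t = psi_{t-1} - alpha * C * (r - q),
// with q = max(thetahat, 1 - thetahat) computed from the pre-update
// criterion.
//
// Strategies: 0 veridical, 1 random-in-ambiguous, 2 always-in-ambiguous,
// 3 never-in-ambiguous, 4 oracle (ground-truth boundary), 5 external
// per-trial boundary (used for the estimated-bias reward method).
// Conditions coded 0 = L, 1 = N, 2 = R; choices -1 = left, +1 = right.
// Ties (perceived value equal to criterion, or stimulus equal to the
// boundary) resolve to rightward choice / reward granted.

// [[Rcpp::export]]
List rl_session(NumericVector omega, IntegerVector cond,
                NumericMatrix Ptrue, NumericVector psi0,
                double alpha, NumericVector Sigma,
                int strategy, NumericVector boundary_in,
                double random_prob, bool shared) {
  const int n = omega.size();
  if (cond.size() != n || Ptrue.nrow() != n)
    stop("omega, cond and Ptrue must agree in length");
  NumericVector psi = clone(psi0);
  IntegerVector choice(n);
  IntegerVector reward(n);
  NumericVector boundary_used(n);
  NumericMatrix psiTrace(n, 3);

  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    const int k = cond[t];
    const double om = omega[t];
    const double P = Ptrue(t, k);
    const double psi_k = shared ? psi[0] : psi[k];

    const double om_hat = R::rnorm(om - P, Sigma[k]);
    const int C = (om_hat >= psi_k) ? 1 : -1;

    // reward boundary in stimulus coordinates
    double b = 0.0;
    bool amb = false;
    if (k != 1) {
      const double lo = std::min(0.0, P);
      const double hi = std::max(0.0, P);
      amb = (om >= lo && om <= hi);
    }
    switch (strategy) {
    case 0: b = 0.0; break;
    case 1: case 2: case 3: b = 0.0; break;       // veridical outside band
    case 4: b = (k == 1) ? 0.0 : P; break;
    case 5: b = boundary_in[t]; break;
    default: stop("unknown strategy code");
    }

    int r;
    if (amb && strategy == 1) {
      r = (R::unif_rand() < random_prob) ? 1 : 0;
    } else if (amb && strategy == 2) {
      r = 1;
    } else if (amb && strategy == 3) {
      r = 0;
    } else {
      r = ((C == -1 && om < b) || (C == 1 && om > b) || om == b) ? 1 : 0;
    }

    const double theta = R::pnorm((om_hat - psi_k) / Sigma[k], 0.0, 1.0, 1, 0);
    const double q = std::max(theta, 1.0 - theta);
    const double psi_new = psi_k - alpha * C * (r - q);
    if (shared) {
      psi[0] = psi[1] = psi[2] = psi_new;
    } else {
      psi[k] = psi_new;
    }

    choice[t] = C;
    reward[t] = r;
    boundary_used[t] = b;
    psiTrace(t, 0) = psi[0];
    psiTrace(t, 1) = psi[1];
    psiTrace(t, 2) = psi[2];
  }

  return List::create(_["choice"] = choice, _["reward"] = reward,
                      _["boundary"] = boundary_used,
                      _["psi"] = psiTrace, _["psi_end"] = psi);
}
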