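#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time kinetic Monte Carlo over single-site flips of a two-state
// lattice. Metropolis-style barriers: k = k0 * exp(-(max(dE,0) + lock)/RT),
// where the lock barrier applies only to moves taking a locked site out of
// the untransformed (0) conformation.
//
// The trigger field can switch on per site at actTime[i] (instantaneous
// trigger binding corresponds to all actTime equal to the global switch-on
// time). Energy terms:
//   E = J * (# discordant adjacent pairs)
//       - sum_i h[i] * s_i * [t >= actTime[i]]          (h = 0 off-trigger)
//       + sum_i strain[i] * s_i * [t >= fieldOnTime]
// Rates are recomputed from scratch each step; lattices here are tiny.
//
// [[Rcpp::export(name = ".kmc_run")]]
List kmc_run(IntegerMatrix nbr,        // nSites x maxDeg, 0-based, -1 padded
             NumericVector h,          // per-site trigger stabilization
             NumericVector actTime,    // per-site field activation time
             NumericVector strain,     // per-site strain term
             double fieldOnTime,
             NumericVector lockBar,    // per-site U->T barrier
             double J, double k0, double RT,
             double duration,
             int maxEvents,
             bool stopWhenComplete) {
  const int n = nbr.nrow();
  const int maxDeg = nbr.ncol();
  std::vector<int> s(n, 0);
  std::vector<double> evTime;
  std::vector<int> evSite, evState;

  // future times at which rates change discontinuously
  std::vector<double> switches;
  switches.push_back(fieldOnTime);
  for (int i = 0; i < n; ++i) switches.push_back(actTime[i]);
  std::sort(switches.begin(), switches.end());
  switches.erase(std::unique(switches.begin(), switches.end()),
                 switches.end());

  double t = 0.0;
  size_t swIdx = 0;
  while (swIdx < switches.size() && switches[swIdx] <= t) ++swIdx;

  std::vector<double> rate(n);
  int nEvents = 0;
  bool complete = false;

  while (t < duration && nEvents < maxEvents) {
    // rates for flipping each site at current time t
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      int d = 0, deg = 0;
      for (int k = 0; k < maxDeg; ++k) {
        int j = nbr(i, k);
        if (j < 0) break;
        ++deg;
        if (s[j] != s[i]) ++d;
      }
      double dE = J * (deg - 2 * d);
      double sign = (s[i] == 0) ? 1.0 : -1.0; // flipping to 1 adds field terms
      if (t >= actTime[i]) dE += -h[i] * sign;
      if (t >= fieldOnTime) dE += strain[i] * sign;
      double barrier = (dE > 0 ? dE : 0.0) + (s[i] == 0 ? lockBar[i] : 0.0);
      if (!R_finite(barrier))
        stop("non-finite activation barrier encountered");
      rate[i] = k0 * std::exp(-barrier / RT);
      total += rate[i];
    }
    if (total <= 0.0) break;

    double dt = R::exp_rand() / total;
    double tNext = t + dt;

    // rate set changes at the next field switch: advance clock, redraw
    if (swIdx < switches.size() && tNext >= switches[swIdx] &&
        switches[swIdx] < duration) {
      t = switches[swIdx];
      ++swIdx;
      continue;
    }
    if (tNext >= duration) { t = duration; break; }

    double u = unif_rand() * total, acc = 0.0;
    int pick = n - 1;
    for (int i = 0; i < n; ++i) {
      acc += rate[i];
      if (u <= acc) { pick = i; break; }
    }
    t = tNext;
    s[pick] = 1 - s[pick];
    evTime.push_back(t);
    evSite.push_back(pick);
    evState.push_back(s[pick]);
    ++nEvents;

    if (stopWhenComplete) {
      complete = true;
      for (int i = 0; i < n; ++i)
        if (s[i] == 0) { complete = false; break; }
      if (complete) break;
    }
  }

  return List::create(
    _["time"] = wrap(evTime),
    _["site"] = wrap(evSite),   // 0-based; R side converts
    _["state"] = wrap(evState),
    _["final"] = wrap(s),
    _["tEnd"] = t,
    _["completed"] = complete);
}

// Viterbi decoding for a 2-state Gaussian-emission HMM (log space).
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericVector x,
                          NumericVector logPi,   // length 2
                          NumericMatrix logA,    // 2 x 2
                          NumericVector mu, NumericVector sigma) {
  const int n = x.size();
  IntegerVector path(n);
  if (n == 0) return path;
  NumericMatrix delta(n, 2);
  IntegerMatrix psi(n, 2);
  for (int j = 0; j < 2; ++j)
    delta(0, j) = logPi[j] + R::dnorm(x[0], mu[j], sigma[j], 1);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < 2; ++j) {
      double b = R::dnorm(x[t], mu[j], sigma[j], 1);
      double v0 = delta(t - 1, 0) + logA(0, j);
      double v1 = delta(t - 1, 1) + logA(1, j);
      if (v0 >= v1) { delta(t, j) = v0 + b; psi(t, j) = 0; }
      else          { delta(t, j) = v1 + b; psi(t, j) = 1; }
    }
  }
  int last = (delta(n - 1, 0) >= delta(n - 1, 1)) ? 0 : 1;
  path[n - 1] = last + 1;
  for (int t = n - 1; t > 0; --t) {
    last = psi(t, last);
    path[t - 1] = last + 1;
  }
  return path;
}

// One forward-backward pass (scaled) for a 2-state Gaussian HMM.
// Returns loglik, state posteriors gamma, and summed transition counts xi.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(NumericVector x,
                          NumericVector pi0,
                          NumericMatrix A,
                          NumericVector mu, NumericVector sigma) {
  const int n = x.size();
  NumericMatrix B(n, 2), alpha(n, 2), beta(n, 2), gamma(n, 2);
  NumericVector c(n);
  for (int t = 0; t < n; ++t)
    for (int j = 0; j < 2; ++j)
      B(t, j) = R::dnorm(x[t], mu[j], sigma[j], 0) + 1e-300;

  alpha(0, 0) = pi0[0] * B(0, 0);
  alpha(0, 1) = pi0[1] * B(0, 1);
  c[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= c[0]; alpha(0, 1) /= c[0];
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < 2; ++j)
      alpha(t, j) = (alpha(t - 1, 0) * A(0, j) +
                     alpha(t - 1, 1) * A(1, j)) * B(t, j);
    c[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= c[t]; alpha(t, 1) /= c[t];
  }
  beta(n - 1, 0) = 1.0; beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < 2; ++i)
      beta(t, i) = (A(i, 0) * B(t + 1, 0) * beta(t + 1, 0) +
                    A(i, 1) * B(t + 1, 1) * beta(t + 1, 1)) / c[t + 1];
  }
  double ll = 0.0;
  for (int t = 0; t < n; ++t) ll += std::log(c[t]);
  for (int t = 0; t < n; ++t) {
    double z = alpha(t, 0) * beta(t, 0) + alpha(t, 1) * beta(t, 1);
    gamma(t, 0) = alpha(t, 0) * beta(t, 0) / z;
    gamma(t, 1) = alpha(t, 1) * beta(t, 1) / z;
  }
  NumericMatrix xi(2, 2);
  for (int t = 0; t < n - 1; ++t) {
    double z = 0.0;
    double tmp[2][2];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        tmp[i][j] = alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j) /
                    c[t + 1];
        z += tmp[i][j];
      }
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        xi(i, j) += tmp[i][j] / z;
  }
  return List::create(_["logLik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}
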