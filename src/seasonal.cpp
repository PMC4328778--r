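// Fast evaluation and sampling for the two-season (off/in-season)
// piecewise-constant hazard model without covariates, the model used by the
// simulation studies.  The joint log-likelihood is a function of summed
// exposures only, precomputed in R (build_seasonal_design), so each
// evaluation is a short loop over death intervals and never-seen-again
// tails.  The sampler uses R's RNG, so results are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double log1m_exp(double H) {
  // log(1 - exp(-H)) for H > 0
  if (H <= 0.0) return R_NegInf;
  if (H <= M_LN2) return std::log(-std::expm1(-H));
  return std::log1p(-std::exp(-H));
}

static double seasonal_loglik(double l1, double l2, double p,
                              double SE1, double SE2,
                              const NumericVector& dD1,
                              const NumericVector& dD2,
                              double nn, double navail,
                              const IntegerVector& tail_ptr,
                              const NumericVector& tail_d1,
                              const NumericVector& tail_d2) {
  double ll = -(l1 * SE1 + l2 * SE2);
  const int ndead = dD1.size();
  for (int i = 0; i < ndead; ++i) {
    ll += log1m_exp(l1 * dD1[i] + l2 * dD2[i]);
  }
  if (nn > 0.0) {
    if (p <= 0.0) return R_NegInf;
    ll += nn * std::log(p);
  }
  if (navail - nn > 0.0) {
    if (p >= 1.0) return R_NegInf;
    ll += (navail - nn) * std::log1p(-p);
  }
  const double q = 1.0 - p;
  const int n2 = tail_ptr.size() - 1;
  for (int j = 0; j < n2; ++j) {
    double surv = 1.0, qk = 1.0, tail = 0.0;
    for (int k = tail_ptr[j]; k < tail_ptr[j + 1]; ++k) {
      double s2 = surv * std::exp(-(l1 * tail_d1[k] + l2 * tail_d2[k]));
      tail += (surv - s2) * qk;
      surv = s2;
      qk *= q;
    }
    tail += surv * qk;
    ll += std::log(std::max(tail, 1e-300));
  }
  return ll;
}

// [[Rcpp::export(name = ".loglik_seasonal_cpp")]]
double loglik_seasonal_cpp(double lambda1, double lambda2, double p,
                           List design) {
  return seasonal_loglik(lambda1, lambda2, p,
                         as<double>(design["SE1"]), as<double>(design["SE2"]),
                         design["dD1"], design["dD2"],
                         as<double>(design["nn"]), as<double>(design["navail"]),
                         design["tail_ptr"], design["tail_d1"],
                         design["tail_d2"]);
}

// Componentwise adaptive random-walk Metropolis on
// (log lambda1, log lambda2, p) with uniform priors on the log rates and a
// uniform(0,1) prior on p.  Adaptation runs during burn-in only.
// [[Rcpp::export(name = ".sample_seasonal_cpp")]]
List sample_seasonal_cpp(List design, int n_iter, int burn_in,
                         NumericVector init, double lo, double hi,
                         double target_accept, double step0) {
  const double SE1 = as<double>(design["SE1"]);
  const double SE2 = as<double>(design["SE2"]);
  const NumericVector dD1 = design["dD1"], dD2 = design["dD2"];
  const double nn = as<double>(design["nn"]);
  const double navail = as<double>(design["navail"]);
  const IntegerVector tail_ptr = design["tail_ptr"];
  const NumericVector tail_d1 = design["tail_d1"], tail_d2 = design["tail_d2"];

  double th[3] = { init[0], init[1], init[2] };  // log l1, log l2, p
  double ll = seasonal_loglik(std::exp(th[0]), std::exp(th[1]), th[2],
                              SE1, SE2, dD1, dD2, nn, navail,
                              tail_ptr, tail_d1, tail_d2);
  if (!R_FINITE(ll)) stop("log-posterior not finite at the initial point");

  const int n_keep = n_iter - burn_in;
  NumericMatrix draws(n_keep, 3);
  double log_step[3] = { std::log(step0), std::log(step0), std::log(step0) };
  double acc_post[3] = { 0.0, 0.0, 0.0 };

  GetRNGstate();
  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = iter <= burn_in;
    const double gam = adapting ? std::min(0.25, 2.0 / std::sqrt((double)iter))
                                : 0.0;
    for (int c = 0; c < 3; ++c) {
      double prop = th[c] + std::exp(log_step[c]) * norm_rand();
      bool ok = (c == 2) ? (prop > 0.0 && prop < 1.0)
                         : (prop >= lo && prop <= hi);
      bool acc = false;
      if (ok) {
        double cand[3] = { th[0], th[1], th[2] };
        cand[c] = prop;
        double llp = seasonal_loglik(std::exp(cand[0]), std::exp(cand[1]),
                                     cand[2], SE1, SE2, dD1, dD2, nn, navail,
                                     tail_ptr, tail_d1, tail_d2);
        if (R_FINITE(llp) && std::log(unif_rand()) < llp - ll) {
          th[c] = prop;
          ll = llp;
          acc = true;
        }
      }
      if (adapting)
        log_step[c] += gam * ((acc ? 1.0 : 0.0) - target_accept);
      else if (acc)
        acc_post[c] += 1.0;
    }
    if (iter > burn_in) {
      const int k = iter - burn_in - 1;
      draws(k, 0) = std::exp(th[0]);
      draws(k, 1) = std::exp(th[1]);
      draws(k, 2) = th[2];
    }
  }
  PutRNGstate();

  NumericVector accept(3);
  for (int c = 0; c < 3; ++c) accept[c] = acc_post[c] / n_keep;
  return List::create(_["draws"] = draws, _["accept"] = accept);
}
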