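#include <Rcpp.h>
using namespace Rcpp;

// Shared recursion for models 2-5 in presentation order.
//
// E[t]   initial (regression-based) feedback expectation for the trait at
//        position t, already clipped to [1, 100]
// simt   T x T similarity between the traits at positions i and t
// gamma  self-weight; 0 recovers the pure fine-granularity models 2/3
// PE(t) = F(t) - P(t) with P the emitted prediction (pe_mixed = true) or
//        the feedback-based accumulator Pm (pe_mixed = false)
// Missed trials contribute no PE and are skipped in the likelihood.
//
// Dual-rate weighting: alpha_plus when |F - S| <= |P - S| (feedback reduces
// self-role dissonance; ties take the plus rate), alpha_minus otherwise.

static inline double weight_for(double F, double S, double P,
                                double a_plus, double a_minus) {
  return (std::abs(F - S) <= std::abs(P - S)) ? a_plus : a_minus;
}

// [[Rcpp::export]]
List traj_core(NumericVector E, NumericVector S, NumericVector F,
               NumericMatrix simt, double alpha_plus, double alpha_minus,
               double gamma, bool pe_mixed, LogicalVector miss) {
  const int T = E.size();
  NumericVector P(T), Pm(T), PE(T);
  std::vector<double> wpe(T, 0.0);
  for (int t = 0; t < T; ++t) {
    double acc = 0.0;
    for (int i = 0; i < t; ++i) acc += wpe[i] * simt(i, t);
    const double pm = E[t] + acc;
    const double p  = gamma * S[t] + (1.0 - gamma) * pm;
    Pm[t] = pm;
    P[t]  = p;
    if (miss[t]) {
      PE[t] = NA_REAL;
      continue;
    }
    const double pe = F[t] - (pe_mixed ? p : pm);
    PE[t] = pe;
    wpe[t] = weight_for(F[t], S[t], p, alpha_plus, alpha_minus) * pe;
  }
  return List::create(_["P"] = P, _["Pm"] = Pm, _["PE"] = PE);
}

// Negative Gaussian log-likelihood of the observed role ratings around the
// emitted predictions; the expectation E(t) is rebuilt from the per-position
// OLS coefficients (a, b) and the free first-trait expectation E1 so the
// whole objective is one call per optimizer evaluation.
// [[Rcpp::export]]
double negll_core(NumericVector a, NumericVector b, double E1,
                  NumericVector S, NumericVector F, NumericMatrix simt,
                  NumericVector Pobs, double alpha_plus, double alpha_minus,
                  double gamma, bool pe_mixed, double sigma,
                  LogicalVector miss) {
  const int T = S.size();
  const double LOG2PI = 1.837877066409345483560659472811;
  std::vector<double> wpe(T, 0.0);
  double nll = 0.0;
  for (int t = 0; t < T; ++t) {
    double e = a[t] + b[t] * E1;
    if (e < 1.0) e = 1.0; else if (e > 100.0) e = 100.0;
    double acc = 0.0;
    for (int i = 0; i < t; ++i) acc += wpe[i] * simt(i, t);
    const double pm = e + acc;
    const double p  = gamma * S[t] + (1.0 - gamma) * pm;
    if (miss[t]) continue;
    const double pe = F[t] - (pe_mixed ? p : pm);
    wpe[t] = weight_for(F[t], S[t], p, alpha_plus, alpha_minus) * pe;
    const double z = (Pobs[t] - p) / sigma;
    nll += 0.5 * (z * z + LOG2PI) + std::log(sigma);
  }
  return nll;
}

// Squared error between emitted predictions and the feedback itself: the
// objective of the feedback-optimal ("learning-optimal") control fit.
// [[Rcpp::export]]
double feedback_sse_core(NumericVector a, NumericVector b, double E1,
                         NumericVector S, NumericVector F, NumericMatrix simt,
                         double alpha_plus, double alpha_minus, double gamma,
                         bool pe_mixed, LogicalVector miss) {
  const int T = S.size();
  std::vector<double> wpe(T, 0.0);
  double sse = 0.0;
  for (int t = 0; t < T; ++t) {
    double e = a[t] + b[t] * E1;
    if (e < 1.0) e = 1.0; else if (e > 100.0) e = 100.0;
    double acc = 0.0;
    for (int i = 0; i < t; ++i) acc += wpe[i] * simt(i, t);
    const double pm = e + acc;
    const double p  = gamma * S[t] + (1.0 - gamma) * pm;
    if (miss[t]) continue;
    const double pe = F[t] - (pe_mixed ? p : pm);
    wpe[t] = weight_for(F[t], S[t], p, alpha_plus, alpha_minus) * pe;
    const double r = p - F[t];
    sse += r * r;
  }
  return sse;
}
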