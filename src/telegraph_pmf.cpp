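#include <Rcpp.h>
using namespace Rcpp;

// Steady-state copy-number pmf of the telegraph model, evaluated stably.
//
// With a = lam/d, b = (lam+gam)/d, r = rho/d the standard confluent
// hypergeometric form is
//   P_n = r^n/n! * (a)_n/(b)_n * 1F1(a+n; b+n; -r).
// Direct evaluation of 1F1 at a negative argument suffers catastrophic
// cancellation, so we apply Kummer's transformation
//   1F1(a+n; b+n; -r) = exp(-r) * 1F1(b-a; b+n; r),
// whose series has all non-negative terms (b-a = gam/d >= 0 and the term
// ratio (c+k)/(b+n+k) <= 1 keeps the sum within [1, exp(r)]), so after the
// exp(-r) prefactor every quantity stays in [0, 1] and no overflow occurs.

// [[Rcpp::export]]
NumericVector cpp_telegraph_pmf(double lam, double gam, double rho, double d,
                                int nmax) {
  NumericVector out(nmax + 1);
  if (rho <= 0.0 || lam <= 0.0) { // no synthesis, or gene never activates
    out[0] = 1.0;
    return out;
  }
  double a = lam / d, b = (lam + gam) / d, r = rho / d, c = gam / d;
  int kmax = (int) std::ceil(r + 12.0 * std::sqrt(r) + 30.0);
  for (int n = 0; n <= nmax; ++n) {
    // log prefactor: -r + n log r - log n! + log (a)_n - log (b)_n
    double lp = -r + n * std::log(r) - std::lgamma((double) n + 1.0)
      + std::lgamma(a + n) - std::lgamma(a)
      - (std::lgamma(b + n) - std::lgamma(b));
    // series 1F1(c; b+n; r), all terms >= 0; rescale periodically so the
    // partial sums (up to ~exp(r)) cannot overflow before the exp(-r)
    // prefactor is applied
    double term = 1.0, sum = 1.0, log_scale = 0.0;
    for (int k = 1; k <= kmax; ++k) {
      term *= (c + k - 1.0) / (b + n + k - 1.0) * r / k;
      sum += term;
      if (sum > 1e280) {
        sum *= 1e-280;
        term *= 1e-280;
        log_scale += 280.0 * M_LN10;
      }
      if (k > r && term < 1e-16 * sum) break;
    }
    out[n] = std::exp(lp + std::log(sum) + log_scale);
  }
  return out;
}

// Log-likelihood of tabulated counts under the telegraph pmf:
// tab[n+1] = number of cells with count n. Hot path of the MLE fit.
// [[Rcpp::export]]
double cpp_telegraph_loglik(NumericVector tab, double lam, double gam,
                            double rho, double d) {
  int nmax = tab.size() - 1;
  NumericVector p = cpp_telegraph_pmf(lam, gam, rho, d, nmax);
  double ll = 0.0;
  for (int n = 0; n <= nmax; ++n) {
    if (tab[n] > 0) {
      double pn = p[n] > 1e-300 ? p[n] : 1e-300;
      ll += tab[n] * std::log(pn);
    }
  }
  return ll;
}
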