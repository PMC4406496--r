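#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Auto-mutual information curves over lags 0..tau_max for a quantized
// symbol sequence, for a battery of entropy orders in one pass.
// q == 1 selects the Shannon estimator; otherwise the Renyi-q form
//   1/(q-1) * log2( sum_ij P_ij^q / (P_i^(q-1) P_j^(q-1)) )
// summed over cells with nonzero joint probability.  Marginals are the
// row/column sums of the joint table at each lag.
// [[Rcpp::export]]
NumericMatrix amif_all_cpp(IntegerVector sym, int nbins, int tau_max,
                           NumericVector qs) {
  const int n = sym.size();
  const int nq = qs.size();
  if (tau_max >= n) stop("tau_max must be smaller than the series length");
  NumericMatrix out(tau_max + 1, nq);
  std::vector<int> joint(nbins * nbins);
  std::vector<double> px(nbins), py(nbins);
  const double log2e = 1.0 / std::log(2.0);

  for (int tau = 0; tau <= tau_max; ++tau) {
    const int npair = n - tau;
    std::fill(joint.begin(), joint.end(), 0);
    for (int i = 0; i < npair; ++i) {
      joint[sym[i] * nbins + sym[i + tau]] += 1;
    }
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(py.begin(), py.end(), 0.0);
    const double inv = 1.0 / npair;
    for (int a = 0; a < nbins; ++a) {
      for (int b = 0; b < nbins; ++b) {
        const double p = joint[a * nbins + b] * inv;
        px[a] += p;
        py[b] += p;
      }
    }
    for (int k = 0; k < nq; ++k) {
      const double q = qs[k];
      if (q == 1.0) {
        double mi = 0.0;
        for (int a = 0; a < nbins; ++a) {
          if (px[a] <= 0.0) continue;
          for (int b = 0; b < nbins; ++b) {
            const double p = joint[a * nbins + b] * inv;
            if (p > 0.0) {
              mi += p * std::log(p / (px[a] * py[b])) * log2e;
            }
          }
        }
        out(tau, k) = mi;
      } else {
        // log-sum-exp: cell terms span hundreds of orders of magnitude
        // for extreme q, far beyond double range
        double lmax = -std::numeric_limits<double>::infinity();
        std::vector<double> lterms;
        lterms.reserve(nbins * nbins);
        for (int a = 0; a < nbins; ++a) {
          if (px[a] <= 0.0) continue;
          const double lpx = std::log(px[a]);
          for (int b = 0; b < nbins; ++b) {
            const double p = joint[a * nbins + b] * inv;
            if (p > 0.0) {
              const double lt = q * std::log(p) -
                (q - 1.0) * (lpx + std::log(py[b]));
              lterms.push_back(lt);
              if (lt > lmax) lmax = lt;
            }
          }
        }
        double s = 0.0;
        for (double lt : lterms) s += std::exp(lt - lmax);
        out(tau, k) = (lmax + std::log(s)) * log2e / (q - 1.0);
      }
    }
  }
  return out;
}
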