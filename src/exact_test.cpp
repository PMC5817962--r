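#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-sided sum-conditioned NB exact test, one gene at a time.
//
// Conditional on the total s = a + b, the first group's sum follows a
// beta-binomial law with parameters (n1 / phi, n2 / phi); partition
// probabilities are accumulated on the log scale through the pmf ratio
//   p(a) / p(a - 1) = ((a - 1 + r1)(s - a + 1)) / (a (s - a + r2)),
// which degenerates to the Binomial(s, n1 / (n1 + n2)) ratio in the
// Poisson limit phi -> 0. The two-sided p-value is the normalized mass of
// all partitions whose probability is at most (1 + tie_tol) times the
// observed one.
// [[Rcpp::export(name = ".exact_nb_pvalue_cpp")]]
NumericVector exact_nb_pvalue_cpp(NumericVector a, NumericVector s,
                                  double n1, double n2, NumericVector phi,
                                  double tie_tol) {
  const R_xlen_t G = s.size();
  NumericVector p(G);
  double max_s = 0.0;
  for (R_xlen_t g = 0; g < G; g++) if (s[g] > max_s) max_s = s[g];
  std::vector<double> logq((size_t) max_s + 1);
  const double ltol = std::log1p(tie_tol);

  for (R_xlen_t g = 0; g < G; g++) {
    const long S = (long) s[g];
    if (S <= 0) { p[g] = 1.0; continue; }
    const double sd = s[g];
    const double phig = phi[g];
    const bool pois = phig < 1e-8;
    const double r1 = n1 / phig;
    const double r2 = n2 / phig;
    double lq = 0.0, maxlq = 0.0;
    logq[0] = 0.0;
    for (long aa = 1; aa <= S; aa++) {
      double lr;
      if (pois) {
        lr = std::log((n1 * (sd - aa + 1)) / (n2 * aa));
      } else {
        lr = std::log(((aa - 1 + r1) * (sd - aa + 1)) /
                      (aa * (sd - aa + r2)));
      }
      lq += lr;
      logq[aa] = lq;
      if (lq > maxlq) maxlq = lq;
    }
    const double thr = logq[(long) a[g]] + ltol;
    double num = 0.0, den = 0.0;
    for (long aa = 0; aa <= S; aa++) {
      const double q = std::exp(logq[aa] - maxlq);
      den += q;
      if (logq[aa] <= thr) num += q;
    }
    p[g] = (num < den) ? num / den : 1.0;
    if ((g & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return p;
}
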