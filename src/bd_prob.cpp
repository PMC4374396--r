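#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Linear birth-death transition probabilities.
//
// Each gene copy independently duplicates at rate lambda and dies at
// rate mu; state 0 is absorbing (no immigration). A single lineage
// after time t leaves a modified-geometric number of descendants:
//   P(0) = alpha,  P(c >= 1) = (1-alpha) (1-beta) beta^{c-1}
// with
//   alpha = mu (e^{(lambda-mu)t} - 1) / (lambda e^{(lambda-mu)t} - mu)
//   beta  = (lambda/mu) alpha ,
// both reducing to lambda t / (1 + lambda t) when lambda == mu.
// Starting from s independent copies, the transition law is the s-fold
// convolution of that single-lineage law. Computing rows by repeated
// convolution keeps every term non-negative, so the result is accurate
// to machine precision for any rate/time combination — unlike the
// closed-form alternating sum in binomial coefficients, which cancels
// catastrophically once alpha + beta > 1. Truncation at cmax is exact
// for the retained entries: P[s, c] with c <= cmax never involves
// states above cmax.
//
// alpha, beta and their complements are evaluated through expm1 and
// the cancellation-free identities 1 - alpha = r e^{rt} / denom,
// 1 - beta = r / denom (r = lambda - mu, denom = lambda e^{rt} - mu).

struct BDSingle {
  double alpha, beta, oma, omb; // alpha, beta, 1-alpha, 1-beta
};

static BDSingle bd_single(double t, double lambda, double mu) {
  BDSingle x;
  if (t <= 0.0 || (lambda == 0.0 && mu == 0.0)) {
    x.alpha = 0.0; x.beta = 0.0; x.oma = 1.0; x.omb = 1.0;
    return x;
  }
  double r = lambda - mu;
  if (r == 0.0) {
    double lt = lambda * t;
    x.alpha = lt / (1.0 + lt);
    x.beta = x.alpha;
    x.oma = 1.0 / (1.0 + lt);
    x.omb = x.oma;
    return x;
  }
  double e = expm1(r * t);            // e^{rt} - 1, exact near r = 0
  double denom = lambda * e + r;      // lambda e^{rt} - mu
  x.alpha = mu * e / denom;
  x.beta = lambda * e / denom;
  x.oma = r * (e + 1.0) / denom;
  x.omb = r / denom;
  return x;
}

// single-lineage distribution over 0..cmax (tail beyond cmax dropped)
static std::vector<double> bd_row1(const BDSingle &x, int cmax) {
  std::vector<double> row(cmax + 1, 0.0);
  row[0] = x.alpha;
  if (cmax >= 1) {
    double v = x.oma * x.omb; // P(1)
    for (int c = 1; c <= cmax; ++c) {
      row[c] = v;
      v *= x.beta;
    }
  }
  return row;
}

// [[Rcpp::export]]
NumericMatrix bd_prob_matrix_cpp(double t, double lambda, double mu,
                                 int cmax) {
  BDSingle x = bd_single(t, lambda, mu);
  std::vector<double> row1 = bd_row1(x, cmax);
  NumericMatrix P(cmax + 1, cmax + 1);
  P(0, 0) = 1.0;
  std::vector<double> prev(cmax + 1), cur(cmax + 1);
  if (cmax >= 1) {
    for (int c = 0; c <= cmax; ++c) { prev[c] = row1[c]; P(1, c) = row1[c]; }
    for (int s = 2; s <= cmax; ++s) {
      for (int c = 0; c <= cmax; ++c) {
        double acc = 0.0;
        for (int i = 0; i <= c; ++i) acc += prev[i] * row1[c - i];
        cur[c] = acc;
      }
      for (int c = 0; c <= cmax; ++c) { P(s, c) = cur[c]; prev[c] = cur[c]; }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector bd_prob_cpp(IntegerVector s, IntegerVector c, NumericVector t,
                          NumericVector lambda, NumericVector mu) {
  int n = s.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int si = s[i], ci = c[i];
    if (si == 0) { out[i] = (ci == 0) ? 1.0 : 0.0; continue; }
    BDSingle x = bd_single(t[i], lambda[i], mu[i]);
    std::vector<double> row1 = bd_row1(x, ci);
    std::vector<double> prev = row1, cur(ci + 1);
    for (int k = 2; k <= si; ++k) {
      for (int cc = 0; cc <= ci; ++cc) {
        double acc = 0.0;
        for (int j = 0; j <= cc; ++j) acc += prev[j] * row1[cc - j];
        cur[cc] = acc;
      }
      prev = cur;
    }
    out[i] = prev[ci];
  }
  return out;
}
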