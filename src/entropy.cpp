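#include <Rcpp.h>
#include <cmath>
#include <deque>
using namespace Rcpp;

// Sample entropy, embedding m, tolerance r (Chebyshev distance, strict <).
// Template self-matches excluded. Degenerate counts return 0 by convention.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1 || r <= 0.0) return 0.0;
  long long A = 0, B = 0; // matches of length m+1 and m
  int nt = n - m;         // templates of length m start at 0..nt-1
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d < r) {
        ++B;
        if (i + m < n && j + m < n) {
          double dm = std::max(d, std::fabs(x[i + m] - x[j + m]));
          if (dm < r) ++A;
        }
      }
    }
  }
  if (B == 0 || A == 0) return 0.0;
  return -std::log((double)A / (double)B);
}

// Approximate entropy, phi(m) - phi(m+1), self-matches included (Pincus,
// <= r matching). Symmetric half-loop: each unordered template pair is
// examined once and credited to both counts.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1 || r <= 0.0) return 0.0;
  int nt1 = n - m + 1; // templates of length m
  int nt2 = n - m;     // templates of length m+1
  std::vector<long long> c1(nt1, 1), c2(nt2, 1); // self-matches
  for (int i = 0; i < nt1 - 1; ++i) {
    for (int j = i + 1; j < nt1; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        ++c1[i]; ++c1[j];
        if (i < nt2 && j < nt2) {
          double dm = std::max(d, std::fabs(x[i + m] - x[j + m]));
          if (dm <= r) { ++c2[i]; ++c2[j]; }
        }
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < nt1; ++i) phi1 += std::log((double)c1[i] / nt1);
  for (int i = 0; i < nt2; ++i) phi2 += std::log((double)c2[i] / nt2);
  return phi1 / nt1 - phi2 / nt2;
}

// Lempel-Ziv 1976 complexity (number of distinct phrases in the exhaustive
// history) of a binary sequence.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, i = 0, k = 1, l = 1, kmax = 1;
  // classic LZ76 scan (Kaspar & Schuster formulation)
  while (true) {
    if (l + k > n) { ++c; break; }
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Trailing running maximum over the previous `window` samples (current sample
// excluded); the first sample returns its own value. Monotonic-deque, O(n).
// [[Rcpp::export]]
NumericVector runmax_prev_cpp(NumericVector x, int window) {
  int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::deque<int> dq; // indices, values decreasing
  out[0] = x[0];
  for (int t = 1; t < n; ++t) {
    int i = t - 1; // admit previous sample
    while (!dq.empty() && x[dq.back()] <= x[i]) dq.pop_back();
    dq.push_back(i);
    while (!dq.empty() && dq.front() < t - window) dq.pop_front();
    out[t] = x[dq.front()];
  }
  return out;
}
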