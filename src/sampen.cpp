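#include <Rcpp.h>
using namespace Rcpp;

// Sample Entropy kernel, restricted Richman-Moorman estimator.
//
// Both template lengths are counted over the same index set i = 0..N-m-1
// (the N-m starting points for which a template of length m+1 exists), so
// that the m- and (m+1)-length match counts are comparable. Matching uses
// the Chebyshev (max-norm) distance with tolerance <= r_abs; self-matches
// are excluded. Returns -ln(A/B); NA when either count is zero (entropy
// undefined for the segment).
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r_abs) {
  const int n = x.size();
  if (m < 1) stop("template length m must be >= 1");
  if (r_abs < 0) stop("tolerance must be non-negative");
  if (n <= m + 1) stop("series too short for template length m");
  const int nt = n - m;  // templates with a length-(m+1) extension
  long long B = 0, A = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        d = std::abs(x[i + k] - x[j + k]);
        if (d > r_abs) { match_m = false; break; }
      }
      if (!match_m) continue;
      ++B;
      if (std::abs(x[i + m] - x[j + m]) <= r_abs) ++A;
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Per-window Sample Entropy over a single contiguous segment.
// Splits x into floor(n/N) non-overlapping windows of N samples (remainder
// discarded), applies a window-SD-relative tolerance r_rel * sd(window),
// and returns one entropy per window (NA where undefined).
// [[Rcpp::export]]
NumericVector sampen_windows_cpp(NumericVector x, int m, double r_rel, int N) {
  const int n = x.size();
  const int nw = n / N;
  NumericVector out(nw);
  for (int w = 0; w < nw; ++w) {
    NumericVector win = x[Range(w * N, w * N + N - 1)];
    // population-free sample SD of the window
    double mu = mean(win);
    double ss = 0.0;
    for (int k = 0; k < N; ++k) ss += (win[k] - mu) * (win[k] - mu);
    double sdw = std::sqrt(ss / (N - 1));
    out[w] = sampen_cpp(win, m, r_rel * sdw);
  }
  return out;
}
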