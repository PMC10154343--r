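#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sliding bandwidth-restricted cross-correlation of spectrotemporal
// templates over a cochleagram.  The cochleagram is treated as
// zero-extended (silent) beyond its last frame, so a stimulus shorter
// than a template still yields one window.
//
// Templates are demeaned and scaled to unit population SD by the caller.
// mode 0: plain demeaned-template match, value = sum(x * g) / K
// mode 1: local contrast gain control, value = Pearson correlation of the
//         window with the template (window demeaned / unit population SD
//         per step); zero-variance windows score 0 and are counted.

// accumulate dot products of g over x columns [lo, lo+C), zero-extended
static void slide_dot(const NumericMatrix& x, const NumericMatrix& g,
                      const int lo, std::vector<double>& out) {
  const int N = x.nrow(), T = g.nrow(), C = g.ncol();
  const int S = std::max(1, N - T + 1);
  out.assign(S, 0.0);
  double* po = out.data();
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, lo + c);
    const double* gc = &g(0, c);
    for (int t = 0; t < T; ++t) {
      const double gv = gc[t];
      if (gv == 0.0) continue;
      const int smax = std::min(S, N - t);
      const double* xs = xc + t;
      for (int s = 0; s < smax; ++s) po[s] += gv * xs[s];
    }
  }
}

// sliding window sums and sums of squares over the span, zero-extended
static void window_stats(const NumericMatrix& x, const int lo, const int C,
                         const int T, std::vector<double>& wsum,
                         std::vector<double>& wss) {
  const int N = x.nrow();
  const int S = std::max(1, N - T + 1);
  std::vector<double> ra(N, 0.0), rb(N, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, lo + c);
    for (int t = 0; t < N; ++t) {
      const double v = xc[t];
      ra[t] += v;
      rb[t] += v * v;
    }
  }
  std::vector<double> ca(N + 1, 0.0), cb(N + 1, 0.0);
  for (int t = 0; t < N; ++t) {
    ca[t + 1] = ca[t] + ra[t];
    cb[t + 1] = cb[t] + rb[t];
  }
  wsum.resize(S); wss.resize(S);
  for (int s = 0; s < S; ++s) {
    const int e = std::min(N, s + T);
    wsum[s] = ca[e] - ca[s];
    wss[s] = cb[e] - cb[s];
  }
}

// finalize mode-1 values in place; returns the degenerate-window count
static int finalize_local(std::vector<double>& dot,
                          const std::vector<double>& wsum,
                          const std::vector<double>& wss, const double K) {
  int ndeg = 0;
  for (size_t s = 0; s < dot.size(); ++s) {
    const double mean = wsum[s] / K;
    const double var = wss[s] / K - mean * mean;
    if (var <= 1e-24) {
      dot[s] = 0.0;
      ++ndeg;
    } else {
      // template sums to zero, so the window mean drops out of the
      // covariance and the correlation reduces to dot/(K*sd)
      double v = dot[s] / (K * std::sqrt(var));
      if (v > 1.0) v = 1.0;
      if (v < -1.0) v = -1.0;
      dot[s] = v;
    }
  }
  return ndeg;
}

// full response trace for one template; x is the span-restricted block
// [[Rcpp::export]]
List cpp_vm_trace(NumericMatrix x, NumericMatrix g, int mode) {
  if (g.ncol() != x.ncol()) stop("template and input channel counts differ");
  const double K = (double)g.nrow() * (double)g.ncol();
  std::vector<double> dot;
  slide_dot(x, g, 0, dot);
  int ndeg = 0;
  if (mode == 1) {
    std::vector<double> wsum, wss;
    window_stats(x, 0, g.ncol(), g.nrow(), wsum, wss);
    ndeg = finalize_local(dot, wsum, wss, K);
  } else {
    for (size_t s = 0; s < dot.size(); ++s) dot[s] /= K;
  }
  return List::create(_["values"] = NumericVector(dot.begin(), dot.end()),
                      _["n_degenerate"] = ndeg);
}

// maximum response of many templates on one full cochleagram
// gs: list of normalized templates; lo: 1-based first channel per template
// [[Rcpp::export]]
NumericVector cpp_vm_max_batch(NumericMatrix x, List gs, IntegerVector lo,
                               int mode) {
  const int n = gs.size();
  NumericVector out(n);
  std::vector<double> dot, wsum, wss;
  for (int i = 0; i < n; ++i) {
    NumericMatrix g = gs[i];
    const int l0 = lo[i] - 1;
    if (l0 < 0 || l0 + g.ncol() > x.ncol())
      stop("template span outside the cochleagram");
    slide_dot(x, g, l0, dot);
    const double K = (double)g.nrow() * (double)g.ncol();
    if (mode == 1) {
      window_stats(x, l0, g.ncol(), g.nrow(), wsum, wss);
      finalize_local(dot, wsum, wss, K);
    } else {
      for (size_t s = 0; s < dot.size(); ++s) dot[s] /= K;
    }
    out[i] = *std::max_element(dot.begin(), dot.end());
  }
  return out;
}
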