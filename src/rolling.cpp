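#include <Rcpp.h>
#include <deque>
#include <algorithm>
using namespace Rcpp;

// Centered sliding-window kernels used on long (hundreds of kHz-samples)
// physiological traces. Windows shrink at the boundaries: the window for
// index i is [max(0, i-h), min(n-1, i+h)] with h = floor(width/2).

// [[Rcpp::export(name = ".slide_max")]]
NumericVector slide_max(NumericVector x, int width) {
  int n = x.size();
  int h = width / 2;
  NumericVector out(n);
  // monotone deque over a moving right edge; rebuild is avoided by
  // advancing the window one sample at a time
  std::deque<int> dq;
  int right = -1;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h);
    int hi = std::min(n - 1, i + h);
    while (right < hi) {
      ++right;
      while (!dq.empty() && x[dq.back()] <= x[right]) dq.pop_back();
      dq.push_back(right);
    }
    while (!dq.empty() && dq.front() < lo) dq.pop_front();
    out[i] = x[dq.front()];
  }
  return out;
}

// [[Rcpp::export(name = ".slide_sd")]]
NumericVector slide_sd(NumericVector x, int width) {
  int n = x.size();
  int h = width / 2;
  // center on the global mean first so the cumulative sums stay small
  long double gm = 0.0;
  for (int i = 0; i < n; ++i) gm += x[i];
  gm /= n;
  std::vector<long double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    long double v = x[i] - gm;
    cs[i + 1] = cs[i] + v;
    cs2[i + 1] = cs2[i] + v * v;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h);
    int hi = std::min(n - 1, i + h);
    int m = hi - lo + 1;
    long double s = cs[hi + 1] - cs[lo];
    long double s2 = cs2[hi + 1] - cs2[lo];
    long double var = (m > 1) ? (s2 - s * s / m) / (m - 1) : 0.0;
    out[i] = var > 0 ? std::sqrt((double)var) : 0.0;
  }
  return out;
}

static double median_of(std::vector<double> &v) {
  size_t n = v.size();
  size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double m = v[mid];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + mid - 1, v.begin() + mid);
    m = 0.5 * (m + v[mid - 1]);
  }
  return m;
}

// Local median and (unscaled) median absolute deviation in a centered
// window; returned as a two-column matrix [median, mad]. O(n * w log w),
// intended for short windows (~100 samples).
// [[Rcpp::export(name = ".slide_med_mad")]]
NumericMatrix slide_med_mad(NumericVector x, int width) {
  int n = x.size();
  int h = width / 2;
  NumericMatrix out(n, 2);
  std::vector<double> buf, dev;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h);
    int hi = std::min(n - 1, i + h);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    double med = median_of(buf);
    dev.resize(buf.size());
    for (size_t j = 0; j < buf.size(); ++j)
      dev[j] = std::fabs(x[lo + (int)j] - med);
    out(i, 0) = med;
    out(i, 1) = median_of(dev);
  }
  return out;
}
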