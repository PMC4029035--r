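#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Segment-neighborhood dynamic program: exact least-squares segmentation of
// y into k segments for every k = 1..kmax.  O(kmax * d^2) with O(1) interval
// cost queries from prefix sums accumulated in long double.  Ties between
// equal-cost placements keep the smallest last-change index at every cell,
// which pushes changes toward the start of the signal (deterministic).

// [[Rcpp::export(name = ".dp_segment")]]
List dp_segment(NumericVector y, int kmax) {
  const int d = y.size();
  if (d < 1) stop("empty signal");
  if (kmax < 1 || kmax > d) stop("kmax out of range");

  // prefix sums accumulated in extended precision, then queried as doubles
  std::vector<long double> Sl(d + 1, 0.0L), S2l(d + 1, 0.0L);
  for (int i = 0; i < d; ++i) {
    Sl[i + 1] = Sl[i] + (long double)y[i];
    S2l[i + 1] = S2l[i] + (long double)y[i] * (long double)y[i];
  }
  std::vector<double> S(Sl.begin(), Sl.end()), S2(S2l.begin(), S2l.end());
  // RSS of probes i..j (1-based, inclusive); clamped at 0 for round-off.
  auto cost = [&](int i, int j) -> double {
    double s = S[j] - S[i - 1];
    double q = S2[j] - S2[i - 1];
    double c = q - s * s / (double)(j - i + 1);
    return c < 0.0 ? 0.0 : c;
  };

  const double INF = std::numeric_limits<double>::infinity();
  // best[k][j]: minimal RSS of k segments over probes 1..j
  std::vector<std::vector<double> > best(
      kmax + 1, std::vector<double>(d + 1, INF));
  std::vector<std::vector<int> > back(kmax + 1, std::vector<int>(d + 1, 0));
  for (int j = 1; j <= d; ++j) best[1][j] = cost(1, j);
  for (int k = 2; k <= kmax; ++k) {
    const std::vector<double>& prev = best[k - 1];
    std::vector<double>& cur = best[k];
    std::vector<int>& bk = back[k];
    for (int j = k; j <= d; ++j) {
      double b = INF;
      int arg = -1;
      const double Sj = S[j], S2j = S2[j];
      for (int i = k - 1; i <= j - 1; ++i) {
        double s = Sj - S[i];
        double v = prev[i] + (S2j - S2[i]) - s * s / (double)(j - i);
        if (v < b) { b = v; arg = i; }
      }
      if (b < 0.0) b = 0.0;
      cur[j] = b;
      bk[j] = arg;
    }
  }

  List models(kmax);
  for (int k = 1; k <= kmax; ++k) {
    IntegerVector changes(k - 1);
    int j = d;
    for (int kk = k; kk >= 2; --kk) {
      int i = back[kk][j];
      changes[kk - 2] = i;
      j = i;
    }
    NumericVector means(k);
    int prev = 0;
    for (int s = 0; s < k; ++s) {
      int end = (s == k - 1) ? d : changes[s];
      means[s] = (double)((S[end] - S[prev]) / (long double)(end - prev));
      prev = end;
    }
    models[k - 1] = List::create(
        _["k"] = k,
        _["change_indices"] = changes,
        _["segment_means"] = means,
        _["rss"] = (double)best[k][d]);
  }
  return models;
}
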