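#include <Rcpp.h>
using namespace Rcpp;

// Local maxima (1-based indices). Plateau tops count once, at their left
// edge; endpoints are never maxima.
// [[Rcpp::export]]
IntegerVector local_maxima_cpp(NumericVector x) {
  int n = x.size();
  std::vector<int> out;
  int i = 1;
  while (i < n - 1) {
    if (x[i - 1] < x[i]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[i]) ++j;
      if (j < n - 1 && x[j + 1] < x[i]) out.push_back(i + 1);
      i = j + 1;
    } else {
      ++i;
    }
  }
  return wrap(out);
}

// Topographic prominence of each peak: height above the higher of the two
// lowest saddles separating it from higher terrain (or the signal ends).
// [[Rcpp::export]]
NumericVector peak_prominence_cpp(NumericVector x, IntegerVector peaks) {
  int n = x.size(), m = peaks.size();
  NumericVector prom(m);
  for (int k = 0; k < m; ++k) {
    int p = peaks[k] - 1;
    double h = x[p];
    double left_min = h, right_min = h;
    for (int i = p - 1; i >= 0; --i) {
      if (x[i] > h) break;
      if (x[i] < left_min) left_min = x[i];
    }
    for (int i = p + 1; i < n; ++i) {
      if (x[i] > h) break;
      if (x[i] < right_min) right_min = x[i];
    }
    prom[k] = h - std::max(left_min, right_min);
  }
  return prom;
}
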