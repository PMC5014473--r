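#include <Rcpp.h>
using namespace Rcpp;

// 2x2 chi-square without continuity correction; 0 when a margin is empty.
static double chisq2x2(double a, double b, double c, double d) {
  double n = a + b + c + d;
  double r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d;
  double den = r1 * r2 * c1 * c2;
  if (den <= 0.0) return 0.0;
  double num = a * d - b * c;
  return n * num * num / den;
}

static void shuffle_in_place(std::vector<int>& v) {
  // Fisher-Yates driven by R's RNG so set.seed() governs permutations
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

static double maxchi_stat(const std::vector<int>& v, int w, int* pos) {
  int n = (int)v.size();
  std::vector<int> cs(n + 1, 0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + v[i];
  double best = -1.0;
  int bestpos = -1;
  for (int s = 0; s + 2 * w <= n; ++s) {
    int lm = cs[s + w] - cs[s];
    int rm = cs[s + 2 * w] - cs[s + w];
    double st = chisq2x2((double)lm, (double)(w - lm),
                         (double)rm, (double)(w - rm));
    if (st > best + 1e-12) { best = st; bestpos = s + w; }
  }
  if (pos) *pos = bestpos;
  return best;
}

// Peak of the sliding-frame 2x2 chi-square over a 0/1 match vector.
// Returns the max statistic and the 1-based index of the first right-half
// site of the maximizing frame (leftmost frame on ties).
// [[Rcpp::export]]
List maxchi_peak_cpp(IntegerVector v, int w) {
  std::vector<int> vv(v.begin(), v.end());
  int pos = -1;
  double best = maxchi_stat(vv, w, &pos);
  return List::create(_["stat"] = best, _["pos"] = pos + 1);
}

// Sequential permutation test for the maxchi peak statistic.
// Stops early once `early_k` exceedances are seen; returns the exceedance
// count and the number of permutations actually run.
// [[Rcpp::export]]
List maxchi_perm_cpp(IntegerVector v, int w, double observed,
                     int n_perm, int early_k) {
  std::vector<int> vv(v.begin(), v.end());
  int k = 0, done = 0;
  for (int b = 0; b < n_perm; ++b) {
    shuffle_in_place(vv);
    double st = maxchi_stat(vv, w, nullptr);
    if (st >= observed - 1e-9) ++k;
    ++done;
    if (k >= early_k) break;
  }
  return List::create(_["k"] = k, _["n"] = done);
}

// Maximum descent of the +/-1 random walk: max over 0 <= i < j <= n of
// walk[i] - walk[j], walk[0] = 0. Leftmost (smallest i, then smallest j)
// maximizer. Interval of sites achieving the descent is (i+1 .. j), 1-based.
static double max_descent(const std::vector<int>& steps, int* ai, int* aj) {
  int n = (int)steps.size();
  double walk = 0.0, maxpre = 0.0;
  int idxmax = 0;
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int j = 1; j <= n; ++j) {
    walk += steps[j - 1];
    double d = maxpre - walk;
    if (d > best + 1e-12) { best = d; bi = idxmax; bj = j; }
    if (walk > maxpre + 1e-12) { maxpre = walk; idxmax = j; }
  }
  if (ai) *ai = bi;
  if (aj) *aj = bj;
  return best;
}

static double sym_descent(const std::vector<int>& steps,
                          int* ai, int* aj, int* orient) {
  int i1, j1, i2, j2;
  double d1 = max_descent(steps, &i1, &j1);
  std::vector<int> neg(steps.size());
  for (size_t t = 0; t < steps.size(); ++t) neg[t] = -steps[t];
  double d2 = max_descent(neg, &i2, &j2);
  bool take2 = (d2 > d1 + 1e-12) ||
               (std::abs(d2 - d1) <= 1e-12 && (i2 < i1 || (i2 == i1 && j2 < j1)));
  if (take2) {
    if (ai) *ai = i2; if (aj) *aj = j2; if (orient) *orient = -1;
    return d2;
  }
  if (ai) *ai = i1; if (aj) *aj = j1; if (orient) *orient = 1;
  return d1;
}

// Plain maximum descent of the walk (leftmost maximizer).
// [[Rcpp::export]]
List maxdescent_cpp(IntegerVector steps) {
  std::vector<int> vv(steps.begin(), steps.end());
  int i = 0, j = 0;
  double d = max_descent(vv, &i, &j);
  return List::create(_["stat"] = d, _["from"] = i + 1, _["to"] = j);
}

// Orientation-symmetric maximum descent (the larger of the walk's and the
// mirrored walk's descent) used by the scan, which tries both parent
// orderings; parent relabelling cannot change it.
// [[Rcpp::export]]
List symdescent_cpp(IntegerVector steps) {
  std::vector<int> vv(steps.begin(), steps.end());
  int i = 0, j = 0, orient = 1;
  double d = sym_descent(vv, &i, &j, &orient);
  return List::create(_["stat"] = d, _["from"] = i + 1, _["to"] = j,
                      _["orientation"] = orient);
}

// [[Rcpp::export]]
List maxdescent_perm_cpp(IntegerVector steps, double observed,
                         int n_perm, int early_k) {
  std::vector<int> vv(steps.begin(), steps.end());
  int k = 0, done = 0;
  for (int b = 0; b < n_perm; ++b) {
    shuffle_in_place(vv);
    double st = sym_descent(vv, nullptr, nullptr, nullptr);
    if (st >= observed - 1e-9) ++k;
    ++done;
    if (k >= early_k) break;
  }
  return List::create(_["k"] = k, _["n"] = done);
}
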