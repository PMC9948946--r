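#include <Rcpp.h>
using namespace Rcpp;

// Adaptive-partitioning mutual information on rank pairs.
//
// Points live on the integer grid {0..N-1}^2 (each margin a permutation,
// so marginals are exactly uniform). The unit square is split recursively
// into quadrants while a chi-square test rejects uniformity of the four
// quadrant counts; each terminal cell contributes its plug-in MI term.
// The root split is always taken so that the null distribution of the
// estimate is continuous, which the exponential tail fit used for
// threshold calibration relies on.

static const double CHI2_CRIT = 7.814728; // chi-square df=3, alpha=0.05
static const int    MIN_SPLIT = 8;        // do not split cells smaller than this

static double miRec(std::vector<int>& xs, std::vector<int>& ys,
                    int lo, int hi, int x1, int x2, int y1, int y2, int N,
                    bool force) {
  int n = hi - lo;
  if (n == 0) return 0.0;
  double p  = (double)n / N;
  double px = (double)(x2 - x1) / N;
  double py = (double)(y2 - y1) / N;
  double leaf = p * std::log(p / (px * py));
  if (n < MIN_SPLIT || x2 - x1 < 2 || y2 - y1 < 2) return leaf;
  int xm = x1 + (x2 - x1) / 2, ym = y1 + (y2 - y1) / 2;
  int c[4] = {0, 0, 0, 0};
  for (int i = lo; i < hi; ++i)
    c[(xs[i] >= xm ? 1 : 0) + (ys[i] >= ym ? 2 : 0)]++;
  double e = n / 4.0, chi2 = 0.0;
  for (int q = 0; q < 4; ++q) chi2 += (c[q] - e) * (c[q] - e) / e;
  if (!force && chi2 < CHI2_CRIT) return leaf;
  // bucket the points into quadrant-contiguous order
  std::vector<int> bx(xs.begin() + lo, xs.begin() + hi);
  std::vector<int> by(ys.begin() + lo, ys.begin() + hi);
  int off[4];
  off[0] = lo; off[1] = lo + c[0]; off[2] = off[1] + c[1]; off[3] = off[2] + c[2];
  int pos[4] = {off[0], off[1], off[2], off[3]};
  for (int i = 0; i < n; ++i) {
    int q = (bx[i] >= xm ? 1 : 0) + (by[i] >= ym ? 2 : 0);
    xs[pos[q]] = bx[i]; ys[pos[q]] = by[i]; pos[q]++;
  }
  double s = 0.0;
  s += miRec(xs, ys, off[0], off[0] + c[0], x1, xm, y1, ym, N, false);
  s += miRec(xs, ys, off[1], off[1] + c[1], xm, x2, y1, ym, N, false);
  s += miRec(xs, ys, off[2], off[2] + c[2], x1, xm, ym, y2, N, false);
  s += miRec(xs, ys, off[3], off[3] + c[3], xm, x2, ym, y2, N, false);
  return s;
}

static double miFromRanks(const int* rx, const int* ry, int n) {
  std::vector<int> xs(rx, rx + n), ys(ry, ry + n);
  double v = miRec(xs, ys, 0, n, 0, n, 0, n, n, true);
  return v < 0 ? 0 : v;
}

// [[Rcpp::export]]
double cpp_mi(IntegerVector rx, IntegerVector ry) {
  if (rx.size() != ry.size()) stop("rank vectors differ in length");
  return miFromRanks(INTEGER(rx), INTEGER(ry), rx.size());
}

// Null MI draws: pairs of independent continuous samples of size n,
// rank-transformed. Uses the R RNG so results are reproducible under
// set.seed().
// [[Rcpp::export]]
NumericVector cpp_mi_null(int n, int nDraws) {
  NumericVector out(nDraws);
  std::vector<int> xs(n), ys(n), idx(n);
  for (int d = 0; d < nDraws; ++d) {
    NumericVector x = runif(n), y = runif(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b){ return x[a] < x[b]; });
    for (int i = 0; i < n; ++i) xs[idx[i]] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b){ return y[a] < y[b]; });
    for (int i = 0; i < n; ++i) ys[idx[i]] = i;
    out[d] = miFromRanks(xs.data(), ys.data(), n);
  }
  return out;
}

// MI between every TF column and every gene column of a rank matrix.
// `ranks` is samples x genes with 0-based ranks per column; `tfIdx`
// holds 0-based column indices of the regulators. Self pairs are NA.
// [[Rcpp::export]]
NumericMatrix cpp_mi_matrix(IntegerMatrix ranks, IntegerVector tfIdx) {
  int n = ranks.nrow(), G = ranks.ncol(), T = tfIdx.size();
  NumericMatrix out(T, G);
  for (int t = 0; t < T; ++t) {
    int tc = tfIdx[t];
    const int* rx = &ranks(0, tc);
    for (int g = 0; g < G; ++g) {
      if (g == tc) { out(t, g) = NA_REAL; continue; }
      out(t, g) = miFromRanks(rx, &ranks(0, g), n);
    }
  }
  return out;
}

// Sliding-window PWM score at every offset of an encoded sequence
// (codes 0..3 = ACGT, negative = ambiguous). Windows containing an
// ambiguous base score NA. `score` is a 4 x L log-odds matrix.
// [[Rcpp::export]]
NumericVector cpp_pwm_scan(IntegerVector codes, NumericMatrix score) {
  int S = codes.size(), L = score.ncol();
  if (S < L) return NumericVector(0);
  NumericVector out(S - L + 1);
  for (int o = 0; o + L <= S; ++o) {
    double s = 0.0; bool ok = true;
    for (int l = 0; l < L; ++l) {
      int c = codes[o + l];
      if (c < 0) { ok = false; break; }
      s += score(c, l);
    }
    out[o] = ok ? s : NA_REAL;
  }
  return out;
}
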