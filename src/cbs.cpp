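#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation core.
//
// For a marker series x[0..n-1], an arc is the run x[i+1..j] (1-based marker
// indices i+1..j, so 0 <= i < j <= n). The statistic compares the arc mean
// with the complement mean, scaled by sqrt(1/k + 1/(n-k)) where k = j - i.
// The overall sd cancels under permutation, so T is left unscaled here.
// Arc and complement must both contain at least min_width markers, and the
// whole-series "arc" (i = 0, j = n) is excluded.
//
// Tie-break: strictly-greater |T| wins while scanning i ascending then j
// ascending, so the leftmost, then shortest, arc is kept.
//
// With S the prefix sums and d = S[j] - S[i],
//   arc_mean - comp_mean = d * (1/k + 1/(n-k)) - S[n]/(n-k)
// so per arc length k the constants c1[k] = 1/k + 1/(n-k),
// c2[k] = S[n]/(n-k) and isq[k] = 1/sqrt(c1[k]) are precomputed and the
// inner loop is one multiply-subtract per (i, j) pair.

struct ArcBest {
  double t;
  int i, j;
};

// workspace reused across permutations of one series
struct ArcWork {
  std::vector<double> cs, c1, c2, isq;
};

static void arc_setup(const double *x, int n, ArcWork &w) {
  w.cs.resize(n + 1);
  w.cs[0] = 0.0;
  for (int m = 0; m < n; ++m) w.cs[m + 1] = w.cs[m] + x[m];
  const double tot = w.cs[n];
  w.c1.assign(n, 0.0);
  w.c2.assign(n, 0.0);
  w.isq.assign(n, 0.0);
  for (int k = 1; k < n; ++k) {
    w.c1[k] = 1.0 / k + 1.0 / (n - k);
    w.c2[k] = tot / (n - k);
    w.isq[k] = 1.0 / std::sqrt(w.c1[k]);
  }
}

// full search recording the argmax (leftmost, then shortest arc on ties)
static ArcBest max_arc_t(const double *x, int n, int min_width, ArcWork &w) {
  arc_setup(x, n, w);
  ArcBest best = {-1.0, -1, -1};
  for (int i = 0; i <= n - min_width; ++i) {
    const int jmax = (i == 0) ? n - 1 : n; // exclude (0, n)
    const double csi = w.cs[i];
    for (int j = i + min_width; j <= jmax; ++j) {
      const int k = j - i;
      if (n - k < min_width) break; // k only grows with j
      const double u = (w.cs[j] - csi) * w.c1[k] - w.c2[k];
      const double t = std::fabs(u) * w.isq[k];
      if (t > best.t) { best.t = t; best.i = i; best.j = j; }
    }
  }
  return best;
}

// permutation scan: only needs to know whether any arc reaches `threshold`
static bool any_arc_reaches(const double *x, int n, int min_width,
                            double threshold, ArcWork &w) {
  arc_setup(x, n, w);
  for (int i = 0; i <= n - min_width; ++i) {
    const int jmax = (i == 0) ? n - 1 : n;
    const double csi = w.cs[i];
    for (int j = i + min_width; j <= jmax; ++j) {
      const int k = j - i;
      if (n - k < min_width) break;
      const double u = (w.cs[j] - csi) * w.c1[k] - w.c2[k];
      if (std::fabs(u) * w.isq[k] >= threshold) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cbs_max_t(NumericVector x, int min_width) {
  const int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["t"] = NA_REAL, _["i"] = NA_INTEGER, _["j"] = NA_INTEGER);
  ArcWork w;
  ArcBest b = max_arc_t(REAL(x), n, min_width, w);
  return List::create(_["t"] = b.t, _["i"] = b.i, _["j"] = b.j);
}

// Permutation test for the best arc of x, with sequential early stopping:
// reject (not significant) once the exceedance count can no longer come in
// under alpha * n_perm; accept once at least m_accept (>= 2/alpha)
// permutations have produced an upper p estimate (e+1)/(m+1) of at most
// alpha / 2. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cbs_perm_test(NumericVector x, int min_width, int n_perm, double alpha,
                   int m_accept) {
  const int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["p"] = 1.0, _["t"] = NA_REAL,
                        _["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["n_perm_used"] = 0);
  ArcWork w;
  ArcBest obs = max_arc_t(REAL(x), n, min_width, w);

  // degenerate (constant) series: nothing to split
  double mn = x[0], mx = x[0];
  for (int m = 1; m < n; ++m) { mn = std::min(mn, x[m]); mx = std::max(mx, x[m]); }
  if (mx - mn < 1e-12 || obs.t <= 0.0)
    return List::create(_["p"] = 1.0, _["t"] = obs.t,
                        _["i"] = obs.i, _["j"] = obs.j, _["n_perm_used"] = 0);

  RNGScope scope;
  std::vector<double> perm(REAL(x), REAL(x) + n);
  const int e_reject = (int)std::floor(alpha * n_perm) + 1;
  const double threshold = obs.t * (1.0 - 1e-12);
  int e = 0, m = 0;
  double p = 1.0;
  while (m < n_perm) {
    // Fisher-Yates with R uniforms
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(perm[k], perm[idx]);
    }
    if (any_arc_reaches(perm.data(), n, min_width, threshold, w)) ++e;
    ++m;
    p = (e + 1.0) / (m + 1.0);
    if (e >= e_reject) break;                    // cannot reach p < alpha
    if (m >= m_accept && p <= alpha / 2.0) break; // clearly significant
  }
  return List::create(_["p"] = p, _["t"] = obs.t,
                      _["i"] = obs.i, _["j"] = obs.j, _["n_perm_used"] = m);
}
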