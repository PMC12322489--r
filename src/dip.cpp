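// Core routines for the dip statistic.
//
// A unimodal CDF is convex left of its mode and concave right of it, with
// an upward jump allowed at the mode. For a mode placed in a gap between
// consecutive distinct order statistics (or at a knot, with a jump), the
// minimal sup-norm fit error decomposes into two one-sided band-fit
// problems plus a monotone junction condition. The one-sided errors come
// from greatest-convex-minorant sweeps; the junction condition is checked
// through the minimal reachable end value (maximal start value) of the
// convex (concave) branch, and the few samples where it binds are
// resolved by bisection on the band width.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct SideRes {
  std::vector<double> full; // minimal 2*eps*n for prefix with usual bands
  std::vector<double> pin;  // variant: prefix ends pinned (pre-jump branch)
};

// Incremental greatest-convex-minorant sweep over knots (z, lower corner
// cb, upper corner ct), tracking the largest deviation of upper corners
// above the minorant. Deviations only grow as the minorant is pushed
// down, so the running maximum over re-scanned spans is exact.
SideRes side_pass(const std::vector<double>& z,
                  const std::vector<double>& cb,
                  const std::vector<double>& ct) {
  const int m = (int) z.size();
  SideRes r;
  r.full.assign(m, 0.0);
  r.pin.assign(m, 0.0);
  if (m == 0) return r;
  std::vector<int> hull(m);
  int k = 0;
  hull[0] = 0;
  double best = ct[0] - cb[0];
  r.pin[0] = 0.0;
  r.full[0] = best;
  for (int j = 1; j < m; ++j) {
    while (k >= 1) {
      const int p = hull[k - 1], q = hull[k];
      if ((cb[q] - cb[p]) * (z[j] - z[p]) >= (cb[j] - cb[p]) * (z[q] - z[p]))
        --k;
      else
        break;
    }
    const int p = hull[k];
    const double slope = (cb[j] - cb[p]) / (z[j] - z[p]);
    double b = 0.0;
    for (int i = p + 1; i < j; ++i) {
      const double dev = ct[i] - (cb[p] + (z[i] - z[p]) * slope);
      if (dev > b) b = dev;
    }
    if (b > best) best = b;
    hull[++k] = j;
    r.pin[j] = best;
    const double own = ct[j] - cb[j];
    if (own > best) best = own;
    r.full[j] = best;
  }
  return r;
}

// Max-envelope of lines over a fixed grid of query positions (Li Chao
// tree): supports arbitrary insertion order with queries only at grid
// points.
class LiChao {
public:
  explicit LiChao(const std::vector<double>& xs)
      : xs_(xs), a_(4 * xs.size(), 0.0), b_(4 * xs.size(), R_NegInf),
        has_(4 * xs.size(), false) {}
  void insert(double a, double b) { ins(1, 0, (int) xs_.size() - 1, a, b); }
  double query(int i) const {
    int lo = 0, hi = (int) xs_.size() - 1, node = 1;
    double best = R_NegInf;
    while (true) {
      if (has_[node]) best = std::max(best, a_[node] * xs_[i] + b_[node]);
      if (lo == hi) break;
      const int mid = (lo + hi) / 2;
      if (i <= mid) { node = 2 * node; hi = mid; }
      else { node = 2 * node + 1; lo = mid + 1; }
    }
    return best;
  }

private:
  void ins(int node, int lo, int hi, double a, double b) {
    while (true) {
      const int mid = (lo + hi) / 2;
      if (!has_[node]) { a_[node] = a; b_[node] = b; has_[node] = true; return; }
      const bool left_better =
          a * xs_[lo] + b > a_[node] * xs_[lo] + b_[node];
      const bool mid_better =
          a * xs_[mid] + b > a_[node] * xs_[mid] + b_[node];
      if (mid_better) { std::swap(a, a_[node]); std::swap(b, b_[node]); }
      if (lo == hi) return;
      if (left_better != mid_better) { node = 2 * node; hi = mid; }
      else { node = 2 * node + 1; lo = mid + 1; }
    }
  }
  const std::vector<double>& xs_;
  std::vector<double> a_, b_;
  std::vector<bool> has_;
};

// Minimal reachable end value of the convex branch at every knot, given
// band bounds L (lower) and U (upper) in count units: combines the
// monotone bound with steep-pair extrapolations (value forced to L at q,
// to U at p < q, extended linearly to the end). Exactness of the pairwise
// form was established against an LP formulation of the same problem.
// The steepest pair for each q is found by tangent search on the lower
// hull of the (z_p, U_p) corners; the extrapolation envelope is a Li Chao
// tree over the knot positions.
void amin_at(const std::vector<double>& z, const std::vector<double>& L,
             const std::vector<double>& U, std::vector<double>& out) {
  const int K = (int) z.size();
  out.assign(K, R_NegInf);
  if (K < 2) return;
  LiChao env(z);
  std::vector<int> hull;
  hull.reserve(K);
  double cm = R_NegInf;
  for (int j = 0; j < K; ++j) {
    if (j >= 2) {
      // E_j: envelope of extrapolation lines from q < j
      out[j] = env.query(j);
    }
    if (j >= 1) {
      cm = std::max(cm, L[j - 1]);
      out[j] = std::max(out[j], cm);
      // steepest slope from (z_j, L_j) back to hull of U-corners
      if (!hull.empty() && j + 1 < K) {
        int lo = 0, hi = (int) hull.size() - 1;
        // slope to hull vertices is unimodal; binary search on the
        // discrete derivative
        while (lo < hi) {
          const int mid = (lo + hi) / 2;
          const double s1 = (L[j] - U[hull[mid]]) / (z[j] - z[hull[mid]]);
          const double s2 = (L[j] - U[hull[mid + 1]]) / (z[j] - z[hull[mid + 1]]);
          if (s2 >= s1) lo = mid + 1; else hi = mid;
        }
        const double s = (L[j] - U[hull[lo]]) / (z[j] - z[hull[lo]]);
        env.insert(s, L[j] - s * z[j]);
      }
    }
    // push U-corner j onto the lower hull
    while (hull.size() >= 2) {
      const int p = hull[hull.size() - 2], q = hull.back();
      if ((U[q] - U[p]) * (z[j] - z[p]) >= (U[j] - U[p]) * (z[q] - z[p]))
        hull.pop_back();
      else
        break;
    }
    hull.push_back(j);
  }
}

struct Geom {
  int n, K;
  std::vector<double> z, cb, ct;   // knots, counts below / up to knot
  std::vector<double> zr, cbr, ctr; // reflected frame
  std::vector<double> aLf, aLp, aRf, aRp;
};

bool feasible(double eps, const Geom& g) {
  const double d2 = 2.0 * eps * g.n;
  const double delta = eps * g.n;
  const int K = g.K;
  if (g.aRf[0] <= d2 || g.aLf[K - 1] <= d2) return true;
  std::vector<double> L(K), U(K), Lr(K), Ur(K), Amin(K), AminR(K);
  for (int i = 0; i < K; ++i) {
    L[i] = g.ct[i] - delta;
    U[i] = g.cb[i] + delta;
    Lr[i] = g.ctr[i] - delta;
    Ur[i] = g.cbr[i] + delta;
  }
  amin_at(g.z, L, U, Amin);
  amin_at(g.zr, Lr, Ur, AminR);
  // Bmax at original knot k = n - AminR at reflected knot K-1-k.
  // All remaining mode placements sit at a knot (with an upward jump
  // allowed): an interior-gap mode is dominated by one at an adjacent
  // knot, because convexity forces the segment entering the mode to be
  // at least as steep as every earlier chord (and symmetrically on the
  // concave side), so spreading the climb across the gap never helps.
  for (int k = 0; k < K; ++k) { // mode at knot k with jump
    if (g.aLp[k] <= d2 && g.aRp[k] <= d2) {
      const double amin = std::max(Amin[k], g.cb[k] - delta);
      const double bmax = std::min(g.n - AminR[K - 1 - k], g.ct[k] + delta);
      if (amin <= bmax) return true;
    }
  }
  return false;
}

} // namespace

// [[Rcpp::export(name = ".dip_core")]]
double dip_core(NumericVector xs) {
  const int n = xs.size();
  // deduplicate (input sorted)
  Geom g;
  g.n = n;
  g.z.reserve(n);
  std::vector<double> cnt;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || xs[i] != xs[i - 1]) {
      g.z.push_back(xs[i]);
      cnt.push_back(1.0);
    } else {
      cnt.back() += 1.0;
    }
  }
  const int K = g.K = (int) g.z.size();
  g.cb.resize(K);
  g.ct.resize(K);
  double run = 0.0;
  for (int i = 0; i < K; ++i) {
    g.cb[i] = run;
    run += cnt[i];
    g.ct[i] = run;
  }
  g.zr.resize(K);
  g.cbr.resize(K);
  g.ctr.resize(K);
  for (int i = 0; i < K; ++i) {
    g.zr[i] = -g.z[K - 1 - i];
    g.cbr[i] = n - g.ct[K - 1 - i];
    g.ctr[i] = n - g.cb[K - 1 - i];
  }
  SideRes left = side_pass(g.z, g.cb, g.ct);
  SideRes right = side_pass(g.zr, g.cbr, g.ctr);
  g.aLf = left.full;
  g.aLp = left.pin;
  g.aRf.resize(K);
  g.aRp.resize(K);
  for (int i = 0; i < K; ++i) {
    g.aRf[i] = right.full[K - 1 - i];
    g.aRp[i] = right.pin[K - 1 - i];
  }
  // uncoupled lower bound over all mode placements
  double cand = std::min(g.aRf[0], g.aLf[K - 1]);
  for (int k = 0; k < K; ++k)
    cand = std::min(cand, std::max(g.aLp[k], g.aRp[k]));
  const double lb = cand / (2.0 * n);
  if (feasible(lb * (1.0 + 1e-12) + 1e-15, g)) return lb;
  // junction constraint binds: expand a bracket, then bisect
  double step = std::max(lb * 1e-3, 1e-10);
  double hi = lb + step;
  while (hi < 0.2500001 && !feasible(hi, g)) {
    step *= 4.0;
    hi = lb + step;
  }
  if (hi > 0.2500001) hi = 0.2500001;
  double lo = lb;
  while (hi - lo > 1e-12) {
    const double mid = 0.5 * (lo + hi);
    if (feasible(mid, g)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}
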