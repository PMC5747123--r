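#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Affine-gap pairwise string alignment over a precomputed base-wise
// similarity matrix sigma (n x m), plus its partition-function analogue and
// stochastic backtracking.
//
// Events: 0 = MATCH(i,j), 1 = GAP_Y (consumes x_i, gap in Y),
//         2 = GAP_X (consumes y_j, gap in X).
// A gap run of length L costs gap_open + (L-1) * gap_ext.
// With free_end, the leading and trailing single-type gap runs cost 0 and
// alignments whose terminal runs mix both gap types are excluded (standard
// semi-global path space).
//
// Layers: M(i,j) best/partition over paths ending in MATCH at (i,j);
//         Y(i,j) ending in GAP_Y; X(i,j) ending in GAP_X.

static inline double lse3(double a, double b, double c) {
  double m = std::max(a, std::max(b, c));
  if (!R_finite(m)) return R_NegInf;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}
static inline double lse2(double a, double b) {
  double m = std::max(a, b);
  if (!R_finite(m)) return R_NegInf;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct Tables {
  int n, m;
  std::vector<double> M, X, Y;
  double& at(std::vector<double>& A, int i, int j) { return A[i * (m + 1) + j]; }
  double v(const std::vector<double>& A, int i, int j) const {
    return A[i * (m + 1) + j];
  }
};

static void fill(Tables& t, const NumericMatrix& sigma, double go, double ge,
                 double invT, bool free_end, bool partition) {
  int n = t.n, m = t.m;
  t.M.assign((n + 1) * (m + 1), R_NegInf);
  t.X.assign((n + 1) * (m + 1), R_NegInf);
  t.Y.assign((n + 1) * (m + 1), R_NegInf);
  t.at(t.M, 0, 0) = 0.0;
  for (int j = 1; j <= m; ++j)
    t.at(t.X, 0, j) = free_end ? 0.0 : -(go + (j - 1) * ge) * invT;
  for (int i = 1; i <= n; ++i)
    t.at(t.Y, i, 0) = free_end ? 0.0 : -(go + (i - 1) * ge) * invT;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diagM = t.v(t.M, i - 1, j - 1), diagX = t.v(t.X, i - 1, j - 1),
             diagY = t.v(t.Y, i - 1, j - 1);
      double comb = partition ? lse3(diagM, diagX, diagY)
                              : std::max(diagM, std::max(diagX, diagY));
      t.at(t.M, i, j) = sigma(i - 1, j - 1) * invT + comb;
      // GAP_Y consumes x_i: predecessors at (i-1, j).  With free ends a
      // switch out of the boundary X-run would create a mixed leading gap
      // run, which the semi-global path space excludes.
      double predX = (free_end && i - 1 == 0) ? R_NegInf : t.v(t.X, i - 1, j);
      double yo = lse2(t.v(t.M, i - 1, j), predX) - go * invT;
      double yo_max = std::max(t.v(t.M, i - 1, j), predX) - go * invT;
      double ygap = t.v(t.Y, i - 1, j) - ge * invT;
      t.at(t.Y, i, j) = partition ? lse2(yo, ygap) : std::max(yo_max, ygap);
      // GAP_X consumes y_j: predecessors at (i, j-1)
      double predY = (free_end && j - 1 == 0) ? R_NegInf : t.v(t.Y, i, j - 1);
      double xo = lse2(t.v(t.M, i, j - 1), predY) - go * invT;
      double xo_max = std::max(t.v(t.M, i, j - 1), predY) - go * invT;
      double xe = t.v(t.X, i, j - 1) - ge * invT;
      t.at(t.X, i, j) = partition ? lse2(xo, xe) : std::max(xo_max, xe);
    }
  }
}

// endpoint set: global -> all three layers at (n,m).
// free_end -> M(n,m); M/X at (i,m) i<n with a free GAP_Y tail;
//             M/Y at (n,j) j<m with a free GAP_X tail.
struct Endpoint { int i, j, layer; };  // layer 0=M 1=Y 2=X

static void endpoints(const Tables& t, bool free_end, std::vector<Endpoint>& es,
                      std::vector<double>& vals) {
  int n = t.n, m = t.m;
  if (!free_end) {
    int L[3] = {0, 1, 2};
    for (int k = 0; k < 3; ++k) {
      Endpoint e; e.i = n; e.j = m; e.layer = L[k];
      es.push_back(e);
      vals.push_back(k == 0 ? t.v(t.M, n, m)
                            : (k == 1 ? t.v(t.Y, n, m) : t.v(t.X, n, m)));
    }
    return;
  }
  // only MATCH endpoints: the free trailing run (if any) is single-type
  Endpoint e; e.i = n; e.j = m; e.layer = 0;
  es.push_back(e); vals.push_back(t.v(t.M, n, m));
  for (int i = 1; i < n; ++i) {
    Endpoint a; a.i = i; a.j = m; a.layer = 0;
    es.push_back(a); vals.push_back(t.v(t.M, i, m));
  }
  for (int j = 1; j < m; ++j) {
    Endpoint a; a.i = n; a.j = j; a.layer = 0;
    es.push_back(a); vals.push_back(t.v(t.M, n, j));
  }
}

// deterministic traceback of one optimal path.
// tie-break: at equal value prefer MATCH > GAP_Y > GAP_X (both for the
// endpoint and for each predecessor choice).
static void traceback_optimal(const Tables& t, const NumericMatrix& sigma,
                              double go, double ge, bool free_end,
                              std::vector<int>& ev, double& best) {
  const double tol = 1e-9;
  int n = t.n, m = t.m;
  std::vector<Endpoint> es; std::vector<double> vals;
  endpoints(t, free_end, es, vals);
  int bi = 0;
  for (size_t k = 1; k < es.size(); ++k)
    if (vals[k] > vals[bi] + tol) bi = (int)k;
  best = vals[bi];
  int i = es[bi].i, j = es[bi].j, layer = es[bi].layer;
  std::vector<int> rev;
  // free trailing gaps
  for (int k = n; k > i; --k) rev.push_back(1);
  for (int k = m; k > j; --k) rev.push_back(2);
  while (i > 0 || j > 0) {
    if (layer == 0) {
      if (i == 0 && j == 0) break;
      rev.push_back(0);
      double target = t.v(t.M, i, j) - sigma(i - 1, j - 1);
      double dM = t.v(t.M, i - 1, j - 1), dY = t.v(t.Y, i - 1, j - 1),
             dX = t.v(t.X, i - 1, j - 1);
      if (std::fabs(dM - target) <= tol) layer = 0;
      else if (std::fabs(dY - target) <= tol) layer = 1;
      else layer = 2;
      --i; --j;
    } else if (layer == 1) {
      rev.push_back(1);
      if (j == 0) {  // boundary column: stay in leading-gap run
        --i; continue;
      }
      double target = t.v(t.Y, i, j);
      if (std::fabs(t.v(t.M, i - 1, j) - go - target) <= tol) layer = 0;
      else if (std::fabs(t.v(t.Y, i - 1, j) - ge - target) <= tol) layer = 1;
      else layer = 2;
      --i;
    } else {
      rev.push_back(2);
      if (i == 0) { --j; continue; }
      double target = t.v(t.X, i, j);
      if (std::fabs(t.v(t.M, i, j - 1) - go - target) <= tol) layer = 0;
      else if (std::fabs(t.v(t.Y, i, j - 1) - go - target) <= tol) layer = 1;
      else layer = 2;
      --j;
    }
  }
  ev.assign(rev.rbegin(), rev.rend());
}

// [[Rcpp::export]]
List c_align_optimal(NumericMatrix sigma, double go, double ge, bool free_end) {
  Tables t; t.n = sigma.nrow(); t.m = sigma.ncol();
  fill(t, sigma, go, ge, 1.0, free_end, false);
  std::vector<int> ev; double best = R_NegInf;
  traceback_optimal(t, sigma, go, ge, free_end, ev, best);
  return List::create(_["score"] = best, _["events"] = wrap(ev));
}

// [[Rcpp::export]]
List c_align_partition(NumericMatrix sigma, double go, double ge, double T,
                       bool free_end) {
  Tables t; t.n = sigma.nrow(); t.m = sigma.ncol();
  double invT = 1.0 / T;
  fill(t, sigma, go, ge, invT, free_end, true);
  std::vector<Endpoint> es; std::vector<double> vals;
  endpoints(t, free_end, es, vals);
  double logZ = R_NegInf;
  for (size_t k = 0; k < vals.size(); ++k) logZ = lse2(logZ, vals[k]);
  int n = t.n, m = t.m;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) {
      M(i, j) = t.v(t.M, i, j); X(i, j) = t.v(t.X, i, j); Y(i, j) = t.v(t.Y, i, j);
    }
  return List::create(_["logZ"] = logZ, _["M"] = M, _["X"] = X, _["Y"] = Y);
}

static int pick3(double w0, double w1, double w2) {
  // sample 0/1/2 proportional to exp(wk - max), -Inf allowed; uses R RNG
  double mx = std::max(w0, std::max(w1, w2));
  double e0 = R_finite(w0) ? std::exp(w0 - mx) : 0.0;
  double e1 = R_finite(w1) ? std::exp(w1 - mx) : 0.0;
  double e2 = R_finite(w2) ? std::exp(w2 - mx) : 0.0;
  double u = unif_rand() * (e0 + e1 + e2);
  if (u <= e0) return 0;
  if (u <= e0 + e1) return 1;
  return 2;
}

// [[Rcpp::export]]
List c_align_sample(NumericMatrix sigma, double go, double ge, double T,
                    bool free_end, int s) {
  Tables t; t.n = sigma.nrow(); t.m = sigma.ncol();
  double invT = 1.0 / T;
  fill(t, sigma, go, ge, invT, free_end, true);
  std::vector<Endpoint> es; std::vector<double> vals;
  endpoints(t, free_end, es, vals);
  double mx = R_NegInf;
  for (size_t k = 0; k < vals.size(); ++k) mx = std::max(mx, vals[k]);
  std::vector<double> cum(vals.size());
  double tot = 0.0;
  for (size_t k = 0; k < vals.size(); ++k) {
    tot += R_finite(vals[k]) ? std::exp(vals[k] - mx) : 0.0;
    cum[k] = tot;
  }
  RNGScope scope;
  List out(s);
  int n = t.n, m = t.m;
  for (int r = 0; r < s; ++r) {
    double u = unif_rand() * tot;
    size_t k = 0;
    while (k + 1 < cum.size() && u > cum[k]) ++k;
    int i = es[k].i, j = es[k].j, layer = es[k].layer;
    std::vector<int> rev;
    for (int q = n; q > i; --q) rev.push_back(1);
    for (int q = m; q > j; --q) rev.push_back(2);
    while (i > 0 || j > 0) {
      if (layer == 0) {
        if (i == 0 && j == 0) break;
        rev.push_back(0);
        layer = pick3(t.v(t.M, i - 1, j - 1), t.v(t.Y, i - 1, j - 1),
                      t.v(t.X, i - 1, j - 1));
        // map: 0->M, 1->Y, 2->X (argument order)
        --i; --j;
      } else if (layer == 1) {
        rev.push_back(1);
        if (j == 0) { --i; continue; }
        double pX = (free_end && i - 1 == 0) ? R_NegInf : t.v(t.X, i - 1, j);
        int c = pick3(t.v(t.M, i - 1, j) - go * invT,
                      t.v(t.Y, i - 1, j) - ge * invT,
                      pX - go * invT);
        layer = c;
        --i;
      } else {
        rev.push_back(2);
        if (i == 0) { --j; continue; }
        double pY = (free_end && j - 1 == 0) ? R_NegInf : t.v(t.Y, i, j - 1);
        int c = pick3(t.v(t.M, i, j - 1) - go * invT,
                      pY - go * invT,
                      t.v(t.X, i, j - 1) - ge * invT);
        layer = c;
        --j;
      }
    }
    IntegerVector ev(rev.size());
    for (size_t q = 0; q < rev.size(); ++q) ev[q] = rev[rev.size() - 1 - q];
    out[r] = ev;
  }
  return out;
}

// [[Rcpp::export]]
double c_dotplot_path_score(IntegerVector xi, IntegerVector yj,
                            NumericMatrix pX, NumericMatrix pY) {
  int k = xi.size();
  double s = 0.0;
  for (int a = 0; a < k; ++a)
    for (int b = a + 1; b < k; ++b)
      s += pX(xi[a] - 1, xi[b] - 1) * pY(yj[a] - 1, yj[b] - 1);
  return s;
}

// [[Rcpp::export]]
NumericMatrix c_all_vs_all_dotplot_self(List dotplots) {
  int n = dotplots.size();
  NumericMatrix out(n, 1);
  for (int k = 0; k < n; ++k) {
    NumericMatrix p = dotplots[k];
    double s = 0.0;
    int L = p.nrow();
    for (int i = 0; i < L; ++i)
      for (int j = i + 1; j < L; ++j) s += p(i, j) * p(i, j);
    out(k, 0) = s;
  }
  return out;
}
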