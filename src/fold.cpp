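#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simplified ensemble folding engine.
//
// A structure S is a non-crossing set of canonical pairs (GC/AU/GU) with
// hairpin loops >= min_hairpin unpaired residues.  Its weight is
//   V(S) = sum over pairs of w(pair type) + stack_bonus * #stacked pairs,
// a stacked pair being (i,j) with (i+1,j-1) also in S.  Boltzmann factor
// exp(V/kT); "energy" reported as -V.
//
// Partition recursions are computed in scaled arithmetic (per-base scale C
// derived from the max-weight structure) so that long sequences neither
// overflow nor underflow.

static inline int idx2(int i, int j, int n) { return i * (n + 2) + j; }

// max-weight (Nussinov-style) DP on an arbitrary non-negative weight matrix.
// W(i,j) > 0 marks a permitted pair.  Returns the pair list of one optimum,
// ties broken toward the lexicographically smallest pair list
// (prefer pairing the leftmost base, with the smallest partner).
static void mfe_dp(const NumericMatrix& W, double stack, int minh,
                   std::vector<double>& N, std::vector<double>& B, int n) {
  // B(i,j): best weight on [i,j] with i paired to j; N(i,j): best on [i,j]
  for (int span = 2; span <= n; ++span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      int j = i + span - 1;
      double b = R_NegInf;
      if (W(i - 1, j - 1) > 0 && j - i - 1 >= minh) {
        double inner = N[idx2(i + 1, j - 1, n)];
        double st = B[idx2(i + 1, j - 1, n)];
        if (R_finite(st)) inner = std::max(inner, st + stack);
        b = W(i - 1, j - 1) + inner;
      }
      B[idx2(i, j, n)] = b;
      // N(i,j) = max( N(i+1,j),  max_k B(i,k) + N(k+1,j) )
      double best = N[idx2(i + 1, j, n)];
      for (int k = i + minh + 1; k <= j; ++k) {
        double bk = B[idx2(i, k, n)];
        if (R_finite(bk)) best = std::max(best, bk + N[idx2(k + 1, j, n)]);
      }
      N[idx2(i, j, n)] = best;
    }
  }
}

static void mfe_traceback(const NumericMatrix& W, double stack, int minh,
                          const std::vector<double>& N,
                          const std::vector<double>& B, int n,
                          int i, int j, bool paired,
                          std::vector<std::pair<int, int> >& out) {
  const double tol = 1e-9;
  while (true) {
    if (i >= j) return;
    if (paired) {
      out.push_back(std::make_pair(i, j));
      double target = B[idx2(i, j, n)] - W(i - 1, j - 1);
      double st = B[idx2(i + 1, j - 1, n)];
      // prefer the unconstrained inner decomposition (its own traceback
      // already prefers the smallest pairs); take the stack only when forced
      if (std::fabs(N[idx2(i + 1, j - 1, n)] - target) <= tol) {
        i = i + 1; j = j - 1; paired = false;
      } else if (R_finite(st) && std::fabs(st + stack - target) <= tol) {
        i = i + 1; j = j - 1; paired = true;
      } else {
        return; // numerical dead end; cannot happen on consistent tables
      }
    } else {
      double target = N[idx2(i, j, n)];
      bool done = false;
      for (int k = i + minh + 1; k <= j; ++k) {
        double bk = B[idx2(i, k, n)];
        if (R_finite(bk) && std::fabs(bk + N[idx2(k + 1, j, n)] - target) <= tol) {
          mfe_traceback(W, stack, minh, N, B, n, i, k, true, out);
          i = k + 1; paired = false; done = true;
          break;
        }
      }
      if (!done) {
        if (std::fabs(N[idx2(i + 1, j, n)] - target) <= tol) { i = i + 1; }
        else return;
      }
    }
  }
}

// [[Rcpp::export]]
List c_mfe_fold(NumericMatrix W, double stack, int minh) {
  int n = W.nrow();
  std::vector<double> N((n + 2) * (n + 2), 0.0), B((n + 2) * (n + 2), R_NegInf);
  mfe_dp(W, stack, minh, N, B, n);
  std::vector<std::pair<int, int> > pairs;
  if (n >= 2) mfe_traceback(W, stack, minh, N, B, n, 1, n, false, pairs);
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    pm(k, 0) = pairs[k].first; pm(k, 1) = pairs[k].second;
  }
  double score = (n >= 2) ? N[idx2(1, n, n)] : 0.0;
  return List::create(_["pairs"] = pm, _["energy"] = -score);
}

// seq: integer codes 0=A 1=C 2=G 3=U
static inline double pair_weight(int a, int b, double wGC, double wAU, double wGU) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return wGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
  return 0.0;
}

// [[Rcpp::export]]
NumericMatrix c_pair_weight_matrix(IntegerVector seq, double wGC, double wAU,
                                   double wGU) {
  int n = seq.size();
  NumericMatrix W(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      W(i, j) = pair_weight(seq[i], seq[j], wGC, wAU, wGU);
  return W;
}

// [[Rcpp::export]]
NumericMatrix c_partition_fold(IntegerVector seq, double wGC, double wAU,
                               double wGU, double stack, double kT, int minh) {
  int n = seq.size();
  NumericMatrix P(n, n);
  if (n < minh + 2) return P;

  NumericMatrix W = c_pair_weight_matrix(seq, wGC, wAU, wGU);
  // scale from the max-weight structure so the dominant term is O(1)
  std::vector<double> Nv((n + 2) * (n + 2), 0.0), Bv((n + 2) * (n + 2), R_NegInf);
  mfe_dp(W, stack, minh, Nv, Bv, n);
  double vstar = Nv[idx2(1, n, n)];
  double C = std::exp(vstar / (n * kT));

  int stride = n + 2;
  std::vector<double> Q((n + 2) * stride, 0.0), Qb((n + 2) * stride, 0.0),
      Qh((n + 2) * stride, 0.0);
  // empty intervals (j < i): Q = 1
  for (int i = 1; i <= n + 1; ++i)
    for (int j = 0; j < i && j <= n; ++j) Q[idx2(i, j, n)] = 1.0;

  double estk = std::exp(stack / kT);
  // inside pass
  for (int span = 1; span <= n; ++span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      int j = i + span - 1;
      double w = W(i - 1, j - 1);
      if (w > 0 && j - i - 1 >= minh) {
        double inner = Q[idx2(i + 1, j - 1, n)] +
                       (estk - 1.0) * Qb[idx2(i + 1, j - 1, n)];
        Qb[idx2(i, j, n)] = std::exp(w / kT) / (C * C) * inner;
      }
      double q = Q[idx2(i, j - 1, n)] / C;
      for (int k = i; k <= j - minh - 1; ++k)
        q += Qb[idx2(k, j, n)] * Q[idx2(i, k - 1, n)];
      Q[idx2(i, j, n)] = q;
    }
  }
  double Ztot = Q[idx2(1, n, n)];
  if (!(Ztot > 0)) return P;

  // outside pass, largest spans first
  for (int span = n; span >= minh + 2; --span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      int j = i + span - 1;
      if (!(Qb[idx2(i, j, n)] > 0)) continue;
      double h = Q[idx2(1, i - 1, n)] * Q[idx2(j + 1, n, n)];
      for (int k = 1; k <= i - 1; ++k) {
        for (int l = j + 1; l <= n; ++l) {
          double qh = Qh[idx2(k, l, n)];
          if (!(qh > 0)) continue;
          double w = W(k - 1, l - 1);
          if (!(w > 0)) continue;
          double term = qh * std::exp(w / kT) / (C * C) *
                        Q[idx2(k + 1, i - 1, n)] * Q[idx2(j + 1, l - 1, n)];
          if (k == i - 1 && l == j + 1) term *= estk;
          h += term;
        }
      }
      Qh[idx2(i, j, n)] = h;
    }
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = i + minh + 1; j <= n; ++j) {
      double p = Qb[idx2(i, j, n)] * Qh[idx2(i, j, n)] / Ztot;
      if (p < 0) p = 0; if (p > 1) p = 1;
      P(i - 1, j - 1) = p; P(j - 1, i - 1) = p;
    }
  }
  return P;
}
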