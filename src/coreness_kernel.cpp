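#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Full density sweep of the multiplex rich-core detection.
//
// Edges are given per layer, 0-based, sorted by decreasing weight with ties
// broken lexicographically; 'off' holds the per-layer offsets into the
// concatenated arrays (length M + 1). Because the set of links retained at
// mean degree k is a prefix of each layer's ordering, per-layer strengths
// are accumulated incrementally as k grows. Richness mu is recomputed from
// the per-layer strengths in fixed layer order at every k so that the
// floating-point result matches a strength-first reference implementation.
//
// [[Rcpp::export]]
List coreness_sweep_cpp(IntegerVector ei, IntegerVector ej, NumericVector ew,
                        IntegerVector off, int N, int M, NumericVector cvec) {
  const int K = N - 1;
  IntegerMatrix delta(K, N);
  std::vector<double> S((size_t)M * N, 0.0);   // per-layer strengths
  std::vector<double> mu(N), mup(N);
  std::vector<int> ord(N), rnk(N);
  std::vector<int> curL(M, 0);
  const int nE = ew.size();
  std::vector<double> cw(nE);                  // c_m * w per edge
  for (int m = 0; m < M; ++m)
    for (int e = off[m]; e < off[m + 1]; ++e) cw[e] = cvec[m] * ew[e];

  for (int k = 1; k <= K; ++k) {
    int Lk = (int)std::floor((double)N * k / 2.0 + 0.5);
    for (int m = 0; m < M; ++m) {
      int nnz = off[m + 1] - off[m];
      int L = std::min(Lk, nnz);
      for (int e = curL[m]; e < L; ++e) {
        int idx = off[m] + e;
        S[(size_t)m * N + ei[idx]] += ew[idx];
        S[(size_t)m * N + ej[idx]] += ew[idx];
      }
      curL[m] = L;
    }
    // mu_i = sum_m c_m * S[m][i], accumulated in ascending layer order
    std::fill(mu.begin(), mu.end(), 0.0);
    for (int m = 0; m < M; ++m) {
      const double cm = cvec[m];
      const double *Sm = &S[(size_t)m * N];
      for (int i = 0; i < N; ++i) mu[i] += cm * Sm[i];
    }
    for (int i = 0; i < N; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (mu[a] != mu[b]) return mu[a] > mu[b];
      return a < b;
    });
    for (int r = 0; r < N; ++r) rnk[ord[r]] = r;
    // mu+ : retained links towards strictly higher-ranked nodes
    // (ranks form a permutation, so rnk[a] != rnk[b]; branchless update)
    std::fill(mup.begin(), mup.end(), 0.0);
    for (int m = 0; m < M; ++m) {
      const int lo = off[m], hi = off[m] + curL[m];
      for (int idx = lo; idx < hi; ++idx) {
        const int a = ei[idx], b = ej[idx];
        const double w = cw[idx];
        const bool d = rnk[b] < rnk[a];
        mup[a] += w * d;
        mup[b] += w * (!d);
      }
    }
    // boundary = first rank position attaining the maximum of mu+
    double best = 0.0;
    int rstar = -1;
    for (int r = 0; r < N; ++r) {
      double v = mup[ord[r]];
      if (v > best) { best = v; rstar = r; }
    }
    if (rstar >= 0)  // all-zero mu+ leaves the core empty
      for (int r = 0; r <= rstar; ++r) delta(k - 1, ord[r]) = 1;
  }

  NumericVector C(N);
  for (int i = 0; i < N; ++i) {
    int s = 0;
    for (int k = 0; k < K; ++k) s += delta(k, i);
    C[i] = (double)s / K;
  }
  return List::create(_["coreness"] = C, _["indicator"] = delta);
}
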