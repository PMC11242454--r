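#include <Rcpp.h>
using namespace Rcpp;

// Observed betaMNTD for all sample pairs plus null moments under tip-label
// permutations ("shuffling taxa across the phylogeny": taxon j takes tip
// perm[j]'s position while abundances stay put).
//
// Per permutation, a nearest-taxon array is built for every sample:
// q_s[t] = min over taxa j present in s of d(t, perm[j]) for every tip t.
// The abundance-weighted betaMNTD of a pair (a, b) is then
//   0.5 * ( sum_{i in a} w_a(i) q_b[perm[i]] +
//           sum_{j in b} w_b(j) q_a[perm[j]] ),
// which costs O(n_samples * richness * n_taxa) per permutation instead of
// O(pairs * richness^2).
//
// `comm`: samples x taxa abundances (renormalised internally); `dmat`:
// taxa x taxa patristic distances in the same column order; `perms`:
// n_null x taxa matrix of 1-based permutations (zero rows = observed
// only).
// [[Rcpp::export]]
List bnti_engine(NumericMatrix comm, NumericMatrix dmat, IntegerMatrix perms) {
  const int n = comm.nrow(), S = comm.ncol();
  if (dmat.nrow() != S || dmat.ncol() != S)
    stop("distance matrix does not match the taxon set");
  const int K = perms.nrow();

  std::vector<std::vector<int> > idx(n);
  std::vector<std::vector<double> > w(n);
  for (int s = 0; s < n; ++s) {
    double tot = 0.0;
    for (int j = 0; j < S; ++j) tot += comm(s, j);
    if (tot <= 0) stop("empty sample in community matrix");
    for (int j = 0; j < S; ++j) {
      if (comm(s, j) > 0) {
        idx[s].push_back(j);
        w[s].push_back(comm(s, j) / tot);
      }
    }
  }

  // row-major copy of the (symmetric) distance matrix for cache locality
  std::vector<double> d((size_t)S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) d[(size_t)i * S + j] = dmat(i, j);

  std::vector<double> q((size_t)n * S);
  std::vector<int> perm(S);

  const int P = n * (n - 1) / 2;
  std::vector<double> val(P);

  auto all_pairs = [&](const std::vector<int>& pm, std::vector<double>& out) {
    // nearest-taxon arrays per sample in permuted tip space
    std::fill(q.begin(), q.end(), R_PosInf);
    for (int s = 0; s < n; ++s) {
      double* qs = q.data() + (size_t)s * S;
      for (size_t jj = 0; jj < idx[s].size(); ++jj) {
        const double* row = d.data() + (size_t)pm[idx[s][jj]] * S;
        for (int t = 0; t < S; ++t)
          if (row[t] < qs[t]) qs[t] = row[t];
      }
    }
    int p = 0;
    for (int a = 0; a < n - 1; ++a) {
      const double* qa = q.data() + (size_t)a * S;
      for (int b = a + 1; b < n; ++b, ++p) {
        const double* qb = q.data() + (size_t)b * S;
        double acc = 0.0;
        for (size_t ii = 0; ii < idx[a].size(); ++ii)
          acc += w[a][ii] * qb[pm[idx[a][ii]]];
        for (size_t jj = 0; jj < idx[b].size(); ++jj)
          acc += w[b][jj] * qa[pm[idx[b][jj]]];
        out[p] = 0.5 * acc;
      }
    }
  };

  std::vector<int> ident(S);
  for (int j = 0; j < S; ++j) ident[j] = j;
  all_pairs(ident, val);

  NumericMatrix obs(n, n);
  int p = 0;
  for (int a = 0; a < n - 1; ++a)
    for (int b = a + 1; b < n; ++b, ++p) obs(a, b) = obs(b, a) = val[p];

  std::vector<double> sum(P, 0.0), sumsq(P, 0.0), nv(P);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < S; ++j) perm[j] = perms(k, j) - 1;
    all_pairs(perm, nv);
    for (p = 0; p < P; ++p) {
      sum[p] += nv[p];
      sumsq[p] += nv[p] * nv[p];
    }
    if (k % 16 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix nmean(n, n), nsd(n, n);
  if (K > 1) {
    p = 0;
    for (int a = 0; a < n - 1; ++a)
      for (int b = a + 1; b < n; ++b, ++p) {
        double m = sum[p] / K;
        double var = (sumsq[p] - K * m * m) / (K - 1);
        if (var < 0) var = 0;
        nmean(a, b) = nmean(b, a) = m;
        nsd(a, b) = nsd(b, a) = std::sqrt(var);
      }
  } else {
    std::fill(nmean.begin(), nmean.end(), NA_REAL);
    std::fill(nsd.begin(), nsd.end(), NA_REAL);
  }

  return List::create(_["obs"] = obs, _["null_mean"] = nmean,
                      _["null_sd"] = nsd, _["n_null"] = K);
}
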