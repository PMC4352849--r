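#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Relative log-probability of a genotype count table conditional on allele
// counts: L = h*log(2) - sum(lgamma(f_ij + 1)), h = heterozygote count.
// Terms constant across tables with the same allele counts are dropped.

// Guo-Thompson switch chain for the HWE exact test. State is the n x 2
// matrix of allele indices; one step picks two distinct individuals, one
// allele of each uniformly, and swaps them. The conditional distribution of
// tables is induced by uniform random pairing of the 2n gene copies, which
// is exchangeable under transpositions, so the swap preserves it exactly
// (acceptance probability 1). Uses R's RNG: results are reproducible under
// set.seed().
// [[Rcpp::export]]
List cpp_hwe_chain(IntegerMatrix geno, int k, int dememorization,
                   int batches, int iterations) {
  int n = geno.nrow();
  std::vector<int> a(n), b(n);
  std::vector<double> lg(2 * n + 2);
  for (int i = 0; i <= 2 * n + 1; ++i) lg[i] = std::lgamma((double)i + 1.0);

  std::vector<int> f((size_t)k * k, 0); // f[i*k+j], i <= j
  double S = 0.0;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    int x = geno(i, 0), y = geno(i, 1);
    if (x > y) std::swap(x, y);
    a[i] = x; b[i] = y;
    f[(size_t)x * k + y] += 1;
    if (x != y) ++h;
  }
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) S += lg[f[(size_t)i * k + j]];
  const double log2 = std::log(2.0);
  double L = h * log2 - S;
  const double Lobs = L;
  const double tol = 1e-9 * (1.0 + std::fabs(Lobs));

  RNGScope scope;
  auto cell = [&](int x, int y) -> int {
    return x <= y ? x * k + y : y * k + x;
  };
  auto remove_geno = [&](int x, int y) {
    int c = cell(x, y);
    S -= lg[f[c]]; f[c] -= 1; S += lg[f[c]];
    if (x != y) { --h; }
  };
  auto add_geno = [&](int x, int y) {
    int c = cell(x, y);
    S -= lg[f[c]]; f[c] += 1; S += lg[f[c]];
    if (x != y) { ++h; }
  };
  auto step = [&]() {
    int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
    int j = (int)(unif_rand() * (n - 1)); if (j >= n - 1) j = n - 2;
    if (j >= i) ++j;
    bool si = unif_rand() < 0.5, sj = unif_rand() < 0.5;
    int &xi = si ? a[i] : b[i];
    int &xj = sj ? a[j] : b[j];
    if (xi == xj) return; // swap is a no-op; table unchanged
    remove_geno(a[i], b[i]);
    remove_geno(a[j], b[j]);
    std::swap(xi, xj);
    if (a[i] > b[i]) std::swap(a[i], b[i]);
    if (a[j] > b[j]) std::swap(a[j], b[j]);
    add_geno(a[i], b[i]);
    add_geno(a[j], b[j]);
    L = h * log2 - S;
  };

  for (int t = 0; t < dememorization; ++t) step();
  NumericVector props(batches);
  for (int bt = 0; bt < batches; ++bt) {
    long hit = 0;
    for (int t = 0; t < iterations; ++t) {
      step();
      if (L <= Lobs + tol) ++hit;
    }
    props[bt] = (double)hit / iterations;
  }
  double p = mean(props);
  double se = 0.0;
  if (batches > 1) se = sd(props) / std::sqrt((double)batches);
  return List::create(_["p"] = p, _["se"] = se, _["batch_props"] = props,
                      _["n_steps"] = (double)dememorization +
                                     (double)batches * iterations);
}

// Permutation G-test of a genotypic two-locus contingency table. g1, g2 are
// 1-based genotype category codes per individual; one locus's codes are
// shuffled across individuals each replicate. With margins fixed by the
// permutation, G is monotone in T = sum(O * log O), so only T is compared.
// [[Rcpp::export]]
List cpp_ld_perm(IntegerVector g1, IntegerVector g2, int k1, int k2,
                 int nperm) {
  int n = g1.size();
  std::vector<int> obs((size_t)k1 * k2, 0);
  for (int i = 0; i < n; ++i) obs[(size_t)(g1[i] - 1) * k2 + (g2[i] - 1)] += 1;
  std::vector<double> xlogx(n + 1);
  xlogx[0] = 0.0;
  for (int i = 1; i <= n; ++i) xlogx[i] = (double)i * std::log((double)i);
  double Tobs = 0.0;
  for (size_t c = 0; c < obs.size(); ++c) Tobs += xlogx[obs[c]];

  // margins (fixed under permutation) for the G statistic itself
  std::vector<int> r(k1, 0), cmarg(k2, 0);
  for (int i = 0; i < n; ++i) { r[g1[i] - 1] += 1; cmarg[g2[i] - 1] += 1; }
  double margT = 0.0;
  for (int i = 0; i < k1; ++i) margT += xlogx[r[i]];
  for (int j = 0; j < k2; ++j) margT += xlogx[cmarg[j]];
  double g_obs = 2.0 * (Tobs - margT + xlogx[n]);

  RNGScope scope;
  std::vector<int> perm(g2.begin(), g2.end());
  std::vector<int> cnt((size_t)k1 * k2, 0);
  long ge = 0;
  const double tol = 1e-9 * (1.0 + std::fabs(Tobs));
  for (int rep = 0; rep < nperm; ++rep) {
    for (int i = n - 1; i > 0; --i) { // Fisher-Yates
      int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i)
      cnt[(size_t)(g1[i] - 1) * k2 + (perm[i] - 1)] += 1;
    double T = 0.0;
    for (size_t c = 0; c < cnt.size(); ++c) T += xlogx[cnt[c]];
    if (T >= Tobs - tol) ++ge;
  }
  double p = nperm > 0 ? (double)ge / nperm : NA_REAL;
  double se = nperm > 0 ? std::sqrt(std::max(p * (1.0 - p), 0.0) / nperm) : NA_REAL;
  return List::create(_["g"] = g_obs, _["p"] = p, _["se"] = se,
                      _["n_ge"] = (double)ge);
}
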