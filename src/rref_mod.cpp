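// Reduced row echelon form over a prime field F_p, p < 2^20.
//
// Workhorse of the invariant derivation: the monomial-evaluation matrices
// reach a few thousand columns once the truncation degree is raised, which
// is past what vectorized R elimination handles comfortably.  All values
// stay below p^2 < 2^40, so exact integer arithmetic in 64 bits suffices.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static int64_t mod_pow_ll(int64_t a, int64_t e, int64_t p) {
  int64_t r = 1;
  a %= p;
  while (e > 0) {
    if (e & 1) r = (r * a) % p;
    a = (a * a) % p;
    e >>= 1;
  }
  return r;
}

// [[Rcpp::export(name = ".rref_mod_cpp")]]
List rref_mod_cpp(NumericMatrix Vin, double pd) {
  const int64_t p = (int64_t)pd;
  const int K = Vin.nrow(), n = Vin.ncol();
  // row-major copy for cache-friendly row operations
  std::vector<int64_t> V((size_t)K * n);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < n; ++j)
      V[(size_t)i * n + j] = (int64_t)Vin(i, j) % p;

  std::vector<int> pivots;
  int r = 0;
  for (int j = 0; j < n && r < K; ++j) {
    int i0 = -1;
    for (int i = r; i < K; ++i)
      if (V[(size_t)i * n + j] != 0) { i0 = i; break; }
    if (i0 < 0) continue;
    if (i0 != r)
      for (int c = j; c < n; ++c)
        std::swap(V[(size_t)r * n + c], V[(size_t)i0 * n + c]);
    const int64_t inv = mod_pow_ll(V[(size_t)r * n + j], p - 2, p);
    for (int c = j; c < n; ++c)
      V[(size_t)r * n + c] = (V[(size_t)r * n + c] * inv) % p;
    for (int i = 0; i < K; ++i) {
      if (i == r) continue;
      const int64_t f = V[(size_t)i * n + j];
      if (f == 0) continue;
      const int64_t fneg = p - f;
      int64_t *rowi = &V[(size_t)i * n];
      const int64_t *rowr = &V[(size_t)r * n];
      for (int c = j; c < n; ++c)
        rowi[c] = (rowi[c] + fneg * rowr[c]) % p;
    }
    pivots.push_back(j + 1);
    ++r;
  }
  NumericMatrix R(r, n);
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < n; ++j)
      R(i, j) = (double)V[(size_t)i * n + j];
  return List::create(_["pivots"] = wrap(pivots), _["R"] = R);
}
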