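// Self-contained, versioned random generator (xoshiro256++ seeded through
// splitmix64) plus the performance-critical permutation kernels. Nothing
// here touches R's own RNG state, so results are reproducible across
// platforms and R releases.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // unbiased integer in [0, n) (Lemire rejection)
  inline uint32_t bounded(uint32_t n) {
    uint64_t m = (uint64_t)(uint32_t)next() * n;
    uint32_t l = (uint32_t)m;
    if (l < n) {
      const uint32_t t = (0u - n) % n;
      while (l < t) {
        m = (uint64_t)(uint32_t)next() * n;
        l = (uint32_t)m;
      }
    }
    return (uint32_t)(m >> 32);
  }

  // standard normal via Marsaglia's polar method
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

inline uint64_t as_seed(double seed) {
  if (!R_finite(seed) || seed < 0 || seed > 9007199254740992.0)
    stop("seed must be a finite non-negative number below 2^53");
  return (uint64_t)seed;
}

}  // namespace

// Full Fisher-Yates permutations of 1..m, one per column.
//' @noRd
// [[Rcpp::export(name = ".cpp_perm_chunk")]]
IntegerMatrix cpp_perm_chunk(double seed, int m, int k) {
  if (m < 1 || k < 1) stop("m and k must be positive");
  Xoshiro256 rng(as_seed(seed));
  IntegerMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    int* col = &out(0, j);
    for (int i = 0; i < m; ++i) col[i] = i + 1;
    for (int i = m - 1; i > 0; --i) {
      const uint32_t r = rng.bounded((uint32_t)(i + 1));
      const int tmp = col[i];
      col[i] = col[r];
      col[r] = tmp;
    }
  }
  return out;
}

// Ordered uniform K-subsets of 1..m, one per column (tail-K Fisher-Yates).
// The pool is deliberately NOT reset between columns: a partial
// Fisher-Yates pass yields a uniform ordered subset from any starting
// arrangement, and the fresh randomness makes columns independent.
//' @noRd
// [[Rcpp::export(name = ".cpp_perm_subset_chunk")]]
IntegerMatrix cpp_perm_subset_chunk(double seed, int m, int K, int k) {
  if (m < 1 || k < 1 || K < 1 || K > m) stop("need 1 <= K <= m and k >= 1");
  Xoshiro256 rng(as_seed(seed));
  std::vector<int> pool((size_t)m);
  for (int i = 0; i < m; ++i) pool[i] = i + 1;
  IntegerMatrix out(K, k);
  for (int j = 0; j < k; ++j) {
    int* col = &out(0, j);
    for (int t = 0; t < K; ++t) {
      const int i = m - 1 - t;
      const uint32_t r = rng.bounded((uint32_t)(i + 1));
      const int tmp = pool[i];
      pool[i] = pool[r];
      pool[r] = tmp;
      col[t] = pool[i];
    }
  }
  return out;
}

// Gather z[idx] column-wise; 8 columns interleaved with software prefetch to
// raise memory-level parallelism (the gather is latency-bound at large m).
//' @noRd
// [[Rcpp::export(name = ".cpp_gather")]]
NumericMatrix cpp_gather(NumericVector z, IntegerMatrix idx) {
  const int m = idx.nrow(), k = idx.ncol();
  if (z.size() != m) stop("length(z) must equal nrow(idx)");
  NumericMatrix out(m, k);
  const double* zp = REAL(z);
  int j = 0;
  for (; j + 8 <= k; j += 8) {
    const int* c[8];
    double* o[8];
    for (int b = 0; b < 8; ++b) {
      c[b] = &idx(0, j + b);
      o[b] = &out(0, j + b);
    }
    int i = 0;
    const int pd = 16;
    for (; i + pd < m; ++i) {
      for (int b = 0; b < 8; ++b)
        __builtin_prefetch(&zp[c[b][i + pd] - 1], 0, 0);
      for (int b = 0; b < 8; ++b) o[b][i] = zp[c[b][i] - 1];
    }
    for (; i < m; ++i)
      for (int b = 0; b < 8; ++b) o[b][i] = zp[c[b][i] - 1];
  }
  for (; j < k; ++j) {
    const int* col = &idx(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < m; ++i) o[i] = zp[col[i] - 1];
  }
  return out;
}

// Gather for instruments carrying a 16-bit code representation
// (value = table[code]): the randomly-accessed array is the 2-byte code
// vector (~1.8 MB at m = 920k), which stays cache-resident where a double
// vector would not. Codes are little-endian uint16 pairs in a raw vector.
//' @noRd
// [[Rcpp::export(name = ".cpp_gather_coded")]]
NumericMatrix cpp_gather_coded(RawVector codes, NumericVector table,
                               IntegerMatrix idx) {
  const int m = idx.nrow(), k = idx.ncol();
  if (codes.size() != 2 * (R_xlen_t)m) stop("codes must hold m uint16 values");
  NumericMatrix out(m, k);
  const uint16_t* cp = (const uint16_t*)RAW(codes);
  const double* tab = REAL(table);
  const int nt = table.size();
  const int pd = 16;
  int j = 0;
  for (; j + 8 <= k; j += 8) {
    const int* c[8];
    double* o[8];
    for (int b = 0; b < 8; ++b) {
      c[b] = &idx(0, j + b);
      o[b] = &out(0, j + b);
    }
    int i = 0;
    for (; i + pd < m; ++i) {
      for (int b = 0; b < 8; ++b)
        __builtin_prefetch(&cp[c[b][i + pd] - 1], 0, 0);
      for (int b = 0; b < 8; ++b) o[b][i] = tab[cp[c[b][i] - 1]];
    }
    for (; i < m; ++i)
      for (int b = 0; b < 8; ++b) o[b][i] = tab[cp[c[b][i] - 1]];
  }
  for (; j < k; ++j) {
    const int* col = &idx(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < m; ++i) {
      const int c = cp[col[i] - 1];
      if (c >= nt) stop("code out of range");
      o[i] = tab[c];
    }
  }
  return out;
}

// Standard normal draws discretized to 2^16 equiprobable quantile cells
// (value = qnorm((c + 0.5) / 65536) for cell c). Returns the double values
// plus their uint16 codes and the cell-value table, enabling the coded
// gather above. Moment error of the discretization is < 1e-4.
//' @noRd
// [[Rcpp::export(name = ".cpp_rnorm_coded")]]
List cpp_rnorm_coded(double seed, double n) {
  const R_xlen_t nn = (R_xlen_t)n;
  if (nn < 0) stop("n must be non-negative");
  Xoshiro256 rng(as_seed(seed));
  NumericVector table(65536);
  for (int c = 0; c < 65536; ++c)
    table[c] = R::qnorm((c + 0.5) / 65536.0, 0.0, 1.0, 1, 0);
  NumericVector vals(nn);
  RawVector codes(2 * nn);
  uint16_t* cp = (uint16_t*)RAW(codes);
  double* vp = REAL(vals);
  for (R_xlen_t i = 0; i < nn; ++i) {
    const uint16_t c = (uint16_t)(rng.next() >> 48);
    cp[i] = c;
    vp[i] = table[c];
  }
  return List::create(_["values"] = vals, _["codes"] = codes,
                      _["table"] = table);
}

// Centered transpose: Tc[l, i] = C[i, l] - means[l], blocked for locality.
//' @noRd
// [[Rcpp::export(name = ".cpp_center_transpose")]]
NumericMatrix cpp_center_transpose(NumericMatrix C, NumericVector means) {
  const int m = C.nrow(), n = C.ncol();
  if (means.size() != n) stop("length(means) must equal ncol(C)");
  NumericMatrix out(n, m);
  double* op = REAL(out);
  const double* mu = REAL(means);
  const int B = 256;
  for (int i0 = 0; i0 < m; i0 += B) {
    const int i1 = std::min(i0 + B, m);
    for (int l = 0; l < n; ++l) {
      const double* cl = &C(0, l);
      const double mul = mu[l];
      for (int i = i0; i < i1; ++i) op[(size_t)i * n + l] = cl[i] - mul;
    }
  }
  return out;
}

// Cross-products of centered covariates with permuted copies of a discrete
// instrument, via group subset sums. For an instrument taking a few distinct
// values v_0 (modal), v_1, ..., a permutation is equivalent to assigning
// uniform disjoint row subsets to the non-modal values; since the covariate
// columns are centered, the modal rows contribute nothing and
//   U[, j] = sum_g (v_g - v_0) * rowsum of Tc over the g-th index block.
// idx holds, per column, the ordered K-subset (blocks of sizes[g] rows);
// Tc is the centered n x m transpose of the covariates.
//' @noRd
// [[Rcpp::export(name = ".cpp_subset_crossprod")]]
NumericMatrix cpp_subset_crossprod(NumericMatrix Tc, IntegerMatrix idx,
                                   IntegerVector sizes, NumericVector wts) {
  const int n = Tc.nrow(), m = Tc.ncol();
  const int k = idx.ncol();
  const int g = sizes.size();
  if (wts.size() != g) stop("sizes and wts must have equal length");
  long Ktot = 0;
  for (int a = 0; a < g; ++a) Ktot += sizes[a];
  if (Ktot > idx.nrow()) stop("idx has fewer rows than sum(sizes)");
  NumericMatrix out(n, k);
  const double* T = REAL(Tc);
  const int pd = 16;
  // four permutation columns in flight to raise memory-level parallelism
  std::vector<double> acc((size_t)4 * n);
  int j = 0;
  for (; j + 4 <= k; j += 4) {
    const int* c[4];
    for (int b = 0; b < 4; ++b) c[b] = &idx(0, j + b);
    int t0 = 0;
    for (int a = 0; a < g; ++a) {
      const double w = wts[a];
      const int t1 = t0 + sizes[a];
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int t = t0; t < t1; ++t) {
        if (t + pd < t1)
          for (int b = 0; b < 4; ++b) {
            const double* p = &T[(size_t)(c[b][t + pd] - 1) * n];
            __builtin_prefetch(p, 0, 0);
            __builtin_prefetch(p + 8, 0, 0);
          }
        for (int b = 0; b < 4; ++b) {
          const double* row = &T[(size_t)(c[b][t] - 1) * n];
          double* ab = &acc[(size_t)b * n];
          for (int l = 0; l < n; ++l) ab[l] += row[l];
        }
      }
      for (int b = 0; b < 4; ++b) {
        double* oj = &out(0, j + b);
        const double* ab = &acc[(size_t)b * n];
        for (int l = 0; l < n; ++l) oj[l] += w * ab[l];
      }
      t0 = t1;
    }
  }
  for (; j < k; ++j) {
    const int* col = &idx(0, j);
    double* oj = &out(0, j);
    int t0 = 0;
    for (int a = 0; a < g; ++a) {
      const double w = wts[a];
      const int t1 = t0 + sizes[a];
      std::fill(acc.begin(), acc.begin() + n, 0.0);
      for (int t = t0; t < t1; ++t) {
        if (t + pd < t1)
          __builtin_prefetch(&T[(size_t)(col[t + pd] - 1) * n], 0, 0);
        const double* row = &T[(size_t)(col[t] - 1) * n];
        for (int l = 0; l < n; ++l) acc[l] += row[l];
      }
      for (int l = 0; l < n; ++l) oj[l] += w * acc[l];
      t0 = t1;
    }
  }
  return out;
}

// Single-precision centered transpose, packed in a raw vector (n x m floats,
// column i contiguous). Used by the large-m subset kernel: memory traffic is
// the bottleneck there and the ~1e-7 relative statistic error is orders of
// magnitude below any permutation tie resolution.
//' @noRd
// [[Rcpp::export(name = ".cpp_center_transpose_f")]]
RawVector cpp_center_transpose_f(NumericMatrix C, NumericVector means) {
  const int m = C.nrow(), n = C.ncol();
  if (means.size() != n) stop("length(means) must equal ncol(C)");
  RawVector out((R_xlen_t)4 * n * m);
  float* op = (float*)RAW(out);
  const double* mu = REAL(means);
  const int B = 256;
  for (int i0 = 0; i0 < m; i0 += B) {
    const int i1 = std::min(i0 + B, m);
    for (int l = 0; l < n; ++l) {
      const double* cl = &C(0, l);
      const double mul = mu[l];
      for (int i = i0; i < i1; ++i)
        op[(size_t)i * n + l] = (float)(cl[i] - mul);
    }
  }
  return out;
}

// Float variant of the subset cross-product kernel (double accumulators).
//' @noRd
// [[Rcpp::export(name = ".cpp_subset_crossprod_f")]]
NumericMatrix cpp_subset_crossprod_f(RawVector Tcf, int n, int m,
                                     IntegerMatrix idx,
                                     IntegerVector sizes, NumericVector wts) {
  if ((R_xlen_t)4 * n * m != Tcf.size()) stop("Tcf has wrong size");
  const int k = idx.ncol();
  const int g = sizes.size();
  if (wts.size() != g) stop("sizes and wts must have equal length");
  long Ktot = 0;
  for (int a = 0; a < g; ++a) Ktot += sizes[a];
  if (Ktot > idx.nrow()) stop("idx has fewer rows than sum(sizes)");
  NumericMatrix out(n, k);
  const float* T = (const float*)RAW(Tcf);
  std::vector<double> acc((size_t)n);
  for (int j = 0; j < k; ++j) {
    const int* col = &idx(0, j);
    double* oj = &out(0, j);
    int t0 = 0;
    for (int a = 0; a < g; ++a) {
      const double w = wts[a];
      const int t1 = t0 + sizes[a];
      std::fill(acc.begin(), acc.begin() + n, 0.0);
      for (int t = t0; t < t1; ++t) {
        if (t + 6 < t1)
          __builtin_prefetch(&T[(size_t)(col[t + 6] - 1) * n], 0, 0);
        const float* row = &T[(size_t)(col[t] - 1) * n];
        for (int l = 0; l < n; ++l) acc[l] += (double)row[l];
      }
      for (int l = 0; l < n; ++l) oj[l] += w * acc[l];
      t0 = t1;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_rnorm")]]
NumericVector cpp_rnorm(double seed, double n) {
  const R_xlen_t nn = (R_xlen_t)n;
  if (nn < 0) stop("n must be non-negative");
  Xoshiro256 rng(as_seed(seed));
  NumericVector out(nn);
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < nn; ++i) o[i] = rng.norm();
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_runif")]]
NumericVector cpp_runif(double seed, double n) {
  const R_xlen_t nn = (R_xlen_t)n;
  if (nn < 0) stop("n must be non-negative");
  Xoshiro256 rng(as_seed(seed));
  NumericVector out(nn);
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < nn; ++i) o[i] = rng.unif();
  return out;
}

// Dosage draws 0/1/2 with P(0) = p0, P(1) = p1, P(2) = 1 - p0 - p1.
//' @noRd
// [[Rcpp::export(name = ".cpp_dosage")]]
IntegerVector cpp_dosage(double seed, double n, double p0, double p1) {
  const R_xlen_t nn = (R_xlen_t)n;
  if (nn < 0) stop("n must be non-negative");
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1 + 1e-12)
    stop("invalid dosage probabilities");
  Xoshiro256 rng(as_seed(seed));
  IntegerVector out(nn);
  int* o = INTEGER(out);
  const double c1 = p0, c2 = p0 + p1;
  for (R_xlen_t i = 0; i < nn; ++i) {
    const double u = rng.unif();
    o[i] = u < c1 ? 0 : (u < c2 ? 1 : 2);
  }
  return out;
}
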