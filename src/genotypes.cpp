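#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fast deterministic stream for bulk matrix fills: xoshiro256++ seeded from
// R's RNG, so results remain reproducible under set.seed() while avoiding
// the per-call overhead of unif_rand() in O(n*m) loops.

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  inline uint64_t next() {
    uint64_t result = rotl64(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl64(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform on (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

static uint64_t seed_from_R() {
  // two draws from R's RNG give > 100 bits of seed entropy
  uint64_t a = (uint64_t)(unif_rand() * 9007199254740992.0);
  uint64_t b = (uint64_t)(unif_rand() * 9007199254740992.0);
  return a ^ (b << 11) ^ (b >> 3);
}

// Standardised Hardy-Weinberg genotype matrix.  Each entry is a dosage in
// {0,1,2} drawn as Binomial(2, maf[j]), centred by 2*maf[j] and scaled by
// sqrt(2*maf[j]*(1-maf[j])) using the true allele frequency.
// [[Rcpp::export]]
NumericMatrix cpp_std_genotypes(int n, NumericVector maf) {
  int m = maf.size();
  NumericMatrix X(n, m);
  Xoshiro rng(seed_from_R());
  for (int j = 0; j < m; ++j) {
    double f = maf[j];
    double p0 = (1.0 - f) * (1.0 - f);       // P(dosage = 0)
    double p01 = p0 + 2.0 * f * (1.0 - f);   // P(dosage <= 1)
    double s = std::sqrt(2.0 * f * (1.0 - f));
    double v0 = (0.0 - 2.0 * f) / s;
    double v1 = (1.0 - 2.0 * f) / s;
    double v2 = (2.0 - 2.0 * f) / s;
    double *col = &X(0, j);
    for (int i = 0; i < n; ++i) {
      double u = rng.unif();
      col[i] = (u < p0) ? v0 : (u < p01 ? v1 : v2);
    }
  }
  return X;
}

// Matrix of independent standard normals (Box-Muller over the xoshiro
// stream), for the joint-normal genotype approximation in ascertained
// case/control sampling.
// [[Rcpp::export]]
NumericMatrix cpp_norm_matrix(int n, int m) {
  NumericMatrix X(n, m);
  Xoshiro rng(seed_from_R());
  double *p = REAL(X);
  R_xlen_t len = (R_xlen_t)n * m;
  R_xlen_t i = 0;
  while (i + 1 < len) {
    double u1 = rng.unif(), u2 = rng.unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    p[i++] = r * std::cos(2.0 * M_PI * u2);
    p[i++] = r * std::sin(2.0 * M_PI * u2);
  }
  if (i < len) {
    double u1 = rng.unif(), u2 = rng.unif();
    p[i] = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  return X;
}
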