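#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <string>

// 32-bit FNV-1a over the bytes of an ASCII string, with a seed folded
// into the offset basis. Mirrors the package's reference definition.
static uint32_t fnv1a32(const std::string &s, double seed) {
  // integer seeds only; uint32 wraparound == mod 2^32
  uint32_t h = 2166136261u + static_cast<uint32_t>(static_cast<int64_t>(seed));
  for (unsigned char b : s) {
    h ^= static_cast<uint32_t>(b & 0xFFu);
    h *= 16777619u;
  }
  return h;
}

// [[Rcpp::export(name = ".hash32_cpp")]]
double hash32_cpp(std::string s, double seed) {
  return static_cast<double>(fnv1a32(s, seed));
}

// murmur3-style avalanche finalizer: FNV-1a alone is too structured on
// short sequential keys for the uniforms below to pass moment checks
static uint32_t fmix32(uint32_t h) {
  h ^= h >> 16;
  h *= 0x85ebca6bu;
  h ^= h >> 13;
  h *= 0xc2b2ae35u;
  h ^= h >> 16;
  return h;
}

// Deterministic standard normals from hashed counters via Box-Muller:
// u1 = (H(key|a|i) + 0.5) / 2^32, u2 = (H(key|b|i) + 0.5) / 2^32,
// z = sqrt(-2 log u1) * (cos, sin)(2 pi u2).
// [[Rcpp::export(name = ".hash_normals_cpp")]]
Rcpp::NumericVector hash_normals_cpp(std::string key, int n, double seed) {
  int m = (n + 1) / 2;
  Rcpp::NumericVector z(2 * m);
  for (int i = 1; i <= m; ++i) {
    std::string ia = key + "|a|" + std::to_string(i);
    std::string ib = key + "|b|" + std::to_string(i);
    double u1 = (static_cast<double>(fmix32(fnv1a32(ia, seed))) + 0.5) / 4294967296.0;
    double u2 = (static_cast<double>(fmix32(fnv1a32(ib, seed))) + 0.5) / 4294967296.0;
    double r = std::sqrt(-2.0 * std::log(u1));
    z[i - 1] = r * std::cos(2.0 * M_PI * u2);
    z[m + i - 1] = r * std::sin(2.0 * M_PI * u2);
  }
  return Rcpp::NumericVector(z.begin(), z.begin() + n);
}

// In-place Adam update: p, m, v are mutated (callers own these buffers
// exclusively; checkpoint copies are made explicitly on the R side).
// [[Rcpp::export(name = ".adam_update_cpp")]]
void adam_update_cpp(Rcpp::NumericVector p, Rcpp::NumericVector m,
                     Rcpp::NumericVector v, Rcpp::NumericVector g,
                     double lr, double beta1, double beta2, double eps,
                     double t) {
  const double b1t = 1.0 - std::pow(beta1, t);
  const double b2t = 1.0 - std::pow(beta2, t);
  const R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    Rcpp::stop("adam buffers must have equal length");
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    p[i] -= lr * (m[i] / b1t) / (std::sqrt(v[i] / b2t) + eps);
  }
}
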