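#pragma once
#include <cstdint>
#include <cmath>

// Self-contained counter-seeded generator (splitmix64 -> xoshiro256++) so that
// every run is reproducible from a single integer seed independently of R's
// global RNG state and of platform RNG differences.
struct Xoshiro256pp {
  uint64_t s[4];

  static inline uint64_t splitmix64(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
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

  // uniform on [0, 1), 53-bit resolution
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer on {0, ..., n-1}; n is small (lattice sites, directions)
  inline int unif_int(int n) { return (int)(unif() * n); }

  double norm();
};

// Marsaglia-Tsang ziggurat tables for the standard normal (128 strips).
// Normals dominate the per-step cost of the noisy rate-equation engine, so
// the sampler matters; correctness is asserted statistically in the tests.
struct ZigguratTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigguratTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    const double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

namespace {
const ZigguratTables zig_tables; // per-TU copy, initialised at load time
}

inline double Xoshiro256pp::norm() {
  const ZigguratTables &z = zig_tables;
  const double rtail = 3.442619855899;
  for (;;) {
    const int32_t hz = (int32_t)(uint32_t)(next() >> 32);
    const int iz = hz & 127;
    const uint32_t a =
        hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (a < z.kn[iz]) return hz * z.wn[iz];
    if (iz == 0) { // base strip: sample the tail beyond rtail
      double xx, yy;
      do {
        xx = -std::log(1.0 - unif()) / rtail;
        yy = -std::log(1.0 - unif());
      } while (yy + yy < xx * xx);
      return hz > 0 ? rtail + xx : -(rtail + xx);
    }
    const double x = hz * z.wn[iz];
    if (z.fn[iz] + unif() * (z.fn[iz - 1] - z.fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

// Stable cross-platform seed mixing for per-cell / per-run child seeds.
inline uint64_t mix_seed_u64(uint64_t base, uint64_t a, uint64_t b, uint64_t c) {
  uint64_t x = base;
  uint64_t h = Xoshiro256pp::splitmix64(x);
  x = h ^ (a + 0x9e3779b97f4a7c15ULL);
  h = Xoshiro256pp::splitmix64(x);
  x = h ^ (b + 0xbf58476d1ce4e5b9ULL);
  h = Xoshiro256pp::splitmix64(x);
  x = h ^ (c + 0x94d049bb133111ebULL);
  return Xoshiro256pp::splitmix64(x);
}
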