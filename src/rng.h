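#pragma once
#include <cstdint>
#include <cmath>

#ifndef M_PI
#define M_PI 3.14159265358979323846
#endif

// Deterministic per-subsystem random streams (xorshift64* + Box-Muller).
// Each (run seed, agent, subsystem) triple gets its own stream, so enabling
// one noise source never perturbs the draws of another.
class StreamRNG {
  uint64_t s_;
  bool has_cached_;
  double cached_;

public:
  explicit StreamRNG(uint64_t seed) : has_cached_(false), cached_(0.0) {
    // splitmix64 scramble so nearby seeds give unrelated streams
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s_ = z ^ (z >> 31);
    if (s_ == 0) s_ = 0x9E3779B97F4A7C15ULL;
  }

  double unif() {
    s_ ^= s_ >> 12;
    s_ ^= s_ << 25;
    s_ ^= s_ >> 27;
    uint64_t x = s_ * 0x2545F4914F6CDD1DULL;
    // 53-bit mantissa, strictly inside (0, 1)
    return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double norm() {
    if (has_cached_) {
      has_cached_ = false;
      return cached_;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    cached_ = r * std::sin(th);
    has_cached_ = true;
    return r * std::cos(th);
  }
};

inline uint64_t crossim_stream_seed(uint64_t run_seed, int agent, int subsystem) {
  return run_seed * 0x100000001B3ULL + (uint64_t)(agent + 1) * 1013904223ULL +
         (uint64_t)(subsystem + 1) * 69069ULL;
}
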