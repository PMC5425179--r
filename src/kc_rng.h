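#ifndef KC_RNG_H
#define KC_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained mt19937_64 + Box-Muller normal deviates.
// std::normal_distribution is implementation-defined; this stream is not,
// so trajectories are bit-reproducible for a given seed on any platform.
namespace kc {

class RNG {
 public:
  explicit RNG(uint64_t seed) : has_spare_(false), spare_(0.0) {
    mt_[0] = seed;
    for (int i = 1; i < 312; ++i)
      mt_[i] = 6364136223846793005ULL * (mt_[i - 1] ^ (mt_[i - 1] >> 62)) + i;
    idx_ = 312;
  }

  uint64_t next_u64() {
    if (idx_ >= 312) twist();
    uint64_t x = mt_[idx_++];
    x ^= (x >> 29) & 0x5555555555555555ULL;
    x ^= (x << 17) & 0x71D67FFFEDA60000ULL;
    x ^= (x << 37) & 0xFFF7EEE000000000ULL;
    x ^= (x >> 43);
    return x;
  }

  // uniform in (0, 1]
  double unif() {
    return ((next_u64() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }

  // Marsaglia polar method: two deviates per accepted pair, no trig
  double normal() {
    if (has_spare_) { has_spare_ = false; return spare_; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double fac = std::sqrt(-2.0 * std::log(s) / s);
    spare_ = v * fac;
    has_spare_ = true;
    return u * fac;
  }

 private:
  void twist() {
    const uint64_t LM = 0x7FFFFFFFULL, UM = ~LM;
    for (int i = 0; i < 312; ++i) {
      uint64_t x = (mt_[i] & UM) | (mt_[(i + 1) % 312] & LM);
      uint64_t xa = x >> 1;
      if (x & 1ULL) xa ^= 0xB5026F5AA96619E9ULL;
      mt_[i] = mt_[(i + 156) % 312] ^ xa;
    }
    idx_ = 0;
  }

  uint64_t mt_[312];
  int idx_;
  bool has_spare_;
  double spare_;
};

}  // namespace kc

#endif
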