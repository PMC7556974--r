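#ifndef ATOMICNMF_RNG_H
#define ATOMICNMF_RNG_H

#include <cstdint>
#include <cmath>
#include <Rmath.h>

namespace anmf {

// splitmix64 step: advances state, returns a mixed 64-bit word
inline uint64_t splitmix64(uint64_t &s) {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

// Stream classes: every random draw in the engine belongs to a keyed
// substream so that proposal generation/evaluation is a pure function of
// (seed, class, id) -- the basis of the sequential-equivalence contract.
enum StreamClass : uint64_t {
    STREAM_HEADER = 1,  // proposal headers, id1 = global proposal counter
    STREAM_EVAL   = 2,  // proposal evaluation, id1 = global proposal counter
    STREAM_PHASE  = 3,  // per-phase update budget, id1 = phase index
    STREAM_HOOK   = 4   // test hooks
};

// Counter-based generator: state derived by chained splitmix64 hashing of
// the key words; cheap to construct, no correlated low bits.
class Rng {
public:
    Rng(uint64_t seed, uint64_t cls, uint64_t id1 = 0, uint64_t id2 = 0) {
        uint64_t s = seed + 0x632BE59BD9B4E019ULL;
        uint64_t h = splitmix64(s);
        s = h ^ (cls * 0xFF51AFD7ED558CCDULL);
        h = splitmix64(s);
        s = h ^ (id1 * 0xC4CEB9FE1A85EC53ULL);
        h = splitmix64(s);
        s = h ^ (id2 * 0xD6E8FEB86659FD93ULL);
        state_ = splitmix64(s);
    }

    uint64_t next() { return splitmix64(state_); }

    // uniform on [0, 1)
    double uniform() {
        return (next() >> 11) * (1.0 / 9007199254740992.0);
    }

    // unbiased uniform integer on [0, n), n >= 1
    uint64_t below(uint64_t n) {
        const uint64_t threshold = (0 - n) % n;  // 2^64 mod n
        for (;;) {
            uint64_t r = next();
            if (r >= threshold) return r % n;
        }
    }

    double exponential(double rate) {
        return -std::log1p(-uniform()) / rate;
    }

    // Poisson draw by counting unit-rate arrivals before time `mean`;
    // O(mean) but only used once per phase.
    int poisson(double mean) {
        int k = 0;
        double t = exponential(1.0);
        while (t < mean) {
            ++k;
            t += exponential(1.0);
        }
        return k;
    }

    // Truncated-normal draw by inverse CDF on [lo, hi]; consumes exactly one
    // uniform.  ok=false (rejection) when the interval carries < minMass
    // probability.
    double truncNorm(double mean, double sd, double lo, double hi, bool &ok,
                     double minMass = 1e-10) {
        double u = uniform();
        double pLo = ::Rf_pnorm5(lo, mean, sd, 1, 0);
        double pHi = ::Rf_pnorm5(hi, mean, sd, 1, 0);
        if (!(pHi - pLo >= minMass)) {
            ok = false;
            return 0.0;
        }
        ok = true;
        double x = ::Rf_qnorm5(pLo + u * (pHi - pLo), mean, sd, 1, 0);
        if (x < lo) x = lo;
        if (x > hi) x = hi;
        return x;
    }

private:
    uint64_t state_;
};

}  // namespace anmf

#endif
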