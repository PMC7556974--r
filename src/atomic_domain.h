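#ifndef ATOMICNMF_ATOMIC_DOMAIN_H
#define ATOMICNMF_ATOMIC_DOMAIN_H

#include <cstdint>
#include <vector>
#include <algorithm>
#include <stdexcept>
#include "rng.h"

namespace anmf {

constexpr double MASS_EPSILON = 1e-12;

struct Atom {
    uint64_t pos;
    double mass;
};

// One-dimensional atomic domain: point masses at integer positions in
// [0, binSize * nBins).  Each bin maps row-major to one element of the bound
// factor matrix; the element's value is the sum of the masses in its bin.
// Atoms are kept in a position-sorted vector (O(1) uniform selection,
// binary-search neighbours, memmove-cheap insert/erase at realistic counts).
class AtomicDomain {
public:
    int nRow = 0, nCol = 0;
    uint64_t nBins = 0, binSize = 0, usable = 0, maxAtoms = 0;
    double alpha = 0.0, lambda = 1.0;
    std::vector<Atom> atoms;           // sorted by pos, unique positions
    std::vector<double> *elem = nullptr;  // nBins values, row-major (bin index)

    AtomicDomain() = default;

    // binSizeOverride = 0 -> conceptual length 2^64, all bins equal width
    AtomicDomain(int nr, int nc, double a, double l, std::vector<double> *e,
                 uint64_t binSizeOverride = 0)
        : nRow(nr), nCol(nc), alpha(a), lambda(l), elem(e) {
        nBins = static_cast<uint64_t>(nr) * static_cast<uint64_t>(nc);
        binSize = binSizeOverride ? binSizeOverride : UINT64_MAX / nBins;
        usable = binSize * nBins;
        maxAtoms = 100 * nBins;
        if (elem) elem->assign(nBins, 0.0);
    }

    size_t size() const { return atoms.size(); }

    long lowerBound(uint64_t pos) const {
        return std::lower_bound(atoms.begin(), atoms.end(), pos,
                                [](const Atom &a, uint64_t p) { return a.pos < p; }) -
               atoms.begin();
    }

    long findIndex(uint64_t pos) const {
        long i = lowerBound(pos);
        if (i < (long)atoms.size() && atoms[i].pos == pos) return i;
        return -1;
    }

    bool occupied(uint64_t pos) const { return findIndex(pos) >= 0; }

    uint64_t binOf(uint64_t pos) const { return pos / binSize; }

    // (row, col) of the element owning `pos`; row-major bin order
    void elementOf(uint64_t pos, int &r, int &c) const {
        if (pos >= usable) throw std::domain_error("position out of range");
        uint64_t bin = pos / binSize;
        r = static_cast<int>(bin / nCol);
        c = static_cast<int>(bin % nCol);
    }

    void insert(uint64_t pos, double mass) {
        long i = lowerBound(pos);
        if (i < (long)atoms.size() && atoms[i].pos == pos)
            throw std::runtime_error("collision: position occupied");
        atoms.insert(atoms.begin() + i, Atom{pos, mass});
    }

    double erase(uint64_t pos) {
        long i = findIndex(pos);
        if (i < 0) throw std::runtime_error("no atom at position");
        double m = atoms[i].mass;
        atoms.erase(atoms.begin() + i);
        return m;
    }

    void setMass(uint64_t pos, double m) {
        long i = findIndex(pos);
        if (i < 0) throw std::runtime_error("no atom at position");
        atoms[i].mass = m;
    }

    double massAt(uint64_t pos) const {
        long i = findIndex(pos);
        if (i < 0) throw std::runtime_error("no atom at position");
        return atoms[i].mass;
    }

    // Recompute one bin's element value as a fresh left-to-right sum over its
    // atoms (never incremental +-mass), so every execution order produces
    // bit-identical values.
    void recomputeBin(uint64_t bin) {
        uint64_t lo = bin * binSize;
        uint64_t hi = lo + binSize;  // <= usable, no overflow
        double s = 0.0;
        for (long i = lowerBound(lo); i < (long)atoms.size() && atoms[i].pos < hi; ++i)
            s += atoms[i].mass;
        (*elem)[bin] = s;
    }

    void recomputeAll() {
        elem->assign(nBins, 0.0);
        for (const Atom &a : atoms) (*elem)[binOf(a.pos)] += a.mass;
    }

    // uniform over unoccupied positions (rejection sampling; the domain is
    // astronomically sparse in production, and tiny test domains still
    // terminate because at least one position is free)
    uint64_t randomFreePosition(Rng &rng) const {
        if (size() >= usable) throw std::runtime_error("domain full");
        for (;;) {
            uint64_t p = rng.below(usable);
            if (!occupied(p)) return p;
        }
    }

    long randomAtomIndex(Rng &rng) const {
        if (atoms.empty()) throw std::runtime_error("empty domain");
        return static_cast<long>(rng.below(atoms.size()));
    }

    // index of atom with smallest position > pos, or -1
    long rightNeighborIndex(uint64_t pos) const {
        long i = findIndex(pos);
        if (i < 0) throw std::runtime_error("no atom at position");
        return (i + 1 < (long)atoms.size()) ? i + 1 : -1;
    }

    double totalMass() const {
        double s = 0.0;
        for (const Atom &a : atoms) s += a.mass;
        return s;
    }
};

}  // namespace anmf

#endif
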