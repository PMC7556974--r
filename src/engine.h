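#ifndef ATOMICNMF_ENGINE_H
#define ATOMICNMF_ENGINE_H

#include <vector>
#include <unordered_set>
#include <cmath>
#include <stdexcept>
#include "rng.h"
#include "atomic_domain.h"
#include "model.h"

namespace anmf {

enum Kind { BIRTH = 0, DEATH = 1, MOVE = 2, EXCHANGE = 3 };

struct Prop {
    int kind = BIRTH;
    uint64_t pos1 = 0, pos2 = 0;  // birth/death: pos1; move: from/to; exchange: pair
    long elem1 = -1, elem2 = -1;  // affected bins (elem2 = -1 if single)
    int data1 = -1, data2 = -1;   // affected data row (A) / column (P) indices
    uint64_t counter = 0;         // keys the private evaluation substream
};

enum HeaderStatus { H_QUEUED, H_NOOP, H_CONFLICT, H_AMBIG };

// mass draw from the Gibbs conditional: truncated Normal((smu - lambda)/s,
// 1/sqrt(s)) on [lo, hi]; rejection when s == 0 or the interval mass is
// negligible; always consumes exactly one uniform
inline double gibbsMass(const Cond &cp, double lambda, double lo, double hi,
                        Rng &rng, bool &ok) {
    if (!(lo < hi)) throw std::runtime_error("gibbsMass: lower >= upper");
    if (!(cp.s > 0.0)) {
        rng.uniform();
        ok = false;
        return 0.0;
    }
    double mean = (cp.smu - lambda) / cp.s;
    double sd = 1.0 / std::sqrt(cp.s);
    return rng.truncNorm(mean, sd, lo, hi, ok);
}

// truncated Exponential(rate) on [lo, hi]; one uniform
inline double truncExp(Rng &rng, double rate, double lo, double hi) {
    double u = rng.uniform();
    double z = -std::expm1(-rate * (hi - lo));
    return lo - std::log1p(-u * z) / rate;
}

class Engine {
public:
    Model model;
    double maxGibbsA = INFINITY, maxGibbsP = INFINITY;  // mass-draw caps
    std::vector<double> elemA, elemP;  // unused (model.A/model.P are bound); kept for prior-only runs
    AtomicDomain domA, domP;
    uint64_t seed = 1;
    int maxQueue = 64, workers = 1;
    uint64_t counter = 0;  // global proposal counter (shared across phases)

    // batch statistics / internal-contract violations
    long long nBatches = 0, nQueuedTotal = 0, nAmbigFlush = 0, nConflictFlush = 0;
    long long nNoop = 0, nCapNoop = 0, invariantViolations = 0;

    // ---- queue state -------------------------------------------------------
    std::vector<Prop> queue;
    std::vector<char> usedData;
    std::unordered_set<uint64_t> usedPos;
    long pendingDeaths = 0, pendingStructural = 0;  // structural: deaths + moves

    AtomicDomain &dom(int side) { return side == SIDE_A ? domA : domP; }

    int dataIndexOf(int side, long bin) const {
        return side == SIDE_A ? (int)(bin / model.K) : (int)(bin % model.M);
    }

    void resetClaims(int side) {
        queue.clear();
        usedData.assign(side == SIDE_A ? model.N : model.M, 0);
        usedPos.clear();
        pendingDeaths = 0;
        pendingStructural = 0;
    }

    void regClaims(int side, const Prop &p) {
        usedData[p.data1] = 1;
        if (p.data2 >= 0) usedData[p.data2] = 1;
        usedPos.insert(p.pos1);
        if (p.kind == MOVE || p.kind == EXCHANGE) usedPos.insert(p.pos2);
        if (p.kind == DEATH) { ++pendingDeaths; ++pendingStructural; }
        if (p.kind == MOVE) ++pendingStructural;
    }

    // proposal kind from one uniform draw; quartile regions, infeasible kinds
    // remapped to birth
    static int kindAt(uint64_t count, double u) {
        int q = (u < 0.25) ? BIRTH : (u < 0.5) ? DEATH : (u < 0.75) ? MOVE : EXCHANGE;
        if ((q == DEATH || q == MOVE) && count < 1) return BIRTH;
        if (q == EXCHANGE && count < 2) return BIRTH;
        return q;
    }

    // Generate the next proposal header with the sequential algorithm.  All
    // decisions that depend on the atom count are evaluated at both ends of
    // the pending-count interval [lo, hi]; disagreement (or dependence on the
    // unresolved atom set) returns H_AMBIG: the batch is flushed and the same
    // counter key regenerates the header under fully resolved state, so the
    // proposal stream is identical to the sequential (maxQueue = 1) chain.
    HeaderStatus genHeader(int side, Prop &p) {
        AtomicDomain &d = dom(side);
        Rng hr(seed, STREAM_HEADER, counter);
        const uint64_t hi = d.size();
        const uint64_t lo = hi - (uint64_t)pendingDeaths;
        const double mu = d.alpha * (double)d.nBins;
        double u = hr.uniform();
        int kLo = kindAt(lo, u), kHi = kindAt(hi, u);
        if (kLo != kHi) return H_AMBIG;
        const int kind = kLo;

        if (kind == BIRTH) {
            bool capLo = lo >= d.maxAtoms, capHi = hi >= d.maxAtoms;
            if (capLo != capHi) return H_AMBIG;
            if (capHi) { ++nCapNoop; return H_NOOP; }  // cap: silent no-op
            double ua = hr.uniform();
            bool accLo = ua < mu / (double)(lo + 1);
            bool accHi = ua < mu / (double)(hi + 1);
            if (accLo != accHi) return H_AMBIG;
            if (!accLo) return H_NOOP;
            uint64_t pos;
            for (;;) {
                pos = hr.below(d.usable);
                // claimed position: occupancy may differ once pending
                // proposals resolve -> regenerate after the flush
                if (usedPos.count(pos)) return H_AMBIG;
                if (!d.occupied(pos)) break;
            }
            // placeholder atom: the atom set seen by later headers matches
            // the sequential chain; mass is drawn at evaluation
            d.insert(pos, 0.0);
            p = Prop{};
            p.kind = BIRTH;
            p.pos1 = pos;
            p.counter = counter;
            p.elem1 = (long)d.binOf(pos);
            p.data1 = dataIndexOf(side, p.elem1);
            return usedData[p.data1] ? H_CONFLICT : H_QUEUED;
        }

        // death/move/exchange select an atom by uniform index over the sorted
        // atom list; pending deaths/moves make that list unresolved
        if (pendingStructural > 0) return H_AMBIG;

        if (kind == DEATH) {
            double ua = hr.uniform();
            if (!(ua < (double)hi / mu)) return H_NOOP;
            long idx = d.randomAtomIndex(hr);
            p = Prop{};
            p.kind = DEATH;
            p.pos1 = d.atoms[idx].pos;
            p.counter = counter;
            p.elem1 = (long)d.binOf(p.pos1);
            p.data1 = dataIndexOf(side, p.elem1);
            if (usedPos.count(p.pos1) || usedData[p.data1]) return H_CONFLICT;
            return H_QUEUED;
        }

        if (kind == MOVE) {
            long idx = d.randomAtomIndex(hr);
            uint64_t from = d.atoms[idx].pos;
            uint64_t lb = (idx > 0) ? d.atoms[idx - 1].pos + 1 : 0;
            uint64_t ub = (idx + 1 < (long)d.size()) ? d.atoms[idx + 1].pos - 1
                                                     : d.usable - 1;
            uint64_t dest = lb + hr.below(ub - lb + 1);
            p = Prop{};
            p.kind = MOVE;
            p.pos1 = from;
            p.pos2 = dest;
            p.counter = counter;
            p.elem1 = (long)d.binOf(from);
            long destBin = (long)d.binOf(dest);
            p.elem2 = (destBin == p.elem1) ? -1 : destBin;
            p.data1 = dataIndexOf(side, p.elem1);
            p.data2 = (p.elem2 >= 0) ? dataIndexOf(side, p.elem2) : -1;
            if (p.data2 == p.data1) p.data2 = -1;
            bool neighborClaimed =
                (idx > 0 && usedPos.count(d.atoms[idx - 1].pos)) ||
                (idx + 1 < (long)d.size() && usedPos.count(d.atoms[idx + 1].pos));
            if (usedPos.count(from) || usedPos.count(dest) || neighborClaimed ||
                usedData[p.data1] || (p.data2 >= 0 && usedData[p.data2]))
                return H_CONFLICT;
            return H_QUEUED;
        }

        // EXCHANGE: partner is the right neighbour, last atom wraps to first
        long idx = d.randomAtomIndex(hr);
        long pidx = (idx + 1 < (long)d.size()) ? idx + 1 : 0;
        p = Prop{};
        p.kind = EXCHANGE;
        p.pos1 = d.atoms[idx].pos;
        p.pos2 = d.atoms[pidx].pos;
        p.counter = counter;
        p.elem1 = (long)d.binOf(p.pos1);
        long bin2 = (long)d.binOf(p.pos2);
        p.elem2 = (bin2 == p.elem1) ? -1 : bin2;
        p.data1 = dataIndexOf(side, p.elem1);
        p.data2 = (p.elem2 >= 0) ? dataIndexOf(side, p.elem2) : -1;
        if (p.data2 == p.data1) p.data2 = -1;
        if (usedPos.count(p.pos1) || usedPos.count(p.pos2) ||
            usedData[p.data1] || (p.data2 >= 0 && usedData[p.data2]))
            return H_CONFLICT;
        return H_QUEUED;
    }

    // ---- evaluation kernels ------------------------------------------------

    void applyElemDelta(int side, long bin, double before) {
        AtomicDomain &d = dom(side);
        d.recomputeBin((uint64_t)bin);
        if (model.sparseMode) return;
        double delta = (*d.elem)[bin] - before;
        if (delta == 0.0) return;
        if (side == SIDE_A) {
            int n = (int)(bin / model.K), k = (int)(bin % model.K);
            for (int j = 0; j < model.M; ++j)
                model.AP[(size_t)n * model.M + j] += delta * model.P[(size_t)k * model.M + j];
        } else {
            int k = (int)(bin / model.M), m = (int)(bin % model.M);
            for (int i = 0; i < model.N; ++i)
                model.AP[(size_t)i * model.M + m] += delta * model.A[(size_t)i * model.K + k];
        }
    }

    void evaluate(int side, const Prop &p) {
        AtomicDomain &d = dom(side);
        Rng er(seed, STREAM_EVAL, p.counter);
        const int nc = d.nCol;
        const int r1 = (int)(p.elem1 / nc), c1 = (int)(p.elem1 % nc);

        switch (p.kind) {
        case BIRTH: {
            const double cap = (side == SIDE_A) ? maxGibbsA : maxGibbsP;
            Cond cp = model.alphaParams(side, r1, c1);
            bool ok = false;
            double m = gibbsMass(cp, d.lambda, MASS_EPSILON, cap, er, ok);
            if (!ok) {
                // prior-driven fallback, Metropolis-corrected so a mass the
                // likelihood vetoes is not injected (exact when the
                // likelihood is flat: delta-LL is 0 and the draw is kept)
                double mp = truncExp(er, d.lambda, MASS_EPSILON, cap);
                double u = er.uniform();
                m = (std::log(u) < deltaLL(cp, mp)) ? mp : MASS_EPSILON;
            }
            double before = (*d.elem)[p.elem1];
            d.setMass(p.pos1, m);
            applyElemDelta(side, p.elem1, before);
            break;
        }
        case DEATH: {
            double before = (*d.elem)[p.elem1];
            d.erase(p.pos1);
            applyElemDelta(side, p.elem1, before);
            Cond cp = model.alphaParams(side, r1, c1);
            bool ok = false;
            double m = gibbsMass(cp, d.lambda, 0.0,
                                 (side == SIDE_A) ? maxGibbsA : maxGibbsP, er, ok);
            if (ok && m > MASS_EPSILON) {  // resurrected by the Gibbs draw
                before = (*d.elem)[p.elem1];
                d.insert(p.pos1, m);
                applyElemDelta(side, p.elem1, before);
            }
            break;
        }
        case MOVE: {
            double m = d.massAt(p.pos1);
            if (p.elem2 < 0) {  // within-bin: likelihood-neutral, always accept
                d.erase(p.pos1);
                d.insert(p.pos2, m);
                d.recomputeBin((uint64_t)p.elem1);
                break;
            }
            const int r2 = (int)(p.elem2 / nc), c2 = (int)(p.elem2 % nc);
            // +m on destination element, -m on source element
            Cond cp = model.exchangeParams(side, r2, c2, r1, c1);
            double u = er.uniform();
            if (std::log(u) < deltaLL(cp, m)) {
                double before = (*d.elem)[p.elem1];
                d.erase(p.pos1);
                applyElemDelta(side, p.elem1, before);
                before = (*d.elem)[p.elem2];
                d.insert(p.pos2, m);
                applyElemDelta(side, p.elem2, before);
            }
            break;
        }
        case EXCHANGE: {
            double m1 = d.massAt(p.pos1), m2 = d.massAt(p.pos2);
            if (p.elem2 < 0) {
                // same element: conditional of m1 given m1 + m2 under the
                // Exponential prior is uniform; likelihood unchanged
                double T = m1 + m2;
                double lo = MASS_EPSILON, hi = T - MASS_EPSILON;
                if (hi > lo) {
                    double m1p = lo + er.uniform() * (hi - lo);
                    d.setMass(p.pos1, m1p);
                    d.setMass(p.pos2, T - m1p);
                    d.recomputeBin((uint64_t)p.elem1);
                }
                break;
            }
            const int r2 = (int)(p.elem2 / nc), c2 = (int)(p.elem2 % nc);
            Cond cp = model.exchangeParams(side, r1, c1, r2, c2);  // +delta on elem1
            double lo = MASS_EPSILON - m1, hi = m2 - MASS_EPSILON;
            if (!(hi > lo)) break;
            bool ok = false;
            // the Exponential prior cancels for a transfer within one domain
            double delta = gibbsMass(cp, 0.0, lo, hi, er, ok);
            if (!ok) {
                // prior-driven fallback: uniform re-split + Metropolis
                double T = m1 + m2;
                double m1p = MASS_EPSILON + er.uniform() * (T - 2.0 * MASS_EPSILON);
                delta = m1p - m1;
                double u = er.uniform();
                if (!(std::log(u) < deltaLL(cp, delta))) break;
            }
            double before = (*d.elem)[p.elem1];
            d.setMass(p.pos1, m1 + delta);
            applyElemDelta(side, p.elem1, before);
            before = (*d.elem)[p.elem2];
            d.setMass(p.pos2, m2 - delta);
            applyElemDelta(side, p.elem2, before);
            break;
        }
        }
    }

    // evaluate the queue under a deterministic worker schedule (worker w takes
    // slots w, w+W, ...); proposals are mutually independent, so any schedule
    // yields bit-identical state
    void evalQueue(int side) {
        uint64_t lo = dom(side).size() - (uint64_t)pendingDeaths;
        uint64_t hi = dom(side).size();
        for (int w = 0; w < workers; ++w)
            for (size_t i = (size_t)w; i < queue.size(); i += (size_t)workers)
                evaluate(side, queue[i]);
        uint64_t now = dom(side).size();
        if (now < lo || now > hi) ++invariantViolations;
        ++nBatches;
        nQueuedTotal += (long long)queue.size();
    }

    // one phase: `budget` proposals generated with the sequential algorithm,
    // queued until a conflict/ambiguity or maxQueue, then batch-evaluated
    void runPhase(int side, long budget) {
        resetClaims(side);
        long done = 0;
        bool hasCarry = false;
        Prop carry;
        while (done < budget || hasCarry) {
            if (hasCarry) {
                regClaims(side, carry);
                queue.push_back(carry);
                hasCarry = false;
            }
            while ((long)queue.size() < maxQueue && done < budget) {
                Prop p;
                HeaderStatus st = genHeader(side, p);
                if (st == H_AMBIG) {
                    ++nAmbigFlush;
                    if (queue.empty())
                        throw std::logic_error("ambiguous header with empty queue");
                    break;
                }
                ++counter;
                ++done;
                if (st == H_NOOP) { ++nNoop; continue; }
                if (st == H_CONFLICT) {
                    carry = p;
                    hasCarry = true;
                    ++nConflictFlush;
                    break;
                }
                regClaims(side, p);
                queue.push_back(p);
            }
            if (!queue.empty()) evalQueue(side);
            resetClaims(side);
        }
    }
};

}  // namespace anmf

#endif
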