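#ifndef ATOMICNMF_MODEL_H
#define ATOMICNMF_MODEL_H

#include <vector>
#include <cstdint>
#include <cmath>
#include <stdexcept>

namespace anmf {

struct Cond {
    double s = 0.0;    // quadratic coefficient (precision)
    double smu = 0.0;  // linear coefficient (weighted residual projection)
};

inline double deltaLL(const Cond &c, double delta) {
    return c.smu * delta - c.s * delta * delta / 2.0;
}

enum Side { SIDE_A = 0, SIDE_P = 1 };

struct NzEntry {
    int idx;      // column (row view) or row (column view)
    double d;     // data value
    double sinv2; // 1 / S^2 at that entry
};

// Gaussian-likelihood state: D ~ N(AP, S^2).  Dense mode caches AP; sparse
// mode recomputes AP on the fly from the non-zero entries of D plus batch
// Gram precomputations, valid only under the default uncertainty rule
// (constant S = floor on every zero of D).
class Model {
public:
    int N = 0, M = 0, K = 0;
    std::vector<double> D, Sinv2;  // row-major N x M (dense storage of data)
    std::vector<double> A, P;      // row-major N x K, K x M
    std::vector<double> AP;        // row-major N x M, dense mode only
    bool sparseMode = false;
    double s0inv2 = 0.0;           // 1/floor^2 (sparse mode)
    std::vector<std::vector<NzEntry>> nzRow, nzCol;
    std::vector<double> G;         // K x K Gram of the frozen factor
    int gramSide = -1;             // side whose conditionals G serves
    double t = 1.0;                // temperature

    // cost instrumentation: multiply-add count inside conditional-parameter
    // calculations and number of calls, split by side (A-phase / P-phase)
    long long madOps = 0, nParamCalls = 0;
    long long madOpsSide[2] = {0, 0}, nCallsSide[2] = {0, 0};

    void countOps(int side, long long ops) {
        madOps += ops;
        madOpsSide[side] += ops;
    }

    void init(int n, int m, int k, const double *d, const double *sinv2,
              bool sparse, double floorS) {
        N = n; M = m; K = k;
        D.assign(d, d + (size_t)n * m);
        Sinv2.assign(sinv2, sinv2 + (size_t)n * m);
        A.assign((size_t)N * K, 0.0);
        P.assign((size_t)K * M, 0.0);
        sparseMode = sparse;
        if (sparseMode) {
            s0inv2 = 1.0 / (floorS * floorS);
            nzRow.assign(N, {});
            nzCol.assign(M, {});
            for (int i = 0; i < N; ++i)
                for (int j = 0; j < M; ++j) {
                    double v = D[(size_t)i * M + j];
                    if (v != 0.0) {
                        double si = Sinv2[(size_t)i * M + j];
                        nzRow[i].push_back({j, v, si});
                        nzCol[j].push_back({i, v, si});
                    }
                }
        } else {
            AP.assign((size_t)N * M, 0.0);
        }
    }

    void refreshAP() {
        if (sparseMode) return;
        for (int i = 0; i < N; ++i)
            for (int j = 0; j < M; ++j) {
                double s = 0.0;
                for (int l = 0; l < K; ++l)
                    s += A[(size_t)i * K + l] * P[(size_t)l * M + j];
                AP[(size_t)i * M + j] = s;
            }
    }

    double apAt(int i, int j) const {  // on-the-fly product entry
        double s = 0.0;
        for (int l = 0; l < K; ++l)
            s += A[(size_t)i * K + l] * P[(size_t)l * M + j];
        return s;
    }

    double chiSq() const {
        double total = 0.0;
        for (int i = 0; i < N; ++i)
            for (int j = 0; j < M; ++j) {
                double ap = sparseMode ? apAt(i, j) : AP[(size_t)i * M + j];
                double r = D[(size_t)i * M + j] - ap;
                total += r * r * Sinv2[(size_t)i * M + j];
            }
        return total;
    }

    // Gram of the factor frozen during a `side` phase: during an A-phase the
    // frozen factor is P (G[k,l] = sum_j P[k,j]P[l,j]); symmetric with A for
    // a P-phase.
    void precomputeGram(int side) {
        G.assign((size_t)K * K, 0.0);
        gramSide = side;
        if (side == SIDE_A) {
            for (int k = 0; k < K; ++k)
                for (int l = k; l < K; ++l) {
                    double s = 0.0;
                    for (int j = 0; j < M; ++j)
                        s += P[(size_t)k * M + j] * P[(size_t)l * M + j];
                    G[(size_t)k * K + l] = G[(size_t)l * K + k] = s;
                }
        } else {
            for (int k = 0; k < K; ++k)
                for (int l = k; l < K; ++l) {
                    double s = 0.0;
                    for (int i = 0; i < N; ++i)
                        s += A[(size_t)i * K + k] * A[(size_t)i * K + l];
                    G[(size_t)k * K + l] = G[(size_t)l * K + k] = s;
                }
        }
    }

    // single-element conditional parameters; element (r, c) of side's matrix
    // (A: (n, k); P: (k, m)); scaled by temperature
    Cond alphaParams(int side, int r, int c) {
        ++nParamCalls;
        ++nCallsSide[side];
        if (t == 0.0) return Cond{0.0, 0.0};
        Cond out = sparseMode ? alphaParamsSparse(side, r, c)
                              : alphaParamsDense(side, r, c);
        out.s *= t;
        out.smu *= t;
        return out;
    }

    Cond alphaParamsDense(int side, int r, int c) {
        Cond out;
        if (side == SIDE_A) {
            const int n = r, k = c;
            for (int j = 0; j < M; ++j) {
                double p = P[(size_t)k * M + j];
                double si = Sinv2[(size_t)n * M + j];
                double res = D[(size_t)n * M + j] - AP[(size_t)n * M + j];
                out.s += p * p * si;
                out.smu += p * res * si;
            }
            countOps(side, M);
        } else {
            const int k = r, m = c;
            for (int i = 0; i < N; ++i) {
                double a = A[(size_t)i * K + k];
                double si = Sinv2[(size_t)i * M + m];
                double res = D[(size_t)i * M + m] - AP[(size_t)i * M + m];
                out.s += a * a * si;
                out.smu += a * res * si;
            }
            countOps(side, N);
        }
        return out;
    }

    Cond alphaParamsSparse(int side, int r, int c) {
        Cond out;
        if (side == SIDE_A) {
            const int n = r, k = c;
            double sNz = 0, p2 = 0, smuNz = 0, pap = 0;
            for (const NzEntry &e : nzRow[n]) {
                double p = P[(size_t)k * M + e.idx];
                double ap = apAt(n, e.idx);
                sNz += p * p * e.sinv2;
                p2 += p * p;
                smuNz += p * (e.d - ap) * e.sinv2;
                pap += p * ap;
            }
            double ag = 0.0;
            for (int l = 0; l < K; ++l)
                ag += A[(size_t)n * K + l] * G[(size_t)l * K + k];
            out.s = sNz + (G[(size_t)k * K + k] - p2) * s0inv2;
            out.smu = smuNz - (ag - pap) * s0inv2;
            countOps(side, (long long)nzRow[n].size() * (K + 4) + K);
        } else {
            const int k = r, m = c;
            double sNz = 0, a2 = 0, smuNz = 0, aap = 0;
            for (const NzEntry &e : nzCol[m]) {
                double a = A[(size_t)e.idx * K + k];
                double ap = apAt(e.idx, m);
                sNz += a * a * e.sinv2;
                a2 += a * a;
                smuNz += a * (e.d - ap) * e.sinv2;
                aap += a * ap;
            }
            double gp = 0.0;
            for (int l = 0; l < K; ++l)
                gp += G[(size_t)k * K + l] * P[(size_t)l * M + m];
            out.s = sNz + (G[(size_t)k * K + k] - a2) * s0inv2;
            out.smu = smuNz - (gp - aap) * s0inv2;
            countOps(side, (long long)nzCol[m].size() * (K + 4) + K);
        }
        return out;
    }

    // two-element conditional for a perturbation delta * (e1 - e2), both
    // elements in side's matrix; scaled by temperature
    Cond exchangeParams(int side, int r1, int c1, int r2, int c2) {
        if (r1 == r2 && c1 == c2)
            throw std::runtime_error("degenerate pair: identical elements");
        if (t == 0.0) { ++nParamCalls; return Cond{0.0, 0.0}; }
        Cond c1p = alphaParams(side, r1, c1);
        Cond c2p = alphaParams(side, r2, c2);
        Cond out;
        out.smu = c1p.smu - c2p.smu;
        out.s = c1p.s + c2p.s;
        const bool sameData = (side == SIDE_A) ? (r1 == r2) : (c1 == c2);
        if (sameData) out.s -= 2.0 * t * crossTerm(side, r1, c1, r2, c2);
        return out;
    }

private:
    // sum over the shared data row/column of P[k1]P[k2]/S^2 (A side) or
    // A[.,k1]A[.,k2]/S^2 (P side); unscaled by temperature
    double crossTerm(int side, int r1, int c1, int r2, int c2) {
        if (side == SIDE_A) {
            const int n = r1, k1 = c1, k2 = c2;
            if (!sparseMode) {
                double s = 0.0;
                for (int j = 0; j < M; ++j)
                    s += P[(size_t)k1 * M + j] * P[(size_t)k2 * M + j] *
                         Sinv2[(size_t)n * M + j];
                madOps += M;
                return s;
            }
            double sNz = 0, pp = 0;
            for (const NzEntry &e : nzRow[n]) {
                double v = P[(size_t)k1 * M + e.idx] * P[(size_t)k2 * M + e.idx];
                sNz += v * e.sinv2;
                pp += v;
            }
            madOps += (long long)nzRow[n].size() * 3;
            return sNz + (G[(size_t)k1 * K + k2] - pp) * s0inv2;
        }
        const int m = c1, k1 = r1, k2 = r2;
        if (!sparseMode) {
            double s = 0.0;
            for (int i = 0; i < N; ++i)
                s += A[(size_t)i * K + k1] * A[(size_t)i * K + k2] *
                     Sinv2[(size_t)i * M + m];
            madOps += N;
            return s;
        }
        double sNz = 0, aa = 0;
        for (const NzEntry &e : nzCol[m]) {
            double v = A[(size_t)e.idx * K + k1] * A[(size_t)e.idx * K + k2];
            sNz += v * e.sinv2;
            aa += v;
        }
        madOps += (long long)nzCol[m].size() * 3;
        return sNz + (G[(size_t)k1 * K + k2] - aa) * s0inv2;
    }
};

}  // namespace anmf

#endif
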