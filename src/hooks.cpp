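#include <Rcpp.h>
#include "engine.h"

using namespace Rcpp;
using namespace anmf;

// R matrices are column-major; the engine stores row-major
static std::vector<double> rowMajor(const NumericMatrix &X) {
    const int n = X.nrow(), m = X.ncol();
    std::vector<double> v((size_t)n * m);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) v[(size_t)i * m + j] = X(i, j);
    return v;
}

static NumericMatrix fromRowMajor(const std::vector<double> &v, int n, int m) {
    NumericMatrix X(n, m);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) X(i, j) = v[(size_t)i * m + j];
    return X;
}

static std::vector<double> sinv2Of(const NumericMatrix &S) {
    const int n = S.nrow(), m = S.ncol();
    std::vector<double> v((size_t)n * m);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
            double s = S(i, j);
            v[(size_t)i * m + j] = 1.0 / (s * s);
        }
    return v;
}

static void setFactors(Model &mod, const NumericMatrix &A, const NumericMatrix &P) {
    mod.A = rowMajor(A);
    mod.P = rowMajor(P);
    if (!mod.sparseMode) mod.refreshAP();
}

// ---------------------------------------------------------------------------
// full factorization run
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(NumericMatrix D, NumericMatrix S, int K, int nEquil, int nSample,
             double seed, int maxQueue, int workers, bool sparse, double alpha,
             double lambdaA, double lambdaP, int snapshotStride,
             int refreshInterval, double floorS, double maxGibbsA,
             double maxGibbsP, bool verbose = false) {
    const int N = D.nrow(), M = D.ncol();
    Engine eng;
    eng.seed = (uint64_t)seed;
    eng.maxQueue = maxQueue;
    eng.workers = workers;
    eng.maxGibbsA = maxGibbsA;
    eng.maxGibbsP = maxGibbsP;
    std::vector<double> d = rowMajor(D), si = sinv2Of(S);
    eng.model.init(N, M, K, d.data(), si.data(), sparse, floorS);
    eng.domA = AtomicDomain(N, K, alpha, lambdaA, &eng.model.A);
    eng.domP = AtomicDomain(K, M, alpha, lambdaP, &eng.model.P);

    const double chisqBaseline = eng.model.chiSq();
    const long nIter = (long)nEquil + nSample;
    NumericVector chisqTrace(nIter);
    IntegerMatrix atomTrace(nIter, 2);
    std::vector<double> sumA((size_t)N * K, 0.0), ssqA((size_t)N * K, 0.0);
    std::vector<double> sumP((size_t)K * M, 0.0), ssqP((size_t)K * M, 0.0);
    long nSnap = 0;

    for (long it = 0; it < nIter; ++it) {
        const bool sampling = it >= nEquil;
        eng.model.t = sampling ? 1.0
                               : std::min(1.0, 2.0 * (double)it / (double)nEquil);
        if (eng.model.sparseMode) eng.model.precomputeGram(SIDE_A);
        long budA = Rng(eng.seed, STREAM_PHASE, (uint64_t)(2 * it))
                        .poisson(std::max((double)eng.domA.size(), 10.0));
        eng.runPhase(SIDE_A, budA);
        if (eng.model.sparseMode) eng.model.precomputeGram(SIDE_P);
        long budP = Rng(eng.seed, STREAM_PHASE, (uint64_t)(2 * it + 1))
                        .poisson(std::max((double)eng.domP.size(), 10.0));
        eng.runPhase(SIDE_P, budP);
        if (!eng.model.sparseMode && refreshInterval > 0 &&
            (it + 1) % refreshInterval == 0)
            eng.model.refreshAP();
        chisqTrace[it] = eng.model.chiSq();
        atomTrace(it, 0) = (int)eng.domA.size();
        atomTrace(it, 1) = (int)eng.domP.size();
        if (sampling && ((it - nEquil + 1) % snapshotStride == 0)) {
            ++nSnap;
            for (size_t q = 0; q < sumA.size(); ++q) {
                sumA[q] += eng.model.A[q];
                ssqA[q] += eng.model.A[q] * eng.model.A[q];
            }
            for (size_t q = 0; q < sumP.size(); ++q) {
                sumP[q] += eng.model.P[q];
                ssqP[q] += eng.model.P[q] * eng.model.P[q];
            }
        }
        if (verbose && ((it + 1) % 100 == 0 || it + 1 == nIter))
            Rcout << "iter " << (it + 1) << "/" << nIter
                  << "  chisq " << chisqTrace[it]
                  << "  atoms " << eng.domA.size() << "/" << eng.domP.size()
                  << "  mean batch "
                  << (eng.nBatches ? (double)eng.nQueuedTotal / eng.nBatches : 0.0)
                  << "\n";
        Rcpp::checkUserInterrupt();
    }

    auto summarize = [&](std::vector<double> &sum, std::vector<double> &ssq,
                         int nr, int nc, NumericMatrix &mean, NumericMatrix &sd) {
        std::vector<double> mv(sum.size()), sv(sum.size(), 0.0);
        for (size_t q = 0; q < sum.size(); ++q) {
            mv[q] = sum[q] / (double)nSnap;
            if (nSnap > 1) {
                double var = (ssq[q] - (double)nSnap * mv[q] * mv[q]) /
                             (double)(nSnap - 1);
                sv[q] = std::sqrt(std::max(0.0, var));
            }
        }
        mean = fromRowMajor(mv, nr, nc);
        sd = fromRowMajor(sv, nr, nc);
    };
    NumericMatrix Amean, Asd, Pmean, Psd;
    if (nSnap == 0) stop("no samples recorded");
    summarize(sumA, ssqA, N, K, Amean, Asd);
    summarize(sumP, ssqP, K, M, Pmean, Psd);

    return List::create(
        _["Amean"] = Amean, _["Asd"] = Asd, _["Pmean"] = Pmean, _["Psd"] = Psd,
        _["chisqTrace"] = chisqTrace, _["atomTrace"] = atomTrace,
        _["diagnostics"] = List::create(
            _["chisqBaseline"] = chisqBaseline,
            _["chisqFinal"] = chisqTrace[nIter - 1],
            _["nProposals"] = (double)eng.counter,
            _["nParamCalls"] = (double)eng.model.nParamCalls,
            _["madOps"] = (double)eng.model.madOps,
            _["madOpsA"] = (double)eng.model.madOpsSide[0],
            _["madOpsP"] = (double)eng.model.madOpsSide[1],
            _["nCallsA"] = (double)eng.model.nCallsSide[0],
            _["nCallsP"] = (double)eng.model.nCallsSide[1],
            _["nBatches"] = (double)eng.nBatches,
            _["meanBatchSize"] =
                eng.nBatches ? (double)eng.nQueuedTotal / (double)eng.nBatches : 0.0,
            _["nAmbigFlush"] = (double)eng.nAmbigFlush,
            _["nConflictFlush"] = (double)eng.nConflictFlush,
            _["nCapNoop"] = (double)eng.nCapNoop,
            _["invariantViolations"] = (double)eng.invariantViolations,
            _["nSnapshots"] = (double)nSnap));
}

// ---------------------------------------------------------------------------
// flat-likelihood chain on a single atomic domain (prior recovery)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_prior_chain(int nRow, int nCol, double alpha, double lambda,
                     int nOuter, int burn, int massStride, int maxMasses,
                     double seed, int maxQueue, int workers) {
    Engine eng;
    eng.seed = (uint64_t)seed;
    eng.maxQueue = maxQueue;
    eng.workers = workers;
    eng.maxGibbsA = 100.0 / lambda;
    std::vector<double> d((size_t)nRow, 0.0), si((size_t)nRow, 1.0);
    eng.model.init(nRow, 1, nCol, d.data(), si.data(), false, 0.1);
    eng.model.t = 0.0;  // likelihood terms forced to zero
    eng.domA = AtomicDomain(nRow, nCol, alpha, lambda, &eng.model.A);

    IntegerVector countTrace(nOuter);
    std::vector<double> masses;
    // state-independent budgets: sampling the chain at stopping times that
    // depend on the atom count length-biases the recorded distribution
    const double budMean = std::max(alpha * nRow * nCol, 10.0);
    for (int it = 0; it < nOuter; ++it) {
        long bud = Rng(eng.seed, STREAM_PHASE, (uint64_t)it).poisson(budMean);
        eng.runPhase(SIDE_A, bud);
        countTrace[it] = (int)eng.domA.size();
        if (it >= burn && (it - burn) % massStride == 0 &&
            (int)masses.size() < maxMasses)
            for (const Atom &a : eng.domA.atoms) masses.push_back(a.mass);
        if (it % 64 == 0) Rcpp::checkUserInterrupt();
    }
    if ((int)masses.size() > maxMasses) masses.resize(maxMasses);
    return List::create(_["countTrace"] = countTrace,
                        _["masses"] = NumericVector(masses.begin(), masses.end()),
                        _["invariantViolations"] = (double)eng.invariantViolations,
                        _["totalMass"] = eng.domA.totalMass());
}

// ---------------------------------------------------------------------------
// likelihood-math hooks
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_chi_squared(NumericMatrix D, NumericMatrix S, NumericMatrix A,
                       NumericMatrix P, bool sparse = false, double floorS = 0.1) {
    Model mod;
    std::vector<double> d = rowMajor(D), si = sinv2Of(S);
    mod.init(D.nrow(), D.ncol(), A.ncol(), d.data(), si.data(), sparse, floorS);
    setFactors(mod, A, P);
    return mod.chiSq();
}

static Model gridModel(const NumericMatrix &D, const NumericMatrix &S,
                       const NumericMatrix &A, const NumericMatrix &P,
                       double t, bool sparse, double floorS) {
    Model mod;
    std::vector<double> d = rowMajor(D), si = sinv2Of(S);
    mod.init(D.nrow(), D.ncol(), A.ncol(), d.data(), si.data(), sparse, floorS);
    mod.t = t;
    setFactors(mod, A, P);
    return mod;
}

// conditional parameters for every element of A and of P
// [[Rcpp::export]]
List cpp_params_grid(NumericMatrix D, NumericMatrix S, NumericMatrix A,
                     NumericMatrix P, double t, bool sparse, double floorS) {
    Model mod = gridModel(D, S, A, P, t, sparse, floorS);
    const int N = mod.N, M = mod.M, K = mod.K;
    NumericMatrix sA(N, K), smuA(N, K), sP(K, M), smuP(K, M);
    if (sparse) mod.precomputeGram(SIDE_A);
    for (int n = 0; n < N; ++n)
        for (int k = 0; k < K; ++k) {
            Cond c = mod.alphaParams(SIDE_A, n, k);
            sA(n, k) = c.s;
            smuA(n, k) = c.smu;
        }
    if (sparse) mod.precomputeGram(SIDE_P);
    for (int k = 0; k < K; ++k)
        for (int m = 0; m < M; ++m) {
            Cond c = mod.alphaParams(SIDE_P, k, m);
            sP(k, m) = c.s;
            smuP(k, m) = c.smu;
        }
    return List::create(_["sA"] = sA, _["smuA"] = smuA, _["sP"] = sP,
                        _["smuP"] = smuP);
}

// [[Rcpp::export]]
NumericVector cpp_exchange_params(NumericMatrix D, NumericMatrix S,
                                  NumericMatrix A, NumericMatrix P, double t,
                                  int side, int r1, int c1, int r2, int c2,
                                  bool sparse, double floorS) {
    Model mod = gridModel(D, S, A, P, t, sparse, floorS);
    if (sparse) mod.precomputeGram(side);
    Cond c = mod.exchangeParams(side, r1, c1, r2, c2);
    return NumericVector::create(c.s, c.smu);
}

// [[Rcpp::export]]
NumericMatrix cpp_gram(NumericMatrix F) {
    // Gram G = F F^T of a frozen K x M factor
    Model mod;
    const int K = F.nrow(), M = F.ncol();
    std::vector<double> d((size_t)M, 0.0), si((size_t)M, 1.0);
    mod.init(1, M, K, d.data(), si.data(), false, 0.1);
    mod.P = rowMajor(F);
    mod.precomputeGram(SIDE_A);
    return fromRowMajor(mod.G, K, K);
}

// draws (NA on rejection) from the Gibbs conditional mass kernel
// [[Rcpp::export]]
NumericVector cpp_gibbs_mass(double s, double smu, double lambda, double lo,
                             double hi, double seed, int n) {
    Cond cp{s, smu};
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        Rng rng((uint64_t)seed, STREAM_HOOK, (uint64_t)i);
        bool ok = false;
        double v = gibbsMass(cp, lambda, lo, hi, rng, ok);
        out[i] = ok ? v : NA_REAL;
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_poisson_sample(double mean, double seed, int n) {
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        Rng rng((uint64_t)seed, STREAM_HOOK, (uint64_t)i);
        out[i] = rng.poisson(mean);
    }
    return out;
}

// probability that a death proposal resurrects its atom: repeat the death
// kernel from identical model state under nTrials evaluation substreams
// [[Rcpp::export]]
double cpp_death_resurrection_rate(NumericMatrix D, NumericMatrix S,
                                   NumericMatrix A, NumericMatrix P, double t,
                                   double lambda, int side, int r, int c,
                                   double mass, double seed, int nTrials) {
    int resurrected = 0;
    for (int i = 0; i < nTrials; ++i) {
        Model mod = gridModel(D, S, A, P, t, false, 0.1);
        // remove the atom's mass from element (r, c)
        if (side == SIDE_A)
            mod.A[(size_t)r * mod.K + c] -= mass;
        else
            mod.P[(size_t)r * mod.M + c] -= mass;
        mod.refreshAP();
        Cond cp = mod.alphaParams(side, r, c);
        Rng er((uint64_t)seed, STREAM_EVAL, (uint64_t)i);
        bool ok = false;
        double m = gibbsMass(cp, lambda, 0.0, INFINITY, er, ok);
        if (ok && m > MASS_EPSILON) ++resurrected;
    }
    return (double)resurrected / (double)nTrials;
}

// ---------------------------------------------------------------------------
// atomic-domain handle hooks (unit tests)
// ---------------------------------------------------------------------------

struct DomainHandle {
    std::vector<double> elem;
    AtomicDomain d;
};

// [[Rcpp::export]]
SEXP ad_new(int nRow, int nCol, double alpha, double lambda,
            double binSize = 0) {
    XPtr<DomainHandle> h(new DomainHandle(), true);
    h->d = AtomicDomain(nRow, nCol, alpha, lambda, &h->elem,
                        (uint64_t)binSize);
    return h;
}

static DomainHandle *get(SEXP p) { return XPtr<DomainHandle>(p).get(); }

// [[Rcpp::export]]
void ad_insert(SEXP p, double pos, double mass) {
    DomainHandle *h = get(p);
    if (mass <= 0) stop("mass must be positive");
    if ((uint64_t)pos >= h->d.usable) stop("position out of range");
    try {
        h->d.insert((uint64_t)pos, mass);
    } catch (const std::exception &e) {
        stop(e.what());
    }
    h->d.recomputeBin(h->d.binOf((uint64_t)pos));
}

// [[Rcpp::export]]
double ad_erase(SEXP p, double pos) {
    DomainHandle *h = get(p);
    double m;
    try {
        m = h->d.erase((uint64_t)pos);
    } catch (const std::exception &e) {
        stop(e.what());
    }
    h->d.recomputeBin(h->d.binOf((uint64_t)pos));
    return m;
}

// [[Rcpp::export]]
List ad_atoms(SEXP p) {
    DomainHandle *h = get(p);
    NumericVector pos(h->d.size()), mass(h->d.size());
    for (size_t i = 0; i < h->d.size(); ++i) {
        pos[i] = (double)h->d.atoms[i].pos;
        mass[i] = h->d.atoms[i].mass;
    }
    return List::create(_["pos"] = pos, _["mass"] = mass);
}

// [[Rcpp::export]]
NumericMatrix ad_values(SEXP p) {
    DomainHandle *h = get(p);
    return fromRowMajor(h->elem, h->d.nRow, h->d.nCol);
}

// [[Rcpp::export]]
IntegerVector ad_element_of(SEXP p, double pos) {
    DomainHandle *h = get(p);
    int r, c;
    try {
        h->d.elementOf((uint64_t)pos, r, c);
    } catch (const std::exception &e) {
        stop(e.what());
    }
    return IntegerVector::create(r, c);
}

// [[Rcpp::export]]
NumericVector ad_random_free(SEXP p, double seed, int n) {
    DomainHandle *h = get(p);
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        Rng rng((uint64_t)seed, STREAM_HOOK, (uint64_t)i);
        out[i] = (double)h->d.randomFreePosition(rng);
    }
    return out;
}

// [[Rcpp::export]]
NumericVector ad_random_atom(SEXP p, double seed, int n) {
    DomainHandle *h = get(p);
    if (h->d.size() == 0) stop("empty domain");
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        Rng rng((uint64_t)seed, STREAM_HOOK, (uint64_t)i);
        out[i] = (double)h->d.atoms[h->d.randomAtomIndex(rng)].pos;
    }
    return out;
}

// [[Rcpp::export]]
NumericVector ad_right_neighbor(SEXP p, double pos) {
    DomainHandle *h = get(p);
    long i;
    try {
        i = h->d.rightNeighborIndex((uint64_t)pos);
    } catch (const std::exception &e) {
        stop(e.what());
    }
    if (i < 0) return NumericVector::create(NA_REAL, NA_REAL);
    return NumericVector::create((double)h->d.atoms[i].pos, h->d.atoms[i].mass);
}

// max |elem - fresh bin sums| (consistency of incremental maintenance)
// [[Rcpp::export]]
double ad_check(SEXP p) {
    DomainHandle *h = get(p);
    std::vector<double> fresh(h->d.nBins, 0.0);
    for (const Atom &a : h->d.atoms) fresh[h->d.binOf(a.pos)] += a.mass;
    double worst = 0.0;
    for (size_t i = 0; i < fresh.size(); ++i)
        worst = std::max(worst, std::fabs(fresh[i] - h->elem[i]));
    return worst;
}

// [[Rcpp::export]]
double ad_total_mass(SEXP p) { return get(p)->d.totalMass(); }
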