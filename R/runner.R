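#' Atomic-prior Bayesian NMF by asynchronous Gibbs sampling
#'
#' Factors a non-negative genes x cells matrix \eqn{D} into \eqn{A} (genes x
#' patterns) and \eqn{P} (patterns x cells) under the Gaussian likelihood
#' \eqn{D \sim N(AP, S^2)} with the atomic prior: each element of \eqn{A} and
#' \eqn{P} is the bin-sum of point masses on a one-dimensional domain, atom
#' counts Poisson(\code{alpha} per element) and masses Exponential(lambda), so
#' every element is marginally Gamma with a Poisson-distributed shape.  The
#' chain alternates A- and P-phases; within a phase, birth/death/move/exchange
#' proposals are generated sequentially and accumulated into a queue of
#' mutually independent proposals that is evaluated in batch -- the result is
#' bit-identical to the sequential chain for any \code{maxQueue} and
#' \code{nWorkers}.
#'
#' With \code{sparse = TRUE} the conditional-update sums are decomposed into
#' non-zero-data terms plus Gram-matrix terms precomputed once per phase, so
#' the per-proposal cost is proportional to the number of non-zero entries;
#' this requires the default uncertainty rule (constant \eqn{S} on zeros).
#'
#' @param data non-negative numeric matrix (genes x cells), or a
#'   [SimulatedNmfData-class].
#' @param nPatterns number of patterns K (\code{<= min(dim(data))}).
#' @param uncertainty optional explicit uncertainty matrix S (disallowed in
#'   sparse mode).
#' @param uncertaintyScale,uncertaintyFloor parameters of the default rule
#'   \eqn{S = max(scale \cdot D, floor)}.
#' @param nEquil,nSample equilibration and sampling outer iterations
#'   (\code{nSample >= 1}).
#' @param seed integer seed; runs are byte-reproducible given the full
#'   configuration.
#' @param sparse use the sparse conditional-update path.
#' @param maxQueue maximum proposals per asynchronous batch (1 = pure
#'   sequential).
#' @param nWorkers evaluation schedule width; any value yields bit-identical
#'   results (order-independence is the point of the queue).
#' @param alpha expected atoms per matrix element (sparsity of the prior).
#' @param lambda rate of the Exponential atom-mass prior; default
#'   \code{alpha * sqrt(nPatterns / mean(data))} for both domains.
#' @param maxGibbsMass upper truncation (in mass units) of conditional mass
#'   draws; default \code{100 / lambda} per domain.
#' @param snapshotStride record every \code{snapshotStride}-th sampling
#'   iteration.
#' @param refreshInterval dense mode: rebuild the cached AP product from
#'   scratch every this many outer iterations to bound floating-point drift.
#' @param verbose print chi-squared and atom counts every 100 iterations.
#' @return an [AtomicNmfResult-class].
#' @examples
#' sim <- simulateNmfData(30, 20, 2, seed = 1)
#' res <- atomicNMF(simulatedCounts(sim), 2, nEquil = 200, nSample = 100,
#'                  seed = 1)
#' res
#' @export
atomicNMF <- function(data, nPatterns, uncertainty = NULL,
                      uncertaintyScale = 0.1, uncertaintyFloor = 0.1,
                      nEquil = 1000, nSample = 1000, seed = 1, sparse = FALSE,
                      maxQueue = 64, nWorkers = 1, alpha = 0.01, lambda = NULL,
                      maxGibbsMass = NULL, snapshotStride = 1,
                      refreshInterval = 100, verbose = FALSE) {
    if (is(data, "SimulatedNmfData")) data <- simulatedCounts(data)
    stopifnot(is.matrix(data), is.numeric(data))
    if (any(!is.finite(data)) || any(data < 0))
        stop("data must be finite and non-negative")
    N <- nrow(data); M <- ncol(data)
    if (nPatterns < 1 || nPatterns > min(N, M))
        stop("nPatterns must be in [1, min(nrow, ncol)]")
    if (nSample < 1) stop("nSample must be >= 1")
    if (nEquil < 1) stop("nEquil must be >= 1")
    if (snapshotStride < 1 || snapshotStride > nSample)
        stop("snapshotStride must be in [1, nSample]")
    if (sparse && !is.null(uncertainty))
        stop("sparse mode requires the default uncertainty rule; ",
             "an explicit uncertainty matrix is unsupported")
    S <- makeUncertainty(data, uncertaintyScale, uncertaintyFloor, uncertainty)
    if (is.null(lambda)) {
        mD <- mean(data)
        if (mD <= 0) stop("data is identically zero")
        lambda <- alpha * sqrt(nPatterns / mD)
    }
    lambda <- rep_len(lambda, 2)  # (A, P) rates
    if (is.null(maxGibbsMass)) maxGibbsMass <- 100 / lambda
    maxGibbsMass <- rep_len(maxGibbsMass, 2)

    raw <- cpp_run(data, S, as.integer(nPatterns), as.integer(nEquil),
                   as.integer(nSample), as.numeric(seed),
                   as.integer(maxQueue), as.integer(nWorkers), sparse,
                   alpha, lambda[1], lambda[2], as.integer(snapshotStride),
                   as.integer(refreshInterval), uncertaintyFloor,
                   maxGibbsMass[1], maxGibbsMass[2], isTRUE(verbose))

    gn <- rownames(data); if (is.null(gn)) gn <- paste0("gene", seq_len(N))
    cn <- colnames(data); if (is.null(cn)) cn <- paste0("cell", seq_len(M))
    pn <- paste0("Pattern_", seq_len(nPatterns))
    dimnames(raw$Amean) <- dimnames(raw$Asd) <- list(gn, pn)
    dimnames(raw$Pmean) <- dimnames(raw$Psd) <- list(pn, cn)
    colnames(raw$atomTrace) <- c("atomsA", "atomsP")

    cfg <- list(nPatterns = nPatterns, nEquil = nEquil, nSample = nSample,
                sparse = sparse, maxQueue = maxQueue, nWorkers = nWorkers,
                alpha = alpha, lambdaA = lambda[1], lambdaP = lambda[2],
                uncertaintyScale = uncertaintyScale,
                uncertaintyFloor = uncertaintyFloor,
                maxGibbsMassA = maxGibbsMass[1],
                maxGibbsMassP = maxGibbsMass[2],
                explicitUncertainty = !is.null(uncertainty),
                snapshotStride = snapshotStride,
                refreshInterval = refreshInterval)
    new("AtomicNmfResult", Amean = raw$Amean, Asd = raw$Asd,
        Pmean = raw$Pmean, Psd = raw$Psd,
        chisqTrace = as.numeric(raw$chisqTrace), atomTrace = raw$atomTrace,
        seed = as.numeric(seed), config = cfg, diagnostics = raw$diagnostics)
}

#' Flat-likelihood chain over one atomic domain
#'
#' Runs the full proposal machinery (birth/death/move/exchange, asynchronous
#' queue) with the likelihood terms forced to zero, so the stationary law is
#' the atomic prior itself: atom count Poisson(\code{alpha * nRow * nCol}),
#' masses iid Exponential(\code{lambda}).  Used to validate the kernels
#' jointly.
#'
#' @param nRow,nCol shape of the bound matrix (number of bins = nRow * nCol).
#' @param alpha expected atoms per element.
#' @param lambda Exponential mass rate.
#' @param nIter outer iterations (each runs a Poisson-sized proposal budget).
#' @param burn iterations discarded before pooling masses.
#' @param massStride pool atom masses every this many post-burn iterations.
#' @param maxMasses cap on pooled masses.
#' @param seed,maxQueue,nWorkers as in [atomicNMF()].
#' @return list with \code{countTrace} (atom count per iteration),
#'   \code{masses} (pooled atom masses), \code{invariantViolations}, and
#'   \code{totalMass}.
#' @export
samplePriorChain <- function(nRow, nCol, alpha = 0.25, lambda = 1,
                             nIter = 2000, burn = 200, massStride = 20,
                             maxMasses = 5000, seed = 1, maxQueue = 64,
                             nWorkers = 1) {
    cpp_prior_chain(as.integer(nRow), as.integer(nCol), alpha, lambda,
                    as.integer(nIter), as.integer(burn),
                    as.integer(massStride), as.integer(maxMasses),
                    as.numeric(seed), as.integer(maxQueue),
                    as.integer(nWorkers))
}

#' Hardware-independent cost proxy for dense vs sparse updates
#'
#' Runs short factorizations over a grid of simulated datasets and records the
#' multiply-add count inside conditional-parameter calculations -- a
#' hardware-independent proxy for per-proposal cost.  In dense mode the
#' per-call cost is fixed by the matrix shape; in sparse mode it is
#' proportional to the number of non-zero data entries touched.
#'
#' @param nGenes number of genes (fixed across the grid).
#' @param nCells vector of cell counts.
#' @param sparsity vector of target zero fractions.
#' @param nPatterns,depth simulation parameters.
#' @param nEquil,nSample run length of each benchmark run.
#' @param seed base seed.
#' @param modes subset of \code{c("dense", "sparse")}.
#' @return data.frame with one row per (cells, sparsity, mode): total
#'   \code{madOps}, \code{nParamCalls}, \code{nProposals}, the per-call and
#'   per-proposal proxies, and the per-call proxies split by phase
#'   (\code{opsPerCallA} sums over cells, \code{opsPerCallP} over genes).
#' @export
proposalCostBenchmark <- function(nGenes = 150, nCells = 200, sparsity = 0.8,
                                  nPatterns = 3, depth = 10, nEquil = 30,
                                  nSample = 30, seed = 1,
                                  modes = c("dense", "sparse")) {
    grid <- expand.grid(nCells = nCells, sparsity = sparsity, mode = modes,
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        g <- grid[i, ]
        sim <- simulateNmfData(nGenes, g$nCells, nPatterns,
                               sparsity = g$sparsity, depth = depth,
                               seed = seed + 13 * i)
        res <- atomicNMF(simulatedCounts(sim), nPatterns, nEquil = nEquil,
                         nSample = nSample, seed = seed,
                         sparse = (g$mode == "sparse"))
        d <- nmfDiagnostics(res)
        data.frame(nGenes = nGenes, nCells = g$nCells, sparsity = g$sparsity,
                   realizedSparsity = realizedSparsity(sim), mode = g$mode,
                   madOps = d$madOps, nParamCalls = d$nParamCalls,
                   nProposals = d$nProposals,
                   opsPerCall = d$madOps / d$nParamCalls,
                   opsPerProposal = d$madOps / d$nProposals,
                   opsPerCallA = d$madOpsA / d$nCallsA,
                   opsPerCallP = d$madOpsP / d$nCallsP)
    })
    do.call(rbind, rows)
}
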