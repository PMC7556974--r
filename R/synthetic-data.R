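# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Simulate ground-truth NMF factors
#'
#' Builds a known non-negative factor pair.  Pattern matrix rows are smooth
#' activity bumps over the cells: pattern \eqn{k} is a Gaussian bump centred
#' on a contiguous block of roughly \eqn{M/K} cells, plus a small constant
#' baseline so every cell has positive total activity.  Amplitude entries are
#' Gamma(shape 2, scale 1) draws with a fraction of entries per pattern set to
#' zero (marker structure); every gene keeps at least one active pattern.
#'
#' @param nGenes,nCells,nPatterns dimensions (\code{nPatterns <= min(nGenes,
#'   nCells)}).
#' @param seed integer seed; the output is a deterministic function of it.
#' @param markerFraction fraction of amplitude entries zeroed per pattern
#'   (default 0.7).
#' @param baseline constant added to every pattern row (default 0.1).
#' @return list with matrices \code{Atrue} (genes x patterns) and \code{Ptrue}
#'   (patterns x cells).
#' @export
simulateFactors <- function(nGenes, nCells, nPatterns, seed = 1,
                            markerFraction = 0.7, baseline = 0.1) {
    stopifnot(nPatterns >= 1, nPatterns <= min(nGenes, nCells))
    .withSeed(seed, {
        centers <- (seq_len(nPatterns) - 0.5) * nCells / nPatterns
        width <- nCells / (2 * nPatterns)
        P <- t(vapply(seq_len(nPatterns), function(k)
            exp(-((seq_len(nCells) - centers[k])^2) / (2 * width^2)) + baseline,
            numeric(nCells)))
        A <- matrix(stats::rgamma(nGenes * nPatterns, shape = 2, scale = 1),
                    nGenes, nPatterns)
        for (k in seq_len(nPatterns)) {
            off <- sample.int(nGenes, round(markerFraction * nGenes))
            A[off, k] <- 0
        }
        dead <- which(rowSums(A) == 0)
        for (i in dead)  # keep every gene attached to one pattern
            A[i, sample.int(nPatterns, 1)] <- stats::rgamma(1, 2, scale = 1)
        dimnames(A) <- list(paste0("gene", seq_len(nGenes)),
                            paste0("Pattern_", seq_len(nPatterns)))
        dimnames(P) <- list(paste0("Pattern_", seq_len(nPatterns)),
                            paste0("cell", seq_len(nCells)))
        list(Atrue = A, Ptrue = P)
    })
}

#' Simulate sparse counts around known factors
#'
#' Draws \eqn{D_{nj} \sim Poisson(depth \cdot (A_{true}P_{true})_{nj})} and
#' then applies entrywise-independent dropout whose probability is logistic in
#' the log mean (low-expression entries drop out preferentially, the
#' zero-inflation mechanism of droplet single-cell simulators):
#' \deqn{\pi_{nj} = 1 / (1 + \exp(k (\log \lambda_{nj} - x_0)))}
#' with slope \eqn{k = 2}.  The midpoint \eqn{x_0} is calibrated by bisection
#' against the realized zero fraction so it hits \code{sparsityTarget} to
#' within the granularity of the matrix.  Deterministic given \code{seed}.
#'
#' @param truth list with \code{Atrue}, \code{Ptrue} (from
#'   [simulateFactors()]).
#' @param depth positive mean scaling.
#' @param sparsityTarget desired zero fraction in \code{[0, 1)}, or \code{NA}
#'   for no dropout.
#' @param seed integer seed.
#' @param dropoutSlope logistic slope \eqn{k} (default 2).
#' @return list with \code{counts}, \code{dropoutMid} (calibrated \eqn{x_0}),
#'   \code{dropoutRate} (mean dropout probability), \code{expectedMean}
#'   (\eqn{mean(\lambda (1 - \pi))}, the analytic mean of the emitted counts),
#'   and \code{realizedSparsity}.
#' @export
simulateCounts <- function(truth, depth = 10, sparsityTarget = NA, seed = 1,
                           dropoutSlope = 2) {
    stopifnot(depth > 0)
    .withSeed(seed, {
        lam <- depth * (truth$Atrue %*% truth$Ptrue)
        D0 <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam),
                     dimnames = dimnames(lam))
        if (is.na(sparsityTarget)) {
            return(list(counts = D0, dropoutMid = -Inf, dropoutRate = 0,
                        expectedMean = mean(lam),
                        realizedSparsity = mean(D0 == 0)))
        }
        base <- mean(D0 == 0)
        if (base > sparsityTarget + 0.03)
            stop(sprintf(
                "sparsity target %.2f unreachable: counts are already %.2f sparse",
                sparsityTarget, base))
        U <- matrix(stats::runif(length(D0)), nrow(D0), ncol(D0))
        logLam <- log(pmax(lam, 1e-12))
        dropProb <- function(x0) 1 / (1 + exp(dropoutSlope * (logLam - x0)))
        realized <- function(x0) mean(D0 == 0 | U < dropProb(x0))
        lo <- min(logLam) - 20; hi <- max(logLam) + 20
        for (i in 1:60) {
            mid <- (lo + hi) / 2
            if (realized(mid) < sparsityTarget) lo <- mid else hi <- mid
        }
        x0 <- hi
        pi <- dropProb(x0)
        D <- D0 * (U >= pi)
        list(counts = D, dropoutMid = x0, dropoutRate = mean(pi),
             expectedMean = mean(lam * (1 - pi)),
             realizedSparsity = mean(D == 0))
    })
}

#' Simulate a sparse single-cell-like dataset with known factors
#'
#' Combines [simulateFactors()] and [simulateCounts()] into a
#' [SimulatedNmfData-class] object, emulating the statistical structure of
#' droplet single-cell counts: a non-negative low-rank mean, Poisson counts,
#' and zero inflation at a controlled level.
#'
#' @inheritParams simulateFactors
#' @inheritParams simulateCounts
#' @param sparsity target zero fraction (\code{NA} = Poisson zeros only).
#' @return a [SimulatedNmfData-class].
#' @examples
#' sim <- simulateNmfData(50, 40, 2, sparsity = 0.7, seed = 1)
#' realizedSparsity(sim)
#' @export
simulateNmfData <- function(nGenes, nCells, nPatterns, sparsity = NA,
                            depth = 10, seed = 1) {
    truth <- simulateFactors(nGenes, nCells, nPatterns, seed = seed)
    cnt <- simulateCounts(truth, depth = depth, sparsityTarget = sparsity,
                          seed = seed + 1000003L)
    new("SimulatedNmfData", counts = cnt$counts, Atrue = truth$Atrue,
        Ptrue = truth$Ptrue, depth = depth,
        sparsityTarget = as.numeric(sparsity),
        realizedSparsity = cnt$realizedSparsity,
        dropoutRate = cnt$dropoutRate, seed = as.numeric(seed))
}

#' Standard simulated test fixtures
#'
#' A fixed family of simulated datasets used throughout the package's tests
#' and benchmarks, regenerated deterministically from their seeds:
#' \describe{
#'   \item{tiny}{20 x 15, K = 2, no dropout.}
#'   \item{recovery}{200 x 100, K = 3, 20\% zeros (pattern-recovery runs).}
#'   \item{sparse70/sparse80/sparse90}{200 x 200, K = 3, at 70/80/90\% zeros.}
#' }
#'
#' @param name fixture name.
#' @param seed base seed (default 7; fixtures differ by fixed offsets).
#' @return a [SimulatedNmfData-class].
#' @export
nmfFixture <- function(name = c("tiny", "recovery", "sparse70", "sparse80",
                                "sparse90"), seed = 7) {
    name <- match.arg(name)
    switch(name,
        tiny = simulateNmfData(20, 15, 2, sparsity = NA, depth = 10,
                               seed = seed),
        recovery = simulateNmfData(200, 100, 3, sparsity = 0.2, depth = 10,
                                   seed = seed + 1),
        sparse70 = simulateNmfData(200, 200, 3, sparsity = 0.70, depth = 10,
                                   seed = seed + 2),
        sparse80 = simulateNmfData(200, 200, 3, sparsity = 0.80, depth = 10,
                                   seed = seed + 3),
        sparse90 = simulateNmfData(200, 200, 3, sparsity = 0.90, depth = 10,
                                   seed = seed + 4))
}

#' Match estimated patterns to ground truth by cosine similarity
#'
#' One-to-one assignment of estimated pattern rows to true pattern rows
#' maximizing the mean cosine similarity (all permutations enumerated; K is
#' small).
#'
#' @param Pest,Ptrue matrices with one pattern per row and matching column
#'   count.
#' @return list with \code{assignment} (index of the true pattern matched to
#'   each estimated row), \code{cosines}, and \code{meanCosine}.
#' @export
matchPatterns <- function(Pest, Ptrue) {
    stopifnot(nrow(Pest) == nrow(Ptrue), ncol(Pest) == ncol(Ptrue))
    K <- nrow(Pest)
    cosine <- function(x, y) {
        nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
        if (nx == 0 || ny == 0) return(0)
        sum(x * y) / (nx * ny)
    }
    C <- outer(seq_len(K), seq_len(K),
               Vectorize(function(i, j) cosine(Pest[i, ], Ptrue[j, ])))
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
        out
    }
    best <- NULL; bestScore <- -Inf
    for (p in perms(seq_len(K))) {
        sc <- mean(C[cbind(seq_len(K), p)])
        if (sc > bestScore) { bestScore <- sc; best <- p }
    }
    list(assignment = best, cosines = C[cbind(seq_len(K), best)],
         meanCosine = bestScore)
}
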