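#' @import methods
NULL

#' Result of an atomic-prior NMF run
#'
#' Container for the posterior summaries of a Bayesian non-negative matrix
#' factorization \eqn{D \approx AP}: entrywise posterior means and standard
#' deviations of the amplitude matrix \eqn{A} (genes x patterns) and the
#' pattern matrix \eqn{P} (patterns x cells) over sampling-phase snapshots,
#' together with the chi-squared and atom-count traces and the run
#' configuration.
#'
#' @slot Amean,Asd numeric matrices, genes x patterns.
#' @slot Pmean,Psd numeric matrices, patterns x cells.
#' @slot chisqTrace numeric vector, one chi-squared value per outer iteration
#'   (equilibration then sampling).
#' @slot atomTrace integer matrix with one row per outer iteration and columns
#'   \code{atomsA}, \code{atomsP}.
#' @slot seed single number, the run seed.
#' @slot config named list echoing the run configuration.
#' @slot diagnostics named list of engine statistics (baseline/final
#'   chi-squared, proposal and batch counts, operation-count proxies).
#'
#' @seealso [atomicNMF()] which produces this class, accessors
#'   [amplitudeMean()], [patternMean()], [chiSqTrace()], and
#'   [writeNmfResult()].
#' @export
setClass("AtomicNmfResult",
    representation(
        Amean = "matrix", Asd = "matrix",
        Pmean = "matrix", Psd = "matrix",
        chisqTrace = "numeric", atomTrace = "matrix",
        seed = "numeric", config = "list", diagnostics = "list"
    )
)

setValidity("AtomicNmfResult", function(object) {
    msg <- NULL
    if (ncol(object@Amean) != nrow(object@Pmean))
        msg <- c(msg, "pattern dimension of Amean and Pmean disagree")
    if (!all(dim(object@Amean) == dim(object@Asd)) ||
        !all(dim(object@Pmean) == dim(object@Psd)))
        msg <- c(msg, "mean and sd dimensions disagree")
    if (any(object@Amean < 0) || any(object@Pmean < 0))
        msg <- c(msg, "posterior means must be non-negative")
    if (any(object@Asd < 0) || any(object@Psd < 0))
        msg <- c(msg, "posterior sds must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Simulated single-cell counts with known factors
#'
#' Ground-truth container produced by [simulateNmfData()]: a sparse
#' single-cell-like count matrix generated as Poisson draws around a known
#' non-negative rank-K product, with independent dropout calibrated to a
#' target sparsity.
#'
#' @slot counts numeric matrix, genes x cells, non-negative integers.
#' @slot Atrue numeric matrix, genes x patterns (marker-sparse Gamma weights).
#' @slot Ptrue numeric matrix, patterns x cells (smooth activity bumps).
#' @slot depth single number, mean scaling applied to \code{Atrue \%*\% Ptrue}.
#' @slot sparsityTarget target zero fraction (NA when no dropout requested).
#' @slot realizedSparsity achieved zero fraction of \code{counts}.
#' @slot dropoutRate mean dropout probability after calibration.
#' @slot seed single number.
#'
#' @seealso [simulateNmfData()], [nmfFixture()], [matchPatterns()].
#' @export
setClass("SimulatedNmfData",
    representation(
        counts = "matrix", Atrue = "matrix", Ptrue = "matrix",
        depth = "numeric", sparsityTarget = "numeric",
        realizedSparsity = "numeric", dropoutRate = "numeric",
        seed = "numeric"
    )
)

setValidity("SimulatedNmfData", function(object) {
    msg <- NULL
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (nrow(object@counts) != nrow(object@Atrue) ||
        ncol(object@counts) != ncol(object@Ptrue) ||
        ncol(object@Atrue) != nrow(object@Ptrue))
        msg <- c(msg, "factor dimensions inconsistent with counts")
    if (any(colSums(object@Ptrue) <= 0))
        msg <- c(msg, "every column of Ptrue needs a positive entry")
    if (is.null(msg)) TRUE else msg
})
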