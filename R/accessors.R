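#' @describeIn AtomicNmfResult posterior mean of the amplitude matrix A
#'   (genes x patterns).
#' @param object an \code{AtomicNmfResult}.
#' @export
setGeneric("amplitudeMean", function(object) standardGeneric("amplitudeMean"))

#' @describeIn AtomicNmfResult posterior sd of A.
#' @export
setGeneric("amplitudeSd", function(object) standardGeneric("amplitudeSd"))

#' @describeIn AtomicNmfResult posterior mean of the pattern matrix P
#'   (patterns x cells).
#' @export
setGeneric("patternMean", function(object) standardGeneric("patternMean"))

#' @describeIn AtomicNmfResult posterior sd of P.
#' @export
setGeneric("patternSd", function(object) standardGeneric("patternSd"))

#' @describeIn AtomicNmfResult chi-squared fit trace, one value per outer
#'   iteration.
#' @export
setGeneric("chiSqTrace", function(object) standardGeneric("chiSqTrace"))

#' @describeIn AtomicNmfResult atom-count trace (columns \code{atomsA},
#'   \code{atomsP}).
#' @export
setGeneric("atomCountTrace", function(object) standardGeneric("atomCountTrace"))

#' @describeIn AtomicNmfResult engine diagnostics list.
#' @export
setGeneric("nmfDiagnostics", function(object) standardGeneric("nmfDiagnostics"))

setMethod("amplitudeMean", "AtomicNmfResult", function(object) object@Amean)
setMethod("amplitudeSd", "AtomicNmfResult", function(object) object@Asd)
setMethod("patternMean", "AtomicNmfResult", function(object) object@Pmean)
setMethod("patternSd", "AtomicNmfResult", function(object) object@Psd)
setMethod("chiSqTrace", "AtomicNmfResult", function(object) object@chisqTrace)
setMethod("atomCountTrace", "AtomicNmfResult", function(object) object@atomTrace)
setMethod("nmfDiagnostics", "AtomicNmfResult", function(object) object@diagnostics)

setMethod("show", "AtomicNmfResult", function(object) {
    d <- object@diagnostics
    cat("AtomicNmfResult\n")
    cat(sprintf("  %d genes x %d cells, %d patterns\n",
                nrow(object@Amean), ncol(object@Pmean), ncol(object@Amean)))
    cat(sprintf("  chi-squared: %.6g (baseline %.6g, %.1f%% reduction)\n",
                d$chisqFinal, d$chisqBaseline,
                100 * (1 - d$chisqFinal / d$chisqBaseline)))
    cat(sprintf("  %s mode, %d snapshots, mean batch size %.1f\n",
                if (isTRUE(object@config$sparse)) "sparse" else "dense",
                as.integer(d$nSnapshots), d$meanBatchSize))
})

#' @describeIn SimulatedNmfData the simulated count matrix (genes x cells).
#' @param object a \code{SimulatedNmfData}.
#' @export
setGeneric("simulatedCounts", function(object) standardGeneric("simulatedCounts"))

#' @describeIn SimulatedNmfData the true amplitude matrix.
#' @export
setGeneric("trueAmplitude", function(object) standardGeneric("trueAmplitude"))

#' @describeIn SimulatedNmfData the true pattern matrix.
#' @export
setGeneric("truePattern", function(object) standardGeneric("truePattern"))

#' @describeIn SimulatedNmfData achieved zero fraction of the counts.
#' @export
setGeneric("realizedSparsity", function(object) standardGeneric("realizedSparsity"))

setMethod("simulatedCounts", "SimulatedNmfData", function(object) object@counts)
setMethod("trueAmplitude", "SimulatedNmfData", function(object) object@Atrue)
setMethod("truePattern", "SimulatedNmfData", function(object) object@Ptrue)
setMethod("realizedSparsity", "SimulatedNmfData", function(object) object@realizedSparsity)

setMethod("show", "SimulatedNmfData", function(object) {
    cat("SimulatedNmfData\n")
    cat(sprintf("  %d genes x %d cells, %d patterns, depth %.3g\n",
                nrow(object@counts), ncol(object@counts),
                ncol(object@Atrue), object@depth))
    cat(sprintf("  sparsity: %.3f realized (target %s, dropout %.3f)\n",
                object@realizedSparsity,
                if (is.na(object@sparsityTarget)) "none"
                else sprintf("%.2f", object@sparsityTarget),
                object@dropoutRate))
})
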