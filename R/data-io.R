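#' Read a non-negative data matrix from MatrixMarket, CSV or TSV
#'
#' Reads a genes x cells expression matrix.  MatrixMarket files must use the
#' 1-based \code{coordinate real general} dialect; coordinates absent from the
#' file are materialized as exact zeros.  CSV/TSV files are dense with one
#' header row and the first column holding row names.
#'
#' @param path path to the file.
#' @param format one of \code{"auto"} (by extension), \code{"mtx"},
#'   \code{"csv"}, \code{"tsv"}.
#' @param transpose if \code{TRUE}, transpose after reading (for cells x genes
#'   files).
#' @return a numeric matrix with genes as rows and cells as columns; default
#'   dimnames \code{gene<i>}/\code{cell<j>} are supplied when the file has
#'   none.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(",c1,c2", "g1,1,0", "g2,0,4"), tf)
#' readMatrixInput(tf)
#' @export
readMatrixInput <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                            transpose = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv",
                         txt = "tsv",
                         stop("cannot infer format from extension '", ext, "'"))
    }
    X <- switch(format,
        mtx = .readMtx(path),
        csv = .readDense(path, sep = ","),
        tsv = .readDense(path, sep = "\t"))
    if (any(!is.finite(X))) stop("non-finite entry in matrix")
    if (any(X < 0)) stop("negative entry in matrix; data must be non-negative")
    if (transpose) X <- t(X)
    if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
    if (is.null(colnames(X))) colnames(X) <- paste0("cell", seq_len(ncol(X)))
    X
}

.readMtx <- function(path) {
    header <- readLines(path, n = 1L)
    tok <- tolower(strsplit(trimws(header), "\\s+")[[1]])
    if (length(tok) < 5 || tok[1] != "%%matrixmarket" || tok[2] != "matrix")
        stop("malformed MatrixMarket header: ", header)
    if (tok[3] != "coordinate" || !(tok[4] %in% c("real", "integer")) ||
        tok[5] != "general")
        stop("unsupported MatrixMarket dialect '",
             paste(tok[3:5], collapse = " "),
             "'; only 'coordinate real general' is accepted")
    m <- Matrix::readMM(path)
    tm <- methods::as(m, "TsparseMatrix")
    if (anyDuplicated(cbind(tm@i, tm@j)) > 0)
        stop("duplicate coordinate entry in MatrixMarket file")
    as.matrix(m)
}

.readDense <- function(path, sep) {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, comment.char = "")
    X <- as.matrix(df)
    if (!is.numeric(X)) stop("non-numeric entries in dense matrix file")
    X
}

#' Per-entry uncertainty (standard deviation) matrix
#'
#' Builds the Gaussian standard-deviation matrix \eqn{S} for the likelihood
#' \eqn{D \sim N(AP, S^2)}.  By default \eqn{S = \max(scale \cdot D, floor)},
#' so the noise scale is proportional to the signal with a strictly positive
#' floor (in particular \eqn{S = floor} on every zero entry -- the property the
#' sparse update path relies on).
#'
#' @param D non-negative data matrix.
#' @param scale,floor positive reals; defaults 0.1 and 0.1.
#' @param explicit optional explicit S matrix of the same shape (overrides the
#'   rule; must be strictly positive).
#' @return numeric matrix of the same shape as \code{D}, all entries > 0.
#' @examples
#' makeUncertainty(matrix(c(5, 0, 0.5, 2), 2))
#' @export
makeUncertainty <- function(D, scale = 0.1, floor = 0.1, explicit = NULL) {
    if (!is.null(explicit)) {
        if (!all(dim(explicit) == dim(D)))
            stop("explicit uncertainty matrix shape mismatch")
        if (any(explicit <= 0))
            stop("explicit uncertainty matrix must be strictly positive")
        return(explicit)
    }
    if (scale <= 0 || floor <= 0) stop("scale and floor must be positive")
    pmax(scale * D, floor)
}

#' Sparse indexed views of a data matrix
#'
#' Builds row-wise and column-wise indexed views of the non-zero entries of
#' \code{D}, the representation the sparse conditional-update path works from.
#'
#' @param D non-negative numeric matrix.
#' @return a list with elements \code{nnzByRow} and \code{nnzByCol} (one list
#'   entry per row/column, each a two-column matrix \code{idx}, \code{value}
#'   with sorted indices), \code{sparsity} (zero fraction), and \code{dim}.
#' @seealso [densifySparseView()] for the exact inverse.
#' @export
buildSparseView <- function(D) {
    stopifnot(is.matrix(D))
    byRow <- lapply(seq_len(nrow(D)), function(i) {
        j <- which(D[i, ] != 0)
        cbind(idx = j, value = D[i, j])
    })
    byCol <- lapply(seq_len(ncol(D)), function(j) {
        i <- which(D[, j] != 0)
        cbind(idx = i, value = D[i, j])
    })
    nnz <- sum(D != 0)
    list(nnzByRow = byRow, nnzByCol = byCol,
         sparsity = 1 - nnz / length(D), dim = dim(D))
}

#' @rdname buildSparseView
#' @param view a list produced by \code{buildSparseView}.
#' @export
densifySparseView <- function(view) {
    X <- matrix(0, view$dim[1], view$dim[2])
    for (i in seq_along(view$nnzByRow)) {
        v <- view$nnzByRow[[i]]
        if (nrow(v)) X[i, v[, "idx"]] <- v[, "value"]
    }
    X
}

#' Write an NMF result to a directory of TSV files
#'
#' Writes \code{Amean.tsv}, \code{Asd.tsv}, \code{Pmean.tsv}, \code{Psd.tsv}
#' (dense TSV with row/column names, readable by [readMatrixInput()]), the
#' chi-squared and atom-count traces (\code{chisq.tsv}, \code{atoms.tsv}), and
#' a \code{config.txt} metadata file with the run configuration and seed.
#'
#' @param result an [AtomicNmfResult-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
writeNmfResult <- function(result, dir) {
    stopifnot(is(result, "AtomicNmfResult"))
    if (result@diagnostics$nSnapshots < 1) stop("no samples recorded")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    wm <- function(X, f) {
        utils::write.table(X, file.path(dir, f), sep = "\t", quote = FALSE,
                           col.names = NA)
    }
    wm(result@Amean, "Amean.tsv"); wm(result@Asd, "Asd.tsv")
    wm(result@Pmean, "Pmean.tsv"); wm(result@Psd, "Psd.tsv")
    utils::write.table(
        data.frame(iteration = seq_along(result@chisqTrace),
                   chisq = result@chisqTrace),
        file.path(dir, "chisq.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(iteration = seq_len(nrow(result@atomTrace)),
                   atomsA = result@atomTrace[, 1], atomsP = result@atomTrace[, 2]),
        file.path(dir, "atoms.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- c(result@config, list(seed = result@seed))
    writeLines(paste0(names(cfg), "=", vapply(cfg, function(x)
        paste(format(x, digits = 15), collapse = ","), character(1))),
        file.path(dir, "config.txt"))
    invisible(file.path(dir, c("Amean.tsv", "Asd.tsv", "Pmean.tsv", "Psd.tsv",
                               "chisq.tsv", "atoms.tsv", "config.txt")))
}

#' Write a matrix in MatrixMarket coordinate format
#'
#' Convenience wrapper around \code{Matrix::writeMM} for emitting simulated
#' count matrices as \code{.mtx}.
#'
#' @param X numeric matrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMtx <- function(X, path) {
    Matrix::writeMM(methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"),
                    path)
    invisible(path)
}
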