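test_that("MatrixMarket coordinate files materialize absent entries as zeros", {
    tf <- tempfile(fileext = ".mtx")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 "3 2 2", "1 1 5", "3 2 2"), tf)
    X <- readMatrixInput(tf)
    expect_equal(unname(X), matrix(c(5, 0, 0, 0, 0, 2), 3, 2))
})

test_that("dense CSV/TSV with header and row names read correctly", {
    tf <- tempfile(fileext = ".csv")
    writeLines(c(",c1,c2", "g1,1.0,0.0", "g2,0.0,4.0"), tf)
    X <- readMatrixInput(tf)
    expect_equal(unname(X), matrix(c(1, 0, 0, 4), 2, 2))
    expect_equal(rownames(X), c("g1", "g2"))
    tt <- tempfile(fileext = ".tsv")
    writeLines(c("\tc1\tc2", "g1\t1\t0", "g2\t0\t4"), tt)
    expect_equal(readMatrixInput(tt), X)
    expect_equal(readMatrixInput(tt, transpose = TRUE), t(X))
})

test_that("malformed or unsupported inputs are rejected", {
    neg <- tempfile(fileext = ".csv")
    writeLines(c(",c1", "g1,-1"), neg)
    expect_error(readMatrixInput(neg), "negative")
    bad <- tempfile(fileext = ".mtx")
    writeLines(c("%%NotMatrixMarket whatever", "1 1 1", "1 1 1"), bad)
    expect_error(readMatrixInput(bad), "malformed")
    pat <- tempfile(fileext = ".mtx")
    writeLines(c("%%MatrixMarket matrix coordinate pattern general",
                 "2 2 1", "1 1"), pat)
    expect_error(readMatrixInput(pat), "dialect")
    dup <- tempfile(fileext = ".mtx")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 "2 2 2", "1 1 3", "1 1 4"), dup)
    expect_error(readMatrixInput(dup), "duplicate")
    negmtx <- tempfile(fileext = ".mtx")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 "2 2 1", "1 1 -2"), negmtx)
    expect_error(readMatrixInput(negmtx), "negative")
})

test_that("write/read round trips are exact over all three formats", {
    set.seed(11)
    for (i in 1:5) {
        X <- matrix(rpois(12, 3), 4, 3,
                    dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
        fm <- tempfile(fileext = ".mtx")
        writeMtx(X, fm)
        expect_equal(unname(readMatrixInput(fm)), unname(X))
        fc <- tempfile(fileext = ".csv")
        write.table(X, fc, sep = ",", quote = FALSE, col.names = NA)
        expect_equal(readMatrixInput(fc), X)
        ft <- tempfile(fileext = ".tsv")
        write.table(X, ft, sep = "\t", quote = FALSE, col.names = NA)
        expect_equal(readMatrixInput(ft), X)
    }
})

test_that("default uncertainty rule is max(scale*D, floor), positive floor on zeros", {
    D <- matrix(c(5, 0, 0.5, 2), 2, 2)
    S <- makeUncertainty(D, scale = 0.1, floor = 0.1)
    expect_equal(S[1, 1], 0.5)   # 0.1*5 above floor
    expect_equal(S[2, 1], 0.1)   # zero entry -> floor
    expect_equal(S[1, 2], 0.1)   # 0.05 below floor
    expect_true(all(S >= 0.1))
    expect_error(makeUncertainty(D, explicit = matrix(1, 3, 3)), "shape")
    expect_error(makeUncertainty(D, explicit = matrix(0, 2, 2)), "positive")
    E <- matrix(2, 2, 2)
    expect_equal(makeUncertainty(D, explicit = E), E)
})

test_that("sparse views index exactly the non-zero entries and densify back", {
    D <- matrix(c(5, 0, 0, 0, 0, 2), 3, 2)
    v <- buildSparseView(D)
    expect_equal(v$sparsity, 4 / 6)
    expect_equal(v$nnzByRow[[1]][, "idx"], c(idx = 1))
    expect_equal(v$nnzByRow[[3]][, "value"], c(value = 2))
    expect_equal(nrow(v$nnzByRow[[2]]), 0)
    expect_equal(densifySparseView(v), D)

    z <- buildSparseView(matrix(0, 2, 2))
    expect_equal(z$sparsity, 1)
    expect_true(all(vapply(z$nnzByRow, nrow, 1L) == 0))
    f <- buildSparseView(matrix(1:4, 2, 2))
    expect_equal(f$sparsity, 0)

    set.seed(3)
    for (i in 1:5) {
        X <- matrix(rpois(35, 1), 7, 5)
        expect_equal(densifySparseView(buildSparseView(X)), X)
    }
})

test_that("result files round trip through the TSV readers", {
    sim <- simulateNmfData(12, 9, 2, seed = 3)
    res <- atomicNMF(simulatedCounts(sim), 2, nEquil = 60, nSample = 30,
                     seed = 1)
    out <- file.path(tempdir(), "nmf-out")
    files <- writeNmfResult(res, out)
    expect_true(all(file.exists(files)))
    Aback <- readMatrixInput(file.path(out, "Amean.tsv"), format = "tsv")
    expect_equal(Aback, amplitudeMean(res), tolerance = 1e-12)
    tr <- read.delim(file.path(out, "chisq.tsv"))
    expect_equal(nrow(tr), 90)
    cfg <- readLines(file.path(out, "config.txt"))
    expect_true(any(grepl("^seed=1$", cfg)))
})
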