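test_that("a noiseless rank-1 matrix is fit to well under the uncertainty floor", {
    D <- c(1, 2, 3) %*% t(c(4, 5))
    r <- atomicNMF(D, 1, nEquil = 500, nSample = 500, seed = 2)
    d <- nmfDiagnostics(r)
    expect_lt(d$chisqFinal, 0.01 * d$chisqBaseline)
})

test_that("chi-squared improves over the all-zero baseline on every run", {
    for (seed in 1:3) {
        sim <- simulateNmfData(15, 12, 2, seed = seed + 40)
        r <- atomicNMF(simulatedCounts(sim), 2, nEquil = 100, nSample = 50,
                       seed = seed)
        d <- nmfDiagnostics(r)
        expect_lt(d$chisqFinal, d$chisqBaseline)
    }
})

test_that("a single snapshot yields zero posterior sds", {
    sim <- simulateNmfData(10, 8, 2, seed = 5)
    r <- atomicNMF(simulatedCounts(sim), 2, nEquil = 50, nSample = 1, seed = 1)
    expect_true(all(amplitudeSd(r) == 0))
    expect_true(all(patternSd(r) == 0))
    expect_equal(nmfDiagnostics(r)$nSnapshots, 1)
})

test_that("snapshot stride controls the number of recorded samples", {
    sim <- simulateNmfData(10, 8, 2, seed = 5)
    r <- atomicNMF(simulatedCounts(sim), 2, nEquil = 40, nSample = 30,
                   snapshotStride = 7, seed = 1)
    expect_equal(nmfDiagnostics(r)$nSnapshots, 4)  # floor(30/7)
    expect_equal(length(chiSqTrace(r)), 70)
    expect_equal(nrow(atomCountTrace(r)), 70)
})

test_that("identical configuration and seed reproduce the result exactly", {
    sim <- simulateNmfData(12, 10, 2, seed = 9)
    r1 <- atomicNMF(simulatedCounts(sim), 2, nEquil = 80, nSample = 40, seed = 7)
    r2 <- atomicNMF(simulatedCounts(sim), 2, nEquil = 80, nSample = 40, seed = 7)
    expect_identical(amplitudeMean(r1), amplitudeMean(r2))
    expect_identical(patternSd(r1), patternSd(r2))
    expect_identical(chiSqTrace(r1), chiSqTrace(r2))
})

test_that("sparse and dense modes agree closely with matched seeds", {
    sim <- simulateNmfData(30, 25, 2, sparsity = 0.8, seed = 3)
    D <- simulatedCounts(sim)
    rd <- atomicNMF(D, 2, nEquil = 150, nSample = 80, seed = 4, sparse = FALSE)
    rs <- atomicNMF(D, 2, nEquil = 150, nSample = 80, seed = 4, sparse = TRUE)
    expect_lt(max(abs(amplitudeMean(rd) - amplitudeMean(rs))), 1e-6)
    expect_lt(max(abs(patternMean(rd) - patternMean(rs))), 1e-6)
})

test_that("invalid configurations fail fast", {
    D <- matrix(1:6, 2, 3)
    expect_error(atomicNMF(D, 5, nEquil = 10, nSample = 10), "nPatterns")
    expect_error(atomicNMF(D, 1, nSample = 0), "nSample")
    expect_error(atomicNMF(D, 1, sparse = TRUE, uncertainty = matrix(1, 2, 3)),
                 "sparse mode")
    expect_error(atomicNMF(-D, 1), "non-negative")
})

test_that("posterior summaries are non-negative with consistent dimnames", {
    sim <- simulateNmfData(10, 8, 2, seed = 1)
    D <- simulatedCounts(sim)
    r <- atomicNMF(D, 2, nEquil = 60, nSample = 30, seed = 2)
    expect_true(validObject(r))
    expect_equal(rownames(amplitudeMean(r)), rownames(D))
    expect_equal(colnames(patternMean(r)), colnames(D))
    expect_equal(colnames(amplitudeMean(r)), c("Pattern_1", "Pattern_2"))
})

test_that("dense per-call cost is shape-fixed while sparse cost tracks non-zeros", {
    b <- proposalCostBenchmark(nGenes = 60, nCells = 60,
                               sparsity = c(0.7, 0.9), nEquil = 20,
                               nSample = 20, seed = 2)
    dense <- b[b$mode == "dense", ]
    expect_lt(diff(range(dense$opsPerCallA)) / mean(dense$opsPerCallA), 0.01)
    sp <- b[b$mode == "sparse", ]
    expect_lt(sp$opsPerCallA[sp$sparsity == 0.9],
              sp$opsPerCallA[sp$sparsity == 0.7])
})
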