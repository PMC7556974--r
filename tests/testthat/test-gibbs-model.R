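test_that("chi-squared is the uncertainty-weighted squared misfit", {
    one <- matrix(1)
    expect_equal(atomicNMF:::cpp_chi_squared(one, one, one, one), 0)
    expect_equal(atomicNMF:::cpp_chi_squared(matrix(3), one, one, one), 4)
    D <- matrix(c(3, 0), 1, 2); S <- matrix(c(1, 0.5), 1, 2)
    expect_equal(
        atomicNMF:::cpp_chi_squared(D, S, matrix(1), matrix(c(1, 2), 1, 2)),
        20)  # (3-1)^2/1 + (0-2)^2/0.25
    # sparse mode computes the identical quantity without the AP cache
    ins <- randomInstance(8, 6, 2, 0.5, 31)
    expect_equal(
        atomicNMF:::cpp_chi_squared(ins$D, ins$S, ins$A, ins$P, TRUE, 0.1),
        chiSqR(ins), tolerance = 1e-12)
})

test_that("dense conditional parameters match the direct-summation oracle", {
    for (seed in 1:3) {
        ins <- randomInstance(10, 7, 3, 0.4, seed)
        g <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, FALSE, 0.1)
        o <- oracleParamsA(ins)
        expect_equal(g$sA, o$s, tolerance = 1e-10)
        expect_equal(g$smuA, o$smu, tolerance = 1e-10)
    }
})

test_that("a zero row of the frozen factor gives a flat conditional", {
    ins <- randomInstance(5, 6, 2, 0.3, 7)
    ins$P[2, ] <- 0
    g <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, FALSE, 0.1)
    expect_true(all(g$sA[, 2] == 0))
    expect_true(all(g$smuA[, 2] == 0))
})

test_that("temperature scales both conditional coefficients linearly and exactly", {
    ins <- randomInstance(6, 5, 2, 0.5, 12)
    g1 <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, FALSE, 0.1)
    gh <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 0.5, FALSE, 0.1)
    expect_identical(gh$sA, 0.5 * g1$sA)
    expect_identical(gh$smuA, 0.5 * g1$smuA)
    expect_identical(gh$sP, 0.5 * g1$sP)
    expect_identical(gh$smuP, 0.5 * g1$smuP)
})

test_that("batch Gram precomputation is F F^T", {
    G <- atomicNMF:::cpp_gram(matrix(c(1, 0, 2, 1), 2, 2, byrow = FALSE))
    # P = [[1,2],[0,1]] stored row-wise
    P <- matrix(c(1, 2, 0, 1), 2, 2, byrow = TRUE)
    expect_equal(atomicNMF:::cpp_gram(P), matrix(c(5, 2, 2, 1), 2, 2))
    expect_equal(atomicNMF:::cpp_gram(matrix(c(1, 0), 1, 2)), matrix(1))
    set.seed(2)
    F4 <- matrix(rexp(28), 4, 7)
    G4 <- atomicNMF:::cpp_gram(F4)
    expect_equal(G4, t(G4))
    expect_equal(G4, F4 %*% t(F4), tolerance = 1e-12)
})

test_that("sparse conditional parameters equal dense ones on both sides", {
    for (sp in c(0.5, 0.8, 0.95)) for (seed in 1:4) {
        ins <- randomInstance(20, 15, sample(2:4, 1), sp, 100 * seed + sp * 10)
        gd <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, FALSE, 0.1)
        gs <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, TRUE, 0.1)
        for (nm in names(gd)) expect_lt(max(abs(gd[[nm]] - gs[[nm]])), 1e-9)
    }
    # fully dense row (no zeros anywhere): correction terms cancel exactly
    ins <- randomInstance(6, 5, 2, 0, 77)
    ins$D[ins$D == 0] <- 1
    ins$S <- makeUncertainty(ins$D)
    gd <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, FALSE, 0.1)
    gs <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, TRUE, 0.1)
    expect_lt(max(abs(gd$sA - gs$sA)), 1e-9)
})

test_that("an all-zero data row reduces to the precomputed-term limit", {
    ins <- randomInstance(5, 6, 2, 0.3, 19)
    ins$D[3, ] <- 0
    ins$S <- makeUncertainty(ins$D)
    gs <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, TRUE, 0.1)
    G <- ins$P %*% t(ins$P)
    s0 <- 0.1
    expect_equal(gs$sA[3, ], diag(G) / s0^2, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(gs$smuA[3, ], -(ins$A %*% G)[3, ] / s0^2, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("two-element (exchange) parameters match the brute-force delta-LL oracle", {
    quadFit <- function(f, h = 0.1) {
        # f(delta) = smu*delta - s*delta^2/2 recovered from f(+-h)
        list(smu = (f(h) - f(-h)) / (2 * h), s = -(f(h) + f(-h)) / h^2)
    }
    for (seed in 1:3) {
        ins <- randomInstance(7, 6, 3, 0.4, 50 + seed)
        # same data row
        p <- atomicNMF:::cpp_exchange_params(ins$D, ins$S, ins$A, ins$P, 1,
                                             0L, 2L, 1L, 2L, 2L, FALSE, 0.1)
        f <- function(del) {
            A2 <- ins$A
            A2[3, 2] <- A2[3, 2] + del   # elem1 = (row 3, pattern 2), 1-based
            A2[3, 3] <- A2[3, 3] - del   # elem2 = (row 3, pattern 3)
            -(chiSqR(ins, A = A2) - chiSqR(ins)) / 2
        }
        q <- quadFit(f)
        expect_equal(p[1], q$s, tolerance = 1e-6)
        expect_equal(p[2], q$smu, tolerance = 1e-6)
        expect_equal(p[2] * 0 - p[1] * 0, 0)  # delta = 0 -> delta-LL 0

        # different data rows: independent decomposition
        p2 <- atomicNMF:::cpp_exchange_params(ins$D, ins$S, ins$A, ins$P, 1,
                                              0L, 1L, 0L, 4L, 1L, FALSE, 0.1)
        g <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, FALSE, 0.1)
        expect_equal(p2[1], g$sA[2, 1] + g$sA[5, 2], tolerance = 1e-10)
        expect_equal(p2[2], g$smuA[2, 1] - g$smuA[5, 2], tolerance = 1e-10)

        # sparse path agrees
        p2s <- atomicNMF:::cpp_exchange_params(ins$D, ins$S, ins$A, ins$P, 1,
                                               0L, 1L, 0L, 4L, 1L, TRUE, 0.1)
        expect_equal(p2, p2s, tolerance = 1e-9)
        ps <- atomicNMF:::cpp_exchange_params(ins$D, ins$S, ins$A, ins$P, 1,
                                              0L, 2L, 1L, 2L, 2L, TRUE, 0.1)
        expect_equal(p, ps, tolerance = 1e-9)
    }
    ins <- randomInstance(4, 4, 2, 0.4, 3)
    expect_error(
        atomicNMF:::cpp_exchange_params(ins$D, ins$S, ins$A, ins$P, 1,
                                        0L, 1L, 1L, 1L, 1L, FALSE, 0.1),
        "degenerate")
})

test_that("delta-LL from the quadratic form equals the full chi-squared recomputation", {
    set.seed(99)
    worst <- 0
    for (i in 1:100) {
        ins <- randomInstance(8, 7, 3, runif(1, 0.2, 0.8), 200 + i)
        g <- atomicNMF:::cpp_params_grid(ins$D, ins$S, ins$A, ins$P, 1, FALSE, 0.1)
        n <- sample(8, 1); k <- sample(3, 1)
        del <- runif(1, -min(0.5, ins$A[n, k]), 0.5)
        A2 <- ins$A; A2[n, k] <- A2[n, k] + del
        dll <- g$smuA[n, k] * del - g$sA[n, k] * del^2 / 2
        worst <- max(worst, abs(dll + (chiSqR(ins, A = A2) - chiSqR(ins)) / 2))
    }
    expect_lt(worst, 1e-8)
    expect_equal(8 - 2.5, 5.5)  # s=5, smu=8, delta=1 closed form
})

test_that("gibbs mass draws follow the truncated-normal conditional", {
    x <- atomicNMF:::cpp_gibbs_mass(1, 0.3, 0.3, -1e6, 1e6, seed = 4, n = 20000)
    expect_false(anyNA(x))
    expect_lt(abs(mean(x)), 4 / sqrt(20000))         # mean (smu-lambda)/s = 0
    expect_lt(abs(var(x) - 1), 0.1)                  # sd 1/sqrt(s) = 1
    expect_true(all(is.na(atomicNMF:::cpp_gibbs_mass(0, 1, 0.5, 0, 10, 1, 10))))
    expect_true(all(is.na(
        atomicNMF:::cpp_gibbs_mass(1, -100, 0, 0.5, 0.5001, 1, 10))))
    y <- atomicNMF:::cpp_gibbs_mass(2, 3, 0.5, 0.2, 4, seed = 8, n = 5000)
    expect_true(all(y >= 0.2 & y <= 4))
    expect_identical(y, atomicNMF:::cpp_gibbs_mass(2, 3, 0.5, 0.2, 4, 8, 5000))
})
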