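# hooks into the C++ atomic domain; small explicit bin sizes keep positions
# exactly representable as doubles
adNew <- function(nRow, nCol, binSize, alpha = 1, lambda = 1)
    atomicNMF:::ad_new(nRow, nCol, alpha, lambda, binSize)

test_that("positions map to matrix elements in row-major bin order", {
    d <- adNew(2, 3, 10)  # usable = 60
    expect_equal(atomicNMF:::ad_element_of(d, 25), c(0L, 2L))
    expect_equal(atomicNMF:::ad_element_of(d, 0), c(0L, 0L))
    expect_equal(atomicNMF:::ad_element_of(d, 59), c(1L, 2L))
    expect_error(atomicNMF:::ad_element_of(d, 60), "range")
})

test_that("insert and erase maintain bin-summed element values", {
    d <- adNew(2, 3, 10)
    atomicNMF:::ad_insert(d, 7, 2.5)
    expect_equal(atomicNMF:::ad_values(d)[1, 1], 2.5)
    atomicNMF:::ad_insert(d, 3, 1)     # same bin
    expect_equal(atomicNMF:::ad_values(d)[1, 1], 3.5)
    expect_error(atomicNMF:::ad_insert(d, 7, 1), "collision")
    expect_equal(atomicNMF:::ad_erase(d, 7), 2.5)
    expect_equal(atomicNMF:::ad_values(d)[1, 1], 1)   # other atom unchanged
    expect_error(atomicNMF:::ad_erase(d, 42), "no atom")
    atomicNMF:::ad_erase(d, 3)
    expect_true(all(atomicNMF:::ad_values(d) == 0))
    expect_error(atomicNMF:::ad_erase(d, 3), "no atom")
})

test_that("right neighbor is the next atom by position, none for the last", {
    d <- adNew(1, 6, 10)
    for (p in c(3, 9, 20)) atomicNMF:::ad_insert(d, p, 1)
    expect_equal(atomicNMF:::ad_right_neighbor(d, 3)[1], 9)
    expect_equal(atomicNMF:::ad_right_neighbor(d, 9)[1], 20)
    expect_true(is.na(atomicNMF:::ad_right_neighbor(d, 20)[1]))
    expect_error(atomicNMF:::ad_right_neighbor(d, 5), "no atom")
})

test_that("random free positions are in range, avoid atoms, and are deterministic", {
    d <- adNew(2, 3, 10)
    p <- atomicNMF:::ad_random_free(d, seed = 4, n = 200)
    expect_true(all(p >= 0 & p < 60))
    expect_equal(atomicNMF:::ad_random_free(d, seed = 4, n = 200), p)

    # all but one position occupied: the free one is forced
    d2 <- adNew(1, 2, 3)  # usable = 6
    for (p in c(0, 1, 2, 4, 5)) atomicNMF:::ad_insert(d2, p, 1)
    expect_true(all(atomicNMF:::ad_random_free(d2, seed = 9, n = 50) == 3))
})

test_that("random atom selection is uniform over atoms", {
    d <- adNew(1, 4, 100)
    expect_error(atomicNMF:::ad_random_atom(d, 1, 1), "empty")
    atomicNMF:::ad_insert(d, 17, 1)
    expect_true(all(atomicNMF:::ad_random_atom(d, 2, 20) == 17))
    for (p in c(120, 250, 333)) atomicNMF:::ad_insert(d, p, 1)
    draws <- atomicNMF:::ad_random_atom(d, seed = 5, n = 10000)
    freq <- table(factor(draws, levels = c(17, 120, 250, 333))) / 10000
    se <- sqrt(0.25 * 0.75 / 10000)
    expect_true(all(abs(freq - 0.25) < 4 * se))
})

test_that("element values stay exact bin sums over long random op sequences", {
    set.seed(21)
    d <- adNew(5, 4, 1000)  # usable 20000
    present <- c()
    for (i in 1:10000) {
        if (length(present) == 0 || runif(1) < 0.55) {
            p <- sample(0:19999, 1)
            if (!(p %in% present)) {
                atomicNMF:::ad_insert(d, p, rexp(1))
                present <- c(present, p)
            }
        } else {
            p <- present[sample.int(length(present), 1)]
            atomicNMF:::ad_erase(d, p)
            present <- setdiff(present, p)
        }
    }
    expect_lt(atomicNMF:::ad_check(d), 1e-9)
    vals <- atomicNMF:::ad_values(d)
    expect_true(all(vals >= 0))
    expect_equal(sum(vals), atomicNMF:::ad_total_mass(d), tolerance = 1e-12)
})
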