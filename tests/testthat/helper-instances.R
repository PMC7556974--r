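# random model instances used across gibbs-model and engine tests
randomInstance <- function(N, M, K, sparsity, seed) {
    set.seed(seed)
    D <- matrix(rpois(N * M, 6), N, M)
    D[sample(N * M, round(sparsity * N * M))] <- 0
    A <- matrix(rexp(N * K, 1), N, K)
    P <- matrix(rexp(K * M, 1), K, M)
    list(D = D, S = makeUncertainty(D), A = A, P = P)
}

# R-side oracle for the single-element conditional parameters (A side)
oracleParamsA <- function(ins, t = 1) {
    AP <- ins$A %*% ins$P
    K <- ncol(ins$A)
    s <- smu <- matrix(0, nrow(ins$D), K)
    for (n in seq_len(nrow(ins$D))) for (k in seq_len(K)) {
        w <- 1 / ins$S[n, ]^2
        s[n, k] <- t * sum(ins$P[k, ]^2 * w)
        smu[n, k] <- t * sum(ins$P[k, ] * (ins$D[n, ] - AP[n, ]) * w)
    }
    list(s = s, smu = smu)
}

chiSqR <- function(ins, A = ins$A, P = ins$P) sum(((ins$D - A %*% P) / ins$S)^2)
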