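# Independent brute-force oracles used across the suite.  These deliberately
# avoid the code paths they check.

# Pearson correlation from the textbook covariance formula
oraclePCC <- function(x, y) {
    n <- length(x)
    sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
    sxy / sqrt(sum((x - mean(x))^2) / (n - 1) *
               sum((y - mean(y))^2) / (n - 1))
}

# mean silhouette width from the definition
oracleMeanSilhouette <- function(labels, dmat) {
    dmat <- as.matrix(dmat)
    n <- length(labels)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- setdiff(which(labels == labels[i]), i)
        if (!length(own)) { s[i] <- 0; next }
        a <- mean(dmat[i, own])
        b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
            mean(dmat[i, labels == g]), numeric(1)))
        s[i] <- (b - a) / max(a, b)
    }
    mean(s)
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins
oracleFisher <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
    pobs <- dhyper(a, m, n, k)
    sum(probs[probs <= pobs * (1 + 1e-7)])
}

# two-sided Wilcoxon rank-sum p by full enumeration of group assignments
oracleRankSum <- function(x, y) {
    nx <- length(x); ny <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    wobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    combs <- combn(nx + ny, nx)
    ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    mean(abs(ws - mu) >= abs(wobs - mu) - 1e-9)
}

# two-sided Wilcoxon signed-rank p by full 2^n sign enumeration
oracleSignedRank <- function(x, y) {
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) return(1)
    r <- rank(abs(d))
    vobs <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    signs <- expand.grid(rep(list(c(0, 1)), n))
    vs <- as.matrix(signs) %*% r
    mean(abs(vs - mu) >= abs(vobs - mu) - 1e-9)
}

# Smith-Waterman local alignment score, affine gaps in the Biostrings
# convention (gap of length L costs open + L * ext)
oracleSW <- function(a, b, match = 1, mismatch = -2, open = 4, ext = 1) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    M <- matrix(0, n + 1, m + 1)      # match/mismatch state
    X <- matrix(-Inf, n + 1, m + 1)   # gap in b (consume a)
    Y <- matrix(-Inf, n + 1, m + 1)   # gap in a (consume b)
    bestScore <- 0
    for (i in seq_len(n)) for (j in seq_len(m)) {
        sub <- if (a[i] == b[j]) match else mismatch
        M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + sub
        X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                               X[i, j + 1] - ext)
        Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                               Y[i + 1, j] - ext)
        bestScore <- max(bestScore, M[i + 1, j + 1])
    }
    bestScore
}

# global (Needleman-Wunsch) percent identity, linear gap penalty; counts
# identical aligned columns over alignment length
oracleGlobalIdentity <- function(a, b, match = 1, mismatch = -1, gap = -1) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    S <- matrix(0, n + 1, m + 1)
    S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        sub <- if (a[i] == b[j]) match else mismatch
        S[i + 1, j + 1] <- max(S[i, j] + sub, S[i, j + 1] + gap,
                               S[i + 1, j] + gap)
    }
    # traceback counting identities and columns
    i <- n; j <- m; id <- 0; cols <- 0
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            S[i + 1, j + 1] == S[i, j] +
                (if (a[i] == b[j]) match else mismatch)) {
            id <- id + (a[i] == b[j]); i <- i - 1; j <- j - 1
        } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
            i <- i - 1
        } else j <- j - 1
        cols <- cols + 1
    }
    100 * id / cols
}

# reverse complement, independent of the package's helper
oracleRevComp <- function(s) {
    paste(rev(chartr("ACGT", "TGCA",
                     strsplit(s, "")[[1]])), collapse = "")
}

# small labelled ExpressionMatrix builder
makeExpr <- function(values, unit = "TPM",
                     genes = sprintf("g%02d", seq_len(nrow(values))),
                     cells = sprintf("c%02d", seq_len(ncol(values)))) {
    dimnames(values) <- list(genes, cells)
    ExpressionMatrix(values, unit)
}
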