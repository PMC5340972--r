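# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    force(expr)
}

# Largest-remainder (Hamilton) apportionment of n into length(p) groups.
# Ties on the fractional remainder break toward the earlier index.
largestRemainder <- function(n, p) {
    stopifnot(abs(sum(p) - 1) < 1e-9, n >= 0)
    q <- n * p
    base <- floor(q)
    left <- n - sum(base)
    if (left > 0) {
        ord <- order(-(q - base), seq_along(p))  # remainder desc, index asc
        base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    as.integer(base)
}

# Two-sided p-value from a signed z, and back.  p is floored away from 0 so
# the inverse stays finite.
zToP <- function(z) pmax(2 * pnorm(-abs(z)), 1e-300)
pToZ <- function(p, sign = 1) sign * qnorm(pmax(pmin(p, 1), 1e-300) / 2,
                                           lower.tail = FALSE)

# Stouffer combination of signed z-scores with weights w (NA-dropped).
stoufferZ <- function(z, w = rep(1, length(z))) {
    keep <- !is.na(z)
    if (!any(keep)) return(NA_real_)
    z <- z[keep]; w <- w[keep]
    sum(w * z) / sqrt(sum(w^2))
}

randomDNA <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""),
        character(1))
}

# fast character-level reverse complement (hot path of the assembler)
revcompChar <- function(x) {
    vapply(x, function(s) {
        if (!nzchar(s)) return(s)
        intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
    }, character(1), USE.NAMES = FALSE)
}

# Positions (1-based) of stop codons in frame `offset` (0:2) of `seq`.
stopCodonPositions <- function(seq, offset = 0L) {
    n <- nchar(seq)
    starts <- seq.int(1L + offset, n - 2L, by = 3L)
    if (length(starts) == 0L || starts[1] > n - 2L) return(integer(0))
    codons <- substring(seq, starts, starts + 2L)
    starts[codons %in% c("TAA", "TAG", "TGA")]
}

hasStopInFrame <- function(seq, offset = 0L) {
    length(stopCodonPositions(seq, offset)) > 0L
}
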