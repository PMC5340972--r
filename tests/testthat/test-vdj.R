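segs_fix <- generateGermlineSegments(3, 3, len_v = 60, len_j = 30, seed = 7)
vseq_fix <- as.character(vSegments(segs_fix))
jseq_fix <- as.character(jSegments(segs_fix))

test_that("recombinant reference enumerates V x J with exact pads", {
    ref <- buildRecombinantReference(segs_fix)
    expect_length(ref, 9)
    expect_true(all(nchar(refSequences(ref)) == 20 + 60 + 7 + 30 + 50))
    expect_identical(refSequences(ref)[["V01|J02"]],
                     paste0(strrep("N", 20), vseq_fix["V01"],
                            strrep("N", 7), jseq_fix["J02"],
                            strrep("N", 50)))
    # name decoding is a bijection back to (V, J)
    parts <- strsplit(names(refSequences(ref)), "|", fixed = TRUE)
    expect_identical(unique(vapply(parts, length, integer(1))), 2L)
    expect_identical(sort(names(refSequences(ref))),
                     sort(as.vector(outer(names(vseq_fix),
                                          names(jseq_fix), paste,
                                          sep = "|"))))
})

test_that("read recruitment equals a Smith-Waterman screen on clean reads", {
    sce <- generateExpressionDataset(
        syntheticConfig(n_cells = 6, n_genes = 120, seed = 21))
    rs <- generateCellReads(sce, segs_fix, read_len = 60,
                            n_background = 40, n_vdj = 10,
                            error_rate = 0, seed = 22)
    tcell <- which(sce$has_vdj)[1]
    rec <- recruitReads(rs[[tcell]], segs_fix, k = 25)
    # oracle: SW score >= 25 (the score of a 25-base exact match) against
    # any germline segment, either strand, either mate
    swAny <- function(read) {
        targets <- c(vseq_fix, jseq_fix)
        any(vapply(targets, function(tg)
            max(oracleSW(read, tg), oracleSW(oracleRevComp(read), tg)) >=
                25, logical(1)))
    }
    pr <- rs[[tcell]]$pairs
    oracle_keep <- vapply(seq_len(nrow(pr)), function(i)
        swAny(pr$read1[i]) || swAny(pr$read2[i]), logical(1))
    expect_identical(nrow(rec), sum(oracle_keep))
    expect_identical(pr$origin[oracle_keep], rec$origin)
    # an exact 50-mer of a V segment is recruited; a random read is not
    probe <- list(cell_id = "x", pairs = data.frame(
        read1 = c(substring(vseq_fix[1], 5, 54),
                  "TGACTGAGTCAGTTGACCAGTTGATCGAGCATTGACCAGGTTGACAGTAC"),
        read2 = c("TTTTTTTTTTTTTTTTTTTTTTTTTTTTTT",
                  "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTT"),
        origin = c("a", "b")))
    got <- recruitReads(probe, segs_fix, k = 25)
    expect_identical(got$origin, "a")
})

test_that("greedy assembly merges overlaps and respects support", {
    base <- paste0(vseq_fix[1], "ACGTA", jseq_fix[1])   # 95 nt
    r1 <- substring(base, 1, 60)
    r2 <- substring(base, 21, 80)    # 40-base exact overlap with r1
    ctg <- assembleContigs(c(r1, r2), min_reads = 1)
    expect_length(ctg, 1)
    expect_identical(unname(ctg[1]), substring(base, 1, 80))

    # error-free tiling reads, stride 10, over a 300 nt template
    set.seed(23)
    tmpl <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    starts <- seq(1, 241, by = 10)
    reads <- substring(tmpl, starts, starts + 59)
    out <- assembleContigs(reads)
    expect_identical(unname(out[1]), tmpl)
    expect_gte(attr(out, "support")[1], length(starts))

    # unrelated sequences never merge
    set.seed(24)
    u1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    u2 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    expect_length(assembleContigs(c(u1, u2), min_reads = 1), 2)
    expect_length(assembleContigs(c(u1, u2), min_reads = 2), 0)
    expect_length(assembleContigs(character(0)), 0)
})

test_that("contig annotation recovers segments, junction, and strand", {
    junc <- "ACGTA"
    ctg <- paste0(vseq_fix[2], junc, jseq_fix[3])
    ann <- annotateContig(ctg, segs_fix)
    expect_identical(ann$v$name, "V02")
    expect_identical(ann$j$name, "J03")
    expect_equal(ann$v$identity, 100)
    expect_equal(ann$v$recovery, 1)
    expect_equal(ann$j$recovery, 1)
    expect_identical(ann$junction, junc)
    expect_identical(ann$v$strand, "+")

    rc <- oracleRevComp(ctg)
    ann2 <- annotateContig(rc, segs_fix)
    expect_identical(ann2$v$name, "V02")
    expect_identical(ann2$j$name, "J03")
    expect_identical(ann2$v$strand, "-")
    expect_identical(ann2$junction, junc)
})

test_that("alignment scores equal the quadratic dynamic-programming oracle", {
    set.seed(25)
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -2)
    for (rep in 1:6) {
        a <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
        b <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
        # share a planted 20-base block half the time
        if (rep %% 2 == 0)
            b <- paste0(substring(b, 1, 15), substring(a, 11, 30),
                        substring(b, 36, 50))
        got <- Biostrings::score(Biostrings::pairwiseAlignment(
            a, b, type = "local", substitutionMatrix = submat,
            gapOpening = 4, gapExtension = 1))
        expect_equal(got, oracleSW(a, b))
    }
})

test_that("recombination calls enforce every filter with named reasons", {
    ctg <- paste0(vseq_fix[1], "ACGTA", jseq_fix[1])
    ann <- annotateContig(ctg, segs_fix)
    call <- callRecombination(ann, ctg, segs_fix)
    expect_true(call$pass)
    expect_length(call$reasons, 0)

    # in-frame stop planted in the junction (V length 60 keeps the frame)
    ctg_stop <- paste0(vseq_fix[1], "TAA", jseq_fix[1])
    call2 <- callRecombination(annotateContig(ctg_stop, segs_fix),
                               ctg_stop, segs_fix)
    expect_false(call2$pass)
    expect_true("stop codon" %in% call2$reasons)

    # 9 mismatches in the V segment: identity 85% < 90
    vmut <- strsplit(vseq_fix[1], "")[[1]]
    pos <- seq(3, 51, by = 6)
    vmut[pos] <- vapply(vmut[pos], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], character(1))
    ctg_mut <- paste0(paste(vmut, collapse = ""), "CCACA", jseq_fix[1])
    call3 <- callRecombination(annotateContig(ctg_mut, segs_fix),
                               ctg_mut, segs_fix)
    expect_false(call3$pass)
    expect_true(any(grepl("V identity", call3$reasons)))

    # truncated V: recovery below 90%
    ctg_short <- paste0(substring(vseq_fix[1], 15, 60), "ACGTA",
                        jseq_fix[1])
    call4 <- callRecombination(annotateContig(ctg_short, segs_fix),
                               ctg_short, segs_fix)
    expect_false(call4$pass)
    expect_true(any(grepl("V recovery", call4$reasons)))
})

test_that("per-cell detection is exact on clean reads and strand-symmetric", {
    sce <- generateExpressionDataset(
        syntheticConfig(n_cells = 8, n_genes = 120, seed = 26))
    rs <- generateCellReads(sce, segs_fix, n_background = 30, n_vdj = 20,
                            error_rate = 0, seed = 27)
    for (i in seq_along(rs)) {
        d <- detectCellVdj(rs[[i]], segs_fix)
        if (sce$has_vdj[i]) {
            expect_true(d$positive)
            expect_identical(d$vj_pairs$v[1], rs[[i]]$truth$v)
            expect_identical(d$vj_pairs$j[1], rs[[i]]$truth$j)
        } else {
            expect_false(d$positive)
        }
    }
    # reverse-complementing every read leaves the decision unchanged
    i <- which(sce$has_vdj)[1]
    flipped <- rs[[i]]
    flipped$pairs$read1 <- vapply(rs[[i]]$pairs$read1, oracleRevComp,
                                  character(1), USE.NAMES = FALSE)
    flipped$pairs$read2 <- vapply(rs[[i]]$pairs$read2, oracleRevComp,
                                  character(1), USE.NAMES = FALSE)
    d2 <- detectCellVdj(flipped, segs_fix)
    expect_true(d2$positive)
    expect_identical(sort(d2$vj_pairs$v), sort(rs[[i]]$truth$v))

    # monotonicity: a passing call stays passing at a lower identity bar
    d3 <- detectCellVdj(rs[[i]], segs_fix, min_identity = 95)
    d4 <- detectCellVdj(rs[[i]], segs_fix, min_identity = 85)
    expect_true(!d3$positive || d4$positive)
})

test_that("association tests match the exact Fisher oracle and flag degeneracy", {
    positive <- rep(c(TRUE, FALSE), each = 20)
    cl <- rep(c(1, 2), each = 20)
    trbc <- c(rep(50, 20), rep(0, 20))
    res <- associateVdj(positive, cl, trbc, cluster_of_interest = 1)
    expect_lt(abs(res$p_cluster - oracleFisher(20, 0, 0, 20)), 1e-10)
    expect_lt(abs(res$p_trbc1 - oracleFisher(20, 0, 0, 20)), 1e-10)
    allneg <- associateVdj(rep(FALSE, 10), rep(1:2, 5), runif(10), 1)
    expect_equal(allneg$p_cluster, 1)
    expect_true(all(allneg$degenerate))
})
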