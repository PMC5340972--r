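#' Build the synthetic V x J recombinant reference
#'
#' Enumerates all V x J combinations (V-major order).  Each entry is the V
#' sequence and the J sequence joined and padded with N ambiguity bases:
#' \code{pads[1]} N at the 5' end (unknown leader), \code{pads[2]} N between
#' V and J (possible D segment and non-templated junction), and
#' \code{pads[3]} N at the 3' end (constant region).
#'
#' @param segments a [SegmentSet-class].
#' @param pads integer(3), default \code{c(20, 7, 50)}.
#' @return A [RecombinantReference-class]; entries named \code{"V|J"}.
#' @examples
#' segs <- generateGermlineSegments(2, 3, seed = 7)
#' length(buildRecombinantReference(segs))  # 6
#' @export
buildRecombinantReference <- function(segments, pads = c(20L, 7L, 50L)) {
    stopifnot(is(segments, "SegmentSet"), length(pads) == 3L)
    v <- as.character(vSegments(segments))
    j <- as.character(jSegments(segments))
    if (!length(v) || !length(j)) stop("empty segment set")
    grid <- expand.grid(j = names(j), v = names(v),
                        stringsAsFactors = FALSE)[, c("v", "j")]
    seqs <- paste0(strrep("N", pads[1]), v[grid$v],
                   strrep("N", pads[2]), j[grid$j],
                   strrep("N", pads[3]))
    names(seqs) <- paste0(grid$v, "|", grid$j)
    new("RecombinantReference", sequences = seqs,
        vNames = grid$v, jNames = grid$j, pads = as.integer(pads))
}

# all k-mers of a set of sequences, both strands
.kmerSet <- function(seqs, k) {
    seqs <- c(seqs, revcompChar(seqs))
    unique(unlist(lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        substring(s, 1:(n - k + 1), k:n)
    })))
}

.hasSharedKmer <- function(read, kset, k) {
    n <- nchar(read)
    if (n < k) return(FALSE)
    any(substring(read, 1:(n - k + 1), k:n) %in% kset)
}

#' Recruit read pairs sharing a k-mer with the germline segments
#'
#' A read pair is recruited when either mate shares at least one exact k-mer
#' (either strand) with any germline V or J sequence.  This stands in for a
#' permissive gapped alignment against the padded recombinant reference: the
#' N pads carry no sequence information, so only V/J-derived sequence can
#' anchor a read.
#'
#' @param readset one element of the list from [generateCellReads()] (a list
#'   with \code{cell_id} and \code{pairs}).
#' @param segments a [SegmentSet-class].
#' @param k k-mer size (default 25); must not exceed the read length.
#' @return the recruited subset of \code{readset$pairs}.
#' @export
recruitReads <- function(readset, segments, k = 25L) {
    stopifnot(is(segments, "SegmentSet"))
    pairs <- readset$pairs
    if (is.null(pairs) || nrow(pairs) == 0) return(pairs)
    if (k > min(nchar(c(pairs$read1, pairs$read2))))
        stop("k exceeds the read length")
    kset <- .kmerSet(c(as.character(vSegments(segments)),
                       as.character(jSegments(segments))), k)
    keep <- vapply(seq_len(nrow(pairs)), function(i)
        .hasSharedKmer(pairs$read1[i], kset, k) ||
        .hasSharedKmer(pairs$read2[i], kset, k), logical(1))
    pairs[keep, , drop = FALSE]
}

#' Drop reads carrying rare k-mers (sequencing-error filter)
#'
#' Exact-overlap assembly is brittle to substitution errors, so reads whose
#' sequence contains any k-mer observed fewer than \code{min_count} times in
#' the read pool (counting both strands together) are removed before
#' assembly.  At the read depths used for V(D)J detection true k-mers are
#' seen tens of times while error k-mers are near-singletons.  When fewer
#' than \code{floor_reads} reads would survive, filtering is skipped (low
#' coverage makes the spectrum uninformative).
#'
#' @param reads character vector of reads.
#' @param k k-mer size for the spectrum (default 15).
#' @param min_count minimum k-mer multiplicity (default 3).
#' @param floor_reads minimum surviving pool size (default 5).
#' @return the filtered read vector.
#' @export
filterErrorReads <- function(reads, k = 15L, min_count = 3L,
                             floor_reads = 5L) {
    if (length(reads) < floor_reads) return(reads)
    rc <- revcompChar(reads)
    canon <- function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        substring(s, 1:(n - k + 1), k:n)
    }
    kmf <- lapply(reads, canon)
    kmr <- lapply(rc, canon)
    counts <- table(c(unlist(kmf), unlist(kmr)))
    clean <- vapply(seq_along(reads), function(i)
        all(counts[kmf[[i]]] >= min_count), logical(1))
    if (sum(clean) < floor_reads) reads else reads[clean]
}

# longest suffix(a)-prefix(b) exact overlap >= min_overlap, or containment
# of b in a (coded as overlap = nchar(b) with contained = TRUE); 0 if none
.pairOverlap <- function(a, b, min_overlap) {
    na <- nchar(a); nb <- nchar(b)
    if (nb <= na && grepl(b, a, fixed = TRUE))
        return(c(len = nb, contained = 1))
    kmax <- min(na, nb) - (nb <= na)   # k == nb would be containment
    if (kmax < min_overlap) return(c(len = 0, contained = 0))
    ks <- kmax:min_overlap
    hit <- substring(a, na - ks + 1, na) == substring(b, 1, ks)
    if (any(hit)) c(len = ks[which(hit)[1]], contained = 0)
    else c(len = 0, contained = 0)
}

#' Greedy overlap-layout-consensus contig assembly
#'
#' Repeatedly merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least \code{min_overlap} bases, considering
#' both orientations of the incoming sequence; a sequence fully contained in
#' another is absorbed.  Ties on overlap length break lexicographically.
#' Contigs supported by fewer than \code{min_reads} reads are discarded.
#'
#' @param reads character vector of reads (any orientation).
#' @param min_overlap minimum exact overlap (default 31).
#' @param min_reads minimum read support per reported contig (default 2).
#' @return character vector of contigs, longest first (then lexicographic),
#'   with read support as the \code{support} attribute.
#' @export
assembleContigs <- function(reads, min_overlap = 31L, min_reads = 2L) {
    reads <- reads[nzchar(reads)]
    if (!length(reads)) return(character(0))
    tab <- table(reads)
    seqs <- names(tab)
    supp <- as.integer(tab)
    rcs <- revcompChar(seqs)
    n <- length(seqs)

    # best action per ordered pair over orientation combinations (rc of
    # both is the swapped pair's forward case, so three combos suffice):
    # returns overlap length, containment flag, orientation code 1..3
    # (1: a+b, 2: a+rc(b), 3: rc(a)+b)
    best <- function(i, j) {
        cands <- rbind(c(.pairOverlap(seqs[i], seqs[j], min_overlap), 1),
                       c(.pairOverlap(seqs[i], rcs[j], min_overlap), 2),
                       c(.pairOverlap(rcs[i], seqs[j], min_overlap), 3))
        w <- which.max(cands[, 1])
        c(len = unname(cands[w, 1]), contained = unname(cands[w, 2]),
          orient = unname(cands[w, 3]))
    }
    L <- matrix(0L, n, n); Ct <- matrix(0L, n, n); Or <- matrix(1L, n, n)
    if (n > 1) {
        for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
            bb <- best(i, j)
            L[i, j] <- bb[["len"]]; Ct[i, j] <- bb[["contained"]]
            Or[i, j] <- bb[["orient"]]
        }
    }

    repeat {
        if (length(seqs) < 2 || max(L) < min_overlap && max(L * Ct) == 0)
            break
        if (max(L) == 0) break
        orientPair <- function(i, j) {
            o <- Or[i, j]
            c(if (o == 3) rcs[i] else seqs[i],
              if (o == 2) rcs[j] else seqs[j])
        }
        cand <- which(L == max(L), arr.ind = TRUE)
        if (nrow(cand) > 1) {   # lexicographic tie-break on (a', b')
            keys <- apply(cand, 1, function(ij)
                paste(orientPair(ij[1], ij[2]), collapse = "\r"))
            cand <- cand[order(keys)[1], , drop = FALSE]
        }
        i <- cand[1, 1]; j <- cand[1, 2]
        ab <- orientPair(i, j)
        merged <- if (Ct[i, j] == 1) ab[1] else
            paste0(ab[1], substring(ab[2], L[i, j] + 1, nchar(ab[2])))
        msupp <- supp[i] + supp[j]

        keep <- setdiff(seq_along(seqs), c(i, j))
        seqs <- c(seqs[keep], merged)
        rcs <- c(rcs[keep], revcompChar(merged))
        supp <- c(supp[keep], msupp)
        L <- L[keep, keep, drop = FALSE]
        Ct <- Ct[keep, keep, drop = FALSE]
        Or <- Or[keep, keep, drop = FALSE]
        m <- length(seqs)
        if (m == 1) {
            L <- matrix(0L, 1, 1); Ct <- matrix(0L, 1, 1)
            Or <- matrix(1L, 1, 1)
        } else {
            L <- rbind(cbind(L, 0L), 0L)
            Ct <- rbind(cbind(Ct, 0L), 0L)
            Or <- rbind(cbind(Or, 1L), 1L)
        }
        if (m > 1) {
            for (x in seq_len(m - 1)) {
                bb <- best(x, m)
                L[x, m] <- bb[["len"]]; Ct[x, m] <- bb[["contained"]]
                Or[x, m] <- bb[["orient"]]
                bb <- best(m, x)
                L[m, x] <- bb[["len"]]; Ct[m, x] <- bb[["contained"]]
                Or[m, x] <- bb[["orient"]]
            }
        }
    }

    ok <- supp >= min_reads
    seqs <- seqs[ok]; supp <- supp[ok]
    ord <- order(-nchar(seqs), seqs)
    structure(seqs[ord], support = supp[ord])
}

#' Polish a contig by majority vote of anchored reads
#'
#' Reads are anchored onto the contig by their modal exact k-mer offset
#' (both orientations; at least \code{min_anchors} agreeing k-mers) and a
#' per-position base vote is taken: within the contig the consensus
#' replaces the contig base wherever a strict majority differs, removing
#' residual substitution errors that exact-overlap assembly can
#' incorporate; beyond the contig ends the consensus extends the contig
#' wherever at least \code{min_ext_cov} anchored reads cover a position,
#' restoring template termini that assembly-side read filtering may have
#' trimmed.
#'
#' @param contig contig sequence.
#' @param reads read pool (any orientation).
#' @param k anchoring k-mer size (default 15).
#' @param min_anchors minimum agreeing k-mers to place a read (default 3).
#' @param min_ext_cov minimum read coverage to extend past an end
#'   (default 2).
#' @return list: \code{seq} (polished contig), \code{n_placed} (reads
#'   anchored).
#' @export
polishContig <- function(contig, reads, k = 15L, min_anchors = 3L,
                         min_ext_cov = 2L) {
    L <- nchar(contig)
    if (L < k || !length(reads))
        return(list(seq = contig, n_placed = 0L))
    ckmers <- substring(contig, 1:(L - k + 1), k:L)
    bases <- c("A", "C", "G", "T")

    placeOne <- function(r) {
        n <- nchar(r)
        if (n < k) return(NULL)
        rkmers <- substring(r, 1:(n - k + 1), k:n)
        pos <- match(rkmers, ckmers)
        off <- pos - seq_along(rkmers) + 1L
        off <- off[!is.na(off)]
        if (!length(off)) return(NULL)
        tab <- table(off)
        if (max(tab) < min_anchors) return(NULL)
        list(offset = as.integer(names(tab)[which.max(tab)]), read = r)
    }

    placed <- list()
    for (r0 in reads) {
        hit <- placeOne(r0)
        if (is.null(hit)) hit <- placeOne(revcompChar(r0))
        if (!is.null(hit)) placed[[length(placed) + 1]] <- hit
    }
    if (!length(placed)) return(list(seq = contig, n_placed = 0L))

    offs <- vapply(placed, `[[`, integer(1), "offset")
    lens <- vapply(placed, function(h) nchar(h$read), integer(1))
    lo <- min(1L, min(offs))
    hi <- max(L, max(offs + lens - 1L))
    W <- hi - lo + 1L
    votes <- matrix(0L, 4, W, dimnames = list(bases, NULL))
    for (h in placed) {
        rch <- strsplit(h$read, "")[[1]]
        cols <- h$offset + seq_along(rch) - 1L - lo + 1L
        for (b in bases) {
            sel <- rch == b
            if (any(sel))
                votes[b, cols[sel]] <- votes[b, cols[sel]] + 1L
        }
    }

    cov <- colSums(votes)
    cols_ctg <- (1L:L) - lo + 1L
    out <- rep(NA_character_, W)
    cch <- strsplit(contig, "")[[1]]
    out[cols_ctg] <- cch
    for (p in which(cov > 0)) {
        top <- bases[which.max(votes[, p])]
        in_ctg <- p >= cols_ctg[1] && p <= cols_ctg[L]
        if (in_ctg) {
            if (votes[top, p] > cov[p] / 2) out[p] <- top
        } else if (cov[p] >= min_ext_cov) {
            out[p] <- top
        }
    }
    # keep only extensions contiguous with the contig body
    left <- cols_ctg[1]
    while (left > 1L && !is.na(out[left - 1L])) left <- left - 1L
    right <- cols_ctg[L]
    while (right < W && !is.na(out[right + 1L])) right <- right + 1L
    list(seq = paste(out[left:right], collapse = ""),
         n_placed = length(placed))
}

# local alignment of a contig strand against one segment; returns the hit
.alignHit <- function(ctg, segseq, submat) {
    aln <- pairwiseAlignment(ctg, segseq, type = "local",
                             substitutionMatrix = submat,
                             gapOpening = 4, gapExtension = 1)
    pr <- pattern(aln); sr <- subject(aln)
    list(score = Biostrings::score(aln),
         identity = pid(aln, type = "PID1"),
         seg_start = Biostrings::start(sr), seg_end = Biostrings::end(sr),
         ctg_start = Biostrings::start(pr), ctg_end = Biostrings::end(pr),
         recovery = Biostrings::width(sr) / nchar(segseq),
         aligned_ctg_width = Biostrings::width(pr))
}

#' Annotate a contig against germline V and J segments
#'
#' Smith-Waterman local alignment (match +1, mismatch -2, gap opening 4,
#' gap extension 1) of the contig against every V and every J segment on
#' both strands.  The best-scoring hit per class is reported with percent
#' identity over aligned columns, the fraction of the germline segment
#' recovered, contig-side coordinates and coverage, and the junction (contig
#' bases between the V-hit end and the J-hit start, when both hits lie on
#' the same strand).  Hits scoring below \code{score_min} are absent.  A
#' runner-up segment of a different name within 5\% of the best score marks
#' the hit as ambiguous.
#'
#' @param contig contig nucleotide sequence.
#' @param segments a [SegmentSet-class].
#' @param score_min minimum alignment score for a hit (default 20).
#' @return list with \code{v}, \code{j} (each NULL or a hit: name, score,
#'   identity, recovery, qcov, ctg_start, ctg_end, seg_start, seg_end,
#'   strand, ambiguous) and \code{junction} (NA when undefined).
#' @export
annotateContig <- function(contig, segments, score_min = 20) {
    stopifnot(is(segments, "SegmentSet"), nchar(contig) > 0)
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -2)
    strands <- c("+" = contig, "-" = revcompChar(contig))

    bestOf <- function(segs) {
        hits <- list()
        for (st in names(strands)) for (nm in names(segs)) {
            h <- .alignHit(strands[[st]], as.character(segs[[nm]]), submat)
            h$name <- nm; h$strand <- st
            hits[[length(hits) + 1]] <- h
        }
        sc <- vapply(hits, `[[`, numeric(1), "score")
        if (max(sc) < score_min) return(NULL)
        top <- hits[[which.max(sc)]]
        rival <- sc[vapply(hits, `[[`, character(1), "name") != top$name]
        top$ambiguous <- length(rival) > 0 && max(rival) >= 0.95 * top$score
        top
    }

    vhit <- bestOf(vSegments(segments))
    jhit <- bestOf(jSegments(segments))

    junction <- NA_character_
    if (!is.null(vhit) && !is.null(jhit)) {
        if (vhit$strand == jhit$strand &&
            jhit$ctg_start > vhit$ctg_end) {
            junction <- substring(strands[[vhit$strand]],
                                  vhit$ctg_end + 1, jhit$ctg_start - 1)
        } else if (vhit$strand == jhit$strand) {
            junction <- ""   # abutting or overlapping hits
        }
    }

    # contig-side coverage of the eligible span (see vignette)
    nctg <- nchar(contig)
    if (!is.null(vhit))
        vhit$qcov <- vhit$aligned_ctg_width / vhit$ctg_end
    if (!is.null(jhit))
        jhit$qcov <- jhit$aligned_ctg_width / (nctg - jhit$ctg_start + 1)
    list(v = vhit, j = jhit, junction = junction)
}

#' Filter an annotated contig into a recombination call
#'
#' A contig is evidence for TCR-beta V(D)J recombination when a V and a J
#' hit are both present and unambiguous on the same strand, both identities
#' are at least \code{min_identity} percent, at least \code{min_recovery} of
#' each germline segment is recovered, the contig-side coverage of each hit
#' is at least \code{min_qcov}, and the contig carries no stop codon in the
#' reading frame defined by the V segment's frame offset from the V hit
#' through the end of the J hit.  Failure reasons enumerate every violated
#' criterion.
#'
#' @param ann output of [annotateContig()].
#' @param contig the contig sequence.
#' @param segments the [SegmentSet-class] used for annotation (for frame
#'   offsets).
#' @param min_identity percent identity threshold (default 90).
#' @param min_recovery,min_qcov fraction thresholds (default 0.9).
#' @return list: \code{pass}, \code{reasons} (character), \code{v_name},
#'   \code{j_name}, \code{junction}, plus the hit records.
#' @export
callRecombination <- function(ann, contig, segments, min_identity = 90,
                              min_recovery = 0.9, min_qcov = 0.9) {
    reasons <- character(0)
    v <- ann$v; j <- ann$j
    if (is.null(v)) reasons <- c(reasons, "no V hit")
    if (is.null(j)) reasons <- c(reasons, "no J hit")
    if (!is.null(v) && !is.null(j)) {
        if (v$strand != j$strand)
            reasons <- c(reasons, "V and J hits on opposite strands")
        if (isTRUE(v$ambiguous)) reasons <- c(reasons, "ambiguous V hit")
        if (isTRUE(j$ambiguous)) reasons <- c(reasons, "ambiguous J hit")
    }
    chk <- function(hit, cls) {
        r <- character(0)
        if (hit$identity < min_identity)
            r <- c(r, sprintf("%s identity < %g", cls, min_identity))
        if (hit$recovery < min_recovery)
            r <- c(r, sprintf("%s recovery < %g%%", cls,
                              100 * min_recovery))
        if (hit$qcov < min_qcov)
            r <- c(r, sprintf("%s contig coverage < %g%%", cls,
                              100 * min_qcov))
        r
    }
    if (!is.null(v)) reasons <- c(reasons, chk(v, "V"))
    if (!is.null(j)) reasons <- c(reasons, chk(j, "J"))

    if (!is.null(v) && !is.null(j) && v$strand == j$strand) {
        ctg <- if (v$strand == "+") contig else revcompChar(contig)
        frame <- vFrames(segments)[[v$name]]
        # contig position carrying the first in-frame base of the V segment
        anchor <- v$ctg_start + (frame + 1L - v$seg_start)
        while (anchor < 1L) anchor <- anchor + 3L
        region <- substring(ctg, anchor, j$ctg_end)
        if (hasStopInFrame(region, 0L))
            reasons <- c(reasons, "stop codon")
    }

    list(pass = length(reasons) == 0,
         reasons = reasons,
         v_name = if (is.null(v)) NA_character_ else v$name,
         j_name = if (is.null(j)) NA_character_ else j$name,
         junction = ann$junction,
         v = v, j = j, contig = contig)
}

#' Detect V(D)J recombination in one cell's reads
#'
#' Runs the full per-cell detection chain: k-mer recruitment of read pairs,
#' greedy overlap assembly of the recruited reads, germline annotation of
#' each contig, and filtering.  The cell is positive when at least one
#' contig yields a passing call; all passing (V, J) pairs are reported (one
#' is expected per T cell).
#'
#' @param readset one element of [generateCellReads()] output.
#' @param segments a [SegmentSet-class].
#' @param k recruitment k-mer size.
#' @param min_overlap,min_reads assembly parameters.
#' @param min_identity,min_recovery,min_qcov filter thresholds.
#' @return list: \code{cell_id}, \code{positive}, \code{vj_pairs}
#'   (data.frame v/j of passing calls), \code{calls} (all call records).
#' @export
detectCellVdj <- function(readset, segments, k = 25L, min_overlap = 31L,
                          min_reads = 2L, min_identity = 90,
                          min_recovery = 0.9, min_qcov = 0.9) {
    rec <- recruitReads(readset, segments, k = k)
    calls <- list()
    if (!is.null(rec) && nrow(rec) > 0) {
        allreads <- c(rec$read1, rec$read2)
        pool <- filterErrorReads(allreads)
        contigs <- assembleContigs(pool,
                                   min_overlap = min_overlap,
                                   min_reads = min_reads)
        if (length(contigs) > 1) {
            # polish fragments and retry merging, then re-polish
            pol <- unique(vapply(contigs, function(ctg)
                polishContig(ctg, allreads)$seq, character(1),
                USE.NAMES = FALSE))
            contigs <- assembleContigs(pol, min_overlap = min_overlap,
                                       min_reads = 1L)
        }
        if (length(contigs)) {
            pol <- lapply(contigs, polishContig, reads = allreads)
            placed <- vapply(pol, `[[`, integer(1), "n_placed")
            contigs <- unique(vapply(pol, `[[`, character(1),
                                     "seq")[placed >= min_reads])
        }
        for (ctg in contigs) {
            ann <- annotateContig(ctg, segments)
            calls[[length(calls) + 1]] <-
                callRecombination(ann, ctg, segments,
                                  min_identity = min_identity,
                                  min_recovery = min_recovery,
                                  min_qcov = min_qcov)
        }
    }
    passing <- Filter(function(cl) cl$pass, calls)
    vj <- unique(data.frame(
        v = vapply(passing, `[[`, character(1), "v_name"),
        j = vapply(passing, `[[`, character(1), "j_name")))
    list(cell_id = readset$cell_id,
         positive = nrow(vj) > 0,
         vj_pairs = vj,
         calls = calls)
}

#' Detect V(D)J recombination across all cells
#'
#' @param readsets list from [generateCellReads()].
#' @param segments a [SegmentSet-class].
#' @param ... passed to [detectCellVdj()].
#' @return data.frame: \code{cell}, \code{positive}, \code{v}, \code{j}
#'   (best passing pair, NA when negative), \code{n_passing}.
#' @export
detectVdjAcrossCells <- function(readsets, segments, ...) {
    rows <- lapply(readsets, function(rs) {
        d <- detectCellVdj(rs, segments, ...)
        data.frame(cell = d$cell_id,
                   positive = d$positive,
                   v = if (d$positive) d$vj_pairs$v[1] else NA_character_,
                   j = if (d$positive) d$vj_pairs$j[1] else NA_character_,
                   n_passing = nrow(d$vj_pairs))
    })
    do.call(rbind, rows)
}

#' Association of V(D)J detection with cluster membership and trbc1
#'
#' Two-sided Fisher's exact tests on the 2x2 tables (VDJ-positive x in the
#' cluster of interest) and (VDJ-positive x trbc1 expression above the TPM
#' threshold).
#'
#' @param positive logical vector, VDJ detection per evaluable cell.
#' @param cluster_labels cluster label per cell.
#' @param trbc1_tpm trbc1 TPM per cell.
#' @param cluster_of_interest the cluster tested for association.
#' @param tpm_threshold expression threshold (default 5 TPM, strict >).
#' @return list: \code{p_cluster}, \code{p_trbc1}, \code{degenerate} flags.
#' @export
associateVdj <- function(positive, cluster_labels, trbc1_tpm,
                         cluster_of_interest, tpm_threshold = 5) {
    stopifnot(length(positive) == length(cluster_labels),
              length(positive) == length(trbc1_tpm))
    testOne <- function(x) {
        tab <- table(factor(positive, c(FALSE, TRUE)),
                     factor(x, c(FALSE, TRUE)))
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
            return(list(p = 1, degenerate = TRUE))
        list(p = fisher.test(tab)$p.value, degenerate = FALSE)
    }
    a <- testOne(cluster_labels == cluster_of_interest)
    b <- testOne(trbc1_tpm > tpm_threshold)
    list(p_cluster = a$p, p_trbc1 = b$p,
         degenerate = c(cluster = a$degenerate, trbc1 = b$degenerate))
}
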