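#' Default literature marker sets for zebrafish lymphoid/myeloid typing
#'
#' Minimal marker sets: T cells (cd4, cd8a, cd8b, cd28, ctla4), NK-like
#' cells (all members of the nitr, dicp and nk-lysin families, matched by
#' gene-id prefix against the supplied gene universe), and myeloid cells
#' (spi1b).
#'
#' @param genes character vector of gene ids against which family-level
#'   markers (nitr*, dicp*, nkl*) are expanded.
#' @return named list of gene-id vectors.
#' @export
defaultMarkerSets <- function(genes) {
    fam <- function(prefixes) {
        hits <- genes[grepl(paste0("^(", paste(prefixes, collapse = "|"),
                                   ")"), genes)]
        unique(hits)
    }
    list(T = intersect(c("cd4", "cd8a", "cd8b", "cd28", "ctla4"), genes),
         NK = fam(c("nitr", "dicp", "nkl")),
         myeloid = intersect("spi1b", genes))
}

#' Marker sets from the synthetic generator's planted truth
#'
#' @param sce SingleCellExperiment from [generateExpressionDataset()].
#' @return named list of planted marker gene ids per population.
#' @export
markerSetsFromTruth <- function(sce) {
    mo <- rowData(sce)$marker_of
    split(rownames(sce)[!is.na(mo)], mo[!is.na(mo)])
}

#' Marker-set scores per cell
#'
#' The score of a marker set in a cell is the mean E (log2(TPM+1)) over the
#' set's genes present in the matrix.  Genes absent from the matrix are
#' dropped with a warning; a set with no present genes is an error.
#'
#' @param m an [ExpressionMatrix-class] in E units.
#' @param sets named list of gene-id vectors.
#' @return numeric matrix, cells x sets.
#' @export
markerScore <- function(m, sets) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "E",
              length(sets) > 0, !is.null(names(sets)))
    v <- exprValues(m)
    out <- vapply(names(sets), function(nm) {
        present <- intersect(sets[[nm]], rownames(v))
        if (!length(present))
            stop("marker set '", nm, "' has no genes in the matrix")
        if (length(present) < length(sets[[nm]]))
            warning(length(sets[[nm]]) - length(present), " marker gene(s) ",
                    "of set '", nm, "' absent from matrix; dropped")
        colMeans(v[present, , drop = FALSE])
    }, numeric(ncol(v)))
    rownames(out) <- colnames(v)
    out
}

#' Assign cell identities from marker scores
#'
#' A cell is assigned the identity of the unique marker set whose score is
#' strictly above the threshold; cells where zero or two-plus sets exceed it
#' are left unassigned.
#'
#' @param scores cells x sets score matrix from [markerScore()].
#' @param threshold score cutoff (strict >; default 1).
#' @return character vector of labels (set names or \code{"unassigned"}).
#' @export
assignIdentity <- function(scores, threshold = 1) {
    stopifnot(all(is.finite(scores)))
    above <- scores > threshold
    n_above <- rowSums(above)
    labels <- rep("unassigned", nrow(scores))
    one <- n_above == 1
    labels[one] <- colnames(scores)[apply(above[one, , drop = FALSE], 1,
                                          which)]
    setNames(labels, rownames(scores))
}

#' Dropout-aware differential expression, one group versus the rest
#'
#' A two-part statistic suited to zero-inflated single-cell data: per gene,
#' (i) a detection-rate component, Fisher's exact test on the 2x2 table of
#' detected (TPM > 0) versus not in group and rest, and (ii) an expression
#' component, the Wilcoxon rank-sum test on E values restricted to cells
#' detecting the gene.  The two signed z-scores are combined by weighted
#' Stouffer's method (weights: square root of the informative cell counts),
#' the combined two-sided p-values are Holm-adjusted across genes, and the
#' adjusted p is mapped back to a signed z.  The fold-change is the log2
#' ratio of group mean TPM with a pseudocount of 1.
#'
#' @param m an [ExpressionMatrix-class] in TPM units.
#' @param group_labels vector of group labels per cell.
#' @param group_of_interest the label tested against all other cells.
#' @return data.frame per gene: \code{gene}, \code{log2fc}, \code{z},
#'   \code{adj_z}, \code{p}, \code{adj_p}, \code{det_frac_in},
#'   \code{det_frac_out}.
#' @export
differentialExpression <- function(m, group_labels, group_of_interest) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "TPM")
    tpm <- exprValues(m)
    if (length(group_labels) != ncol(tpm))
        stop("group_labels must have one label per cell")
    inA <- group_labels == group_of_interest
    nA <- sum(inA); nB <- sum(!inA)
    if (nA < 3 || nB < 3)
        stop("need at least 3 cells in the group and in the rest")
    E <- log2(tpm + 1)

    res <- lapply(seq_len(nrow(tpm)), function(g) {
        xA <- tpm[g, inA]; xB <- tpm[g, !inA]
        fc <- log2((mean(xA) + 1) / (mean(xB) + 1))
        kA <- sum(xA > 0); kB <- sum(xB > 0)
        det_sign <- sign(kA / nA - kB / nB)

        z_det <- NA_real_; w_det <- NA_real_
        if (kA + kB > 0 && kA + kB < nA + nB) {
            p_det <- fisher.test(matrix(c(kA, nA - kA, kB, nB - kB), 2))$
                p.value
            z_det <- pToZ(p_det, if (det_sign == 0) 1 else det_sign)
            if (det_sign == 0) z_det <- 0
            w_det <- sqrt(nA + nB)
        }

        z_rank <- NA_real_; w_rank <- NA_real_
        eA <- E[g, inA][xA > 0]; eB <- E[g, !inA][xB > 0]
        if (length(eA) >= 2 && length(eB) >= 2) {
            wt <- suppressWarnings(wilcox.test(eA, eB, exact = FALSE,
                                               correct = TRUE))
            rank_sign <- sign(wt$statistic - length(eA) * length(eB) / 2)
            z_rank <- pToZ(wt$p.value, if (rank_sign == 0) 1 else rank_sign)
            if (rank_sign == 0) z_rank <- 0
            w_rank <- sqrt(length(eA) + length(eB))
        }

        z <- stoufferZ(c(z_det, z_rank), c(w_det, w_rank))
        if (is.na(z)) z <- 0
        c(fc = fc, z = z, dfi = kA / nA, dfo = kB / nB)
    })
    res <- do.call(rbind, res)

    p <- zToP(res[, "z"])
    adj_p <- p.adjust(p, method = "holm")
    adj_z <- pToZ(adj_p, ifelse(res[, "z"] >= 0, 1, -1))
    adj_z[res[, "z"] == 0] <- 0

    data.frame(gene = rownames(tpm),
               log2fc = unname(res[, "fc"]),
               z = unname(res[, "z"]),
               adj_z = unname(adj_z),
               p = unname(p),
               adj_p = unname(adj_p),
               det_frac_in = unname(res[, "dfi"]),
               det_frac_out = unname(res[, "dfo"]),
               row.names = NULL)
}

#' Build extended cell-type signatures from differential expression
#'
#' Genes with log2 fold-change strictly above \code{fc_min} and adjusted
#' z-score strictly above \code{adjz_min} form each type's extended
#' signature, ordered by decreasing fold-change.  Genes qualifying for two
#' or more types are removed from all (disjointness).
#'
#' @param de_list named list of [differentialExpression()] tables, one per
#'   type.
#' @param fc_min,adjz_min inclusion thresholds (strict).
#' @return A [SignatureSet-class].
#' @export
buildSignatures <- function(de_list, fc_min = 2, adjz_min = 3) {
    stopifnot(is.list(de_list), !is.null(names(de_list)))
    picked <- lapply(de_list, function(de) {
        d <- de[de$log2fc > fc_min & de$adj_z > adjz_min, , drop = FALSE]
        d <- d[order(-d$log2fc, d$gene), c("gene", "log2fc", "adj_z")]
        rownames(d) <- NULL
        d
    })
    all_genes <- unlist(lapply(picked, `[[`, "gene"))
    dup <- unique(all_genes[duplicated(all_genes)])
    picked <- lapply(picked, function(d) d[!d$gene %in% dup, , drop = FALSE])
    for (nm in names(picked))
        if (nrow(picked[[nm]]) == 0)
            warning("empty signature for type '", nm, "'")
    SignatureSet(picked)
}

#' Standardized signature scores per cell
#'
#' The raw score of a signature in a cell is the mean E over its genes; raw
#' scores are then min-max standardized to [0, 1] per signature across
#' cells.  If all raw scores of a signature are equal the standardized
#' scores are defined as 0.
#'
#' @param m an [ExpressionMatrix-class] in E units.
#' @param sig a [SignatureSet-class].
#' @return numeric matrix, cells x signatures, values in [0, 1].
#' @export
signatureScore <- function(m, sig) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "E",
              is(sig, "SignatureSet"))
    sigs <- signatureGenes(sig)
    if (any(vapply(sigs, nrow, integer(1)) == 0))
        stop("empty signature(s): ",
             paste(names(sigs)[vapply(sigs, nrow, integer(1)) == 0],
                   collapse = ", "))
    v <- exprValues(m)
    out <- vapply(names(sigs), function(nm) {
        genes <- intersect(sigs[[nm]]$gene, rownames(v))
        if (!length(genes))
            stop("signature '", nm, "' has no genes in the matrix")
        raw <- colMeans(v[genes, , drop = FALSE])
        rng <- range(raw)
        if (diff(rng) == 0) return(rep(0, length(raw)))
        (raw - rng[1]) / diff(rng)
    }, numeric(ncol(v)))
    rownames(out) <- colnames(v)
    out
}

#' Enrichment of cluster genes in a mammalian cell-type signature
#'
#' Compares, via two-sided Fisher's exact test, the proportion of genes with
#' orthologs inside a mammalian signature between a cluster's differentially
#' expressed genes and the non-differentially-expressed background.
#'
#' @param de_genes,background_genes disjoint gene-id sets.
#' @param ortholog_map named character vector: gene id -> ortholog id in the
#'   signature's species (NA when no ortholog).
#' @param signature character vector of signature gene ids (ortholog space).
#' @return list: \code{table} (2x2), \code{odds_ratio} (sample OR, NA when
#'   undefined), \code{p}, \code{degenerate} flag.
#' @export
crossSpeciesEnrichment <- function(de_genes, background_genes, ortholog_map,
                                   signature) {
    if (length(intersect(de_genes, background_genes)))
        stop("DE and background gene sets must be disjoint")
    hit <- function(g) {
        o <- unname(ortholog_map[g])
        !is.na(o) & o %in% signature
    }
    a <- sum(hit(de_genes)); b <- length(de_genes) - a
    c_ <- sum(hit(background_genes)); d <- length(background_genes) - c_
    tab <- matrix(c(a, b, c_, d), 2,
                  dimnames = list(c("in_signature", "not"),
                                  c("DE", "background")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(list(table = tab, odds_ratio = NA_real_, p = 1,
                    degenerate = TRUE))
    or <- (a * d) / (b * c_)
    list(table = tab,
         odds_ratio = if (is.nan(or)) NA_real_ else or,
         p = fisher.test(tab)$p.value,
         degenerate = FALSE)
}

#' Side-scatter comparisons between cell groups
#'
#' For each unordered pair of groups, and for each group against all others
#' pooled, reports the percent difference of medians,
#' (median_a / median_b - 1) * 100, and the two-sided Wilcoxon rank-sum
#' p-value (exact for group sizes <= 20 without ties, otherwise normal
#' approximation with tie correction).
#'
#' @param ssc numeric vector of SSC values.
#' @param labels group label per cell.
#' @return data.frame: \code{group_a}, \code{group_b} (a group name or
#'   \code{"rest"}), \code{median_a}, \code{median_b},
#'   \code{percent_diff}, \code{p}, \code{flag}.
#' @export
sscComparison <- function(ssc, labels) {
    stopifnot(length(ssc) == length(labels))
    labels <- as.character(labels)
    groups <- unique(labels)
    cmp <- function(a_name, b_name, xa, xb) {
        if (length(xa) < 2 || length(xb) < 2)
            stop("need at least 2 cells per compared group")
        ma <- median(xa); mb <- median(xb)
        flag <- ""
        pd <- if (mb == 0) { flag <- "zero median denominator"; NA_real_ }
              else (ma / mb - 1) * 100
        use_exact <- max(length(xa), length(xb)) <= 20 &&
            !anyDuplicated(c(xa, xb))
        p <- suppressWarnings(
            wilcox.test(xa, xb, exact = use_exact, correct = TRUE)$p.value)
        data.frame(group_a = a_name, group_b = b_name,
                   median_a = ma, median_b = mb,
                   percent_diff = pd, p = p, flag = flag)
    }
    rows <- list()
    if (length(groups) > 1) {
        for (pr in combn(groups, 2, simplify = FALSE))
            rows[[length(rows) + 1]] <-
                cmp(pr[1], pr[2], ssc[labels == pr[1]], ssc[labels == pr[2]])
        for (g in groups)
            rows[[length(rows) + 1]] <-
                cmp(g, "rest", ssc[labels == g], ssc[labels != g])
    }
    do.call(rbind, rows)
}
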