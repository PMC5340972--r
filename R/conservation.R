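#' Derive cell-type signature genes from bulk expression
#'
#' Reproduces the mammalian signature-derivation scheme on a bulk or
#' microarray expression matrix: genes are prefiltered by requiring a
#' maximal group-mean expression of at least \code{prefilter}; each merged
#' group is tested against all other samples with an empirical-Bayes
#' moderated t-statistic (per-gene pooled variances shrunk toward a common
#' prior whose scale and degrees of freedom are estimated by method of
#' moments on the log variances); genes at Benjamini-Hochberg adjusted
#' p below \code{adj_p_cutoff} are ordered by decreasing fold-change and the
#' top \code{top_n} taken; finally genes appearing in the top list of two or
#' more types are removed from all lists.
#'
#' @param bulk numeric gene x sample matrix (normalized, log-scale units).
#' @param groups sample group labels (one per column).
#' @param prefilter minimal maximal group-mean expression (e.g. 5 for mouse
#'   arrays, 8 for human).
#' @param adj_p_cutoff BH-adjusted p cutoff (default 0.01).
#' @param top_n signature size per type (default 100).
#' @param merge_map optional named character vector renaming groups before
#'   testing (e.g. \code{c(CD4 = "T", CD8 = "T", monocyte = "myeloid",
#'   granulocyte = "myeloid")}).
#' @param prior_df override the estimated prior degrees of freedom (0 gives
#'   the ordinary t-test; NULL estimates by method of moments).
#' @return A [SignatureSet-class] (log2fc = difference of group means;
#'   adj_z = BH-adjusted p mapped to a z-scale).
#' @export
deriveSignatureGenes <- function(bulk, groups, prefilter = 5,
                                 adj_p_cutoff = 0.01, top_n = 100,
                                 merge_map = NULL, prior_df = NULL) {
    stopifnot(is.matrix(bulk), !is.null(rownames(bulk)),
              length(groups) == ncol(bulk), top_n >= 1,
              adj_p_cutoff > 0, adj_p_cutoff < 1)
    groups <- as.character(groups)
    if (!is.null(merge_map)) {
        hit <- groups %in% names(merge_map)
        groups[hit] <- merge_map[groups[hit]]
    }
    tabs <- table(groups)
    if (any(tabs < 2))
        stop("each merged group needs at least 2 samples; offending: ",
             paste(names(tabs)[tabs < 2], collapse = ", "))

    gm <- vapply(names(tabs), function(g)
        rowMeans(bulk[, groups == g, drop = FALSE]), numeric(nrow(bulk)))
    keep <- apply(gm, 1, max) >= prefilter
    x <- bulk[keep, , drop = FALSE]

    sigs <- lapply(names(tabs), function(g) {
        inA <- groups == g
        nA <- sum(inA); nB <- sum(!inA)
        mA <- rowMeans(x[, inA, drop = FALSE])
        mB <- rowMeans(x[, !inA, drop = FALSE])
        ssA <- rowSums((x[, inA, drop = FALSE] - mA)^2)
        ssB <- rowSums((x[, !inA, drop = FALSE] - mB)^2)
        dg <- nA + nB - 2
        s2 <- (ssA + ssB) / dg
        eb <- .ebVariance(s2, dg, prior_df)
        tstat <- (mA - mB) / sqrt(eb$s2_post * (1 / nA + 1 / nB))
        p <- 2 * pt(-abs(tstat), df = dg + eb$d0_finite)
        adj <- p.adjust(p, "BH")
        d <- data.frame(gene = rownames(x), log2fc = mA - mB,
                        adj_z = pToZ(adj, ifelse(tstat >= 0, 1, -1)),
                        adj_p = adj, row.names = NULL)
        d <- d[d$adj_p < adj_p_cutoff & d$log2fc > 0, , drop = FALSE]
        if (nrow(d) == 0)
            warning("no significant genes for group '", g, "'")
        d <- d[order(-d$log2fc, d$gene), , drop = FALSE]
        head(d[, c("gene", "log2fc", "adj_z")], top_n)
    })
    names(sigs) <- names(tabs)

    all_g <- unlist(lapply(sigs, `[[`, "gene"))
    dup <- unique(all_g[duplicated(all_g)])
    sigs <- lapply(sigs, function(d) {
        d <- d[!d$gene %in% dup, , drop = FALSE]
        rownames(d) <- NULL
        d
    })
    SignatureSet(sigs)
}

# empirical-Bayes shrinkage of per-gene variances: prior scale s0^2 and
# df d0 by method of moments on log(s2) (trigamma inversion)
.ebVariance <- function(s2, dg, prior_df = NULL) {
    s2 <- pmax(s2, 1e-12)
    if (!is.null(prior_df) && prior_df == 0)
        return(list(s2_post = s2, d0_finite = 0))
    z <- log(s2)
    e <- z - digamma(dg / 2) + log(dg / 2)
    ev <- var(e) - trigamma(dg / 2)
    if (is.null(prior_df)) {
        if (is.na(ev) || ev <= 0) {
            d0 <- Inf
        } else {
            f <- function(x) trigamma(x / 2) - ev
            d0 <- tryCatch(uniroot(f, c(0.2, 400))$root,
                           error = function(e2) Inf)
        }
    } else d0 <- prior_df
    if (is.finite(d0)) {
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
        list(s2_post = (d0 * s02 + dg * s2) / (d0 + dg),
             d0_finite = d0)
    } else {
        s02 <- exp(mean(e))
        list(s2_post = rep(s02, length(s2)), d0_finite = 2 * dg)
    }
}

#' Proportion of a gene set with an ortholog in a species
#'
#' @param genes gene-id vector.
#' @param table annotation table as from [generateAnnotationTables()].
#' @param species species name (column \code{ortholog_<species>}).
#' @param exclude optional gene ids to remove before evaluation (e.g. a
#'   receptor-family exclusion list for sensitivity analyses).
#' @return the fraction of evaluated genes with an ortholog, with
#'   attributes \code{n_evaluated} and \code{n_dropped} (genes absent from
#'   the table).
#' @export
orthologProportion <- function(genes, table, species, exclude = NULL) {
    col <- paste0("ortholog_", species)
    if (!col %in% names(table)) stop("no column '", col, "' in table")
    genes <- setdiff(genes, exclude)
    hit <- table$gene %in% genes
    n_dropped <- length(genes) - sum(hit)
    if (!sum(hit)) stop("no genes of the set found in the table")
    structure(mean(table[[col]][hit]),
              n_evaluated = sum(hit), n_dropped = n_dropped)
}

#' Permutation test for a difference in ortholog proportions
#'
#' The observed statistic is proportion(setA) - proportion(setB) in the
#' given species.  The null distribution permutes the set-membership labels
#' over the pooled genes \code{n_perm} times; the two-sided p-value uses the
#' add-one estimator \code{(1 + #{|null| >= |observed|}) / (1 + n_perm)} and
#' is therefore never zero.
#'
#' @param setA,setB disjoint gene-id vectors, each with >= 5 genes in the
#'   table.
#' @param table,species as in [orthologProportion()].
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param exclude optional exclusion list applied to both sets.
#' @return list: \code{p}, \code{observed}, \code{prop_a}, \code{prop_b}.
#' @export
permutationTestProportions <- function(setA, setB, table, species,
                                       n_perm = 10000, seed = 1L,
                                       exclude = NULL) {
    setA <- setdiff(setA, exclude); setB <- setdiff(setB, exclude)
    if (length(intersect(setA, setB))) stop("sets must be disjoint")
    col <- paste0("ortholog_", species)
    fA <- table[[col]][table$gene %in% setA]
    fB <- table[[col]][table$gene %in% setB]
    if (length(fA) < 5 || length(fB) < 5)
        stop("need at least 5 evaluable genes per set")
    obs <- mean(fA) - mean(fB)
    pool <- c(fA, fB)
    nA <- length(fA); n <- length(pool)
    null <- withSeed(seed, vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, nA)
        mean(pool[idx]) - mean(pool[-idx])
    }, numeric(1)))
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm)
    list(p = p, observed = obs, prop_a = mean(fA), prop_b = mean(fB))
}

#' Paired Wilcoxon test of per-species conservation proportions
#'
#' Wilcoxon signed-rank test on the paired per-species differences between
#' two gene sets' ortholog proportions; exact for up to 15 informative
#' pairs.
#'
#' @param props_a,props_b aligned numeric vectors of per-species
#'   proportions (>= 5 species).
#' @return two-sided p-value (1 when all differences are zero).
#' @export
pairedWilcoxonAcrossSpecies <- function(props_a, props_b) {
    stopifnot(length(props_a) == length(props_b), length(props_a) >= 5)
    d <- props_a - props_b
    if (all(d == 0)) return(1)
    n_inf <- sum(d != 0)
    suppressWarnings(
        wilcox.test(props_a, props_b, paired = TRUE,
                    exact = n_inf <= 15)$p.value)
}

# shared machinery of the two distributional comparisons
.ranksumCompare <- function(va, vb, what) {
    na_a <- sum(is.na(va)); na_b <- sum(is.na(vb))
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2)
        stop("need at least 2 genes with ", what, " in each set")
    p <- suppressWarnings(wilcox.test(va, vb)$p.value)
    list(median_a = median(va), median_b = median(vb), p = p,
         n_a = length(va), n_b = length(vb),
         n_missing = c(a = na_a, b = na_b))
}

#' Compare percent sequence identity between two gene sets
#'
#' Two-sided Wilcoxon rank-sum test on the (average) percent identities of
#' conserved genes; genes without an ortholog in the species are excluded
#' and counted.
#'
#' @param setA,setB gene-id vectors.
#' @param table,species as in [orthologProportion()].
#' @return list: medians, p, group sizes, missing counts.
#' @export
identityComparison <- function(setA, setB, table, species) {
    col <- paste0("identity_", species)
    if (!col %in% names(table)) stop("no column '", col, "' in table")
    .ranksumCompare(table[[col]][table$gene %in% setA],
                    table[[col]][table$gene %in% setB],
                    "an identity value")
}

#' Compare dN/dS between two gene sets
#'
#' As [identityComparison()] but on the per-gene dN/dS of one-to-one
#' orthologs; genes without a dN/dS value are excluded and counted.
#'
#' @param setA,setB gene-id vectors.
#' @param table annotation table with a \code{dnds} column.
#' @return list: medians, p, group sizes, missing counts.
#' @export
dndsComparison <- function(setA, setB, table) {
    .ranksumCompare(table$dnds[table$gene %in% setA],
                    table$dnds[table$gene %in% setB],
                    "a dN/dS value")
}

#' Top differentially expressed genes per cluster for conservation analysis
#'
#' Per cluster, keeps genes with z strictly above \code{z_min}, sorts by
#' decreasing fold-change (ties by gene id), and takes the top \code{top_n}.
#'
#' @param de_list named list of [differentialExpression()] tables per
#'   cluster.
#' @param z_min z filter (strict >; default 1).
#' @param top_n list size (default 100).
#' @return named list of gene-id vectors.
#' @export
zebrafishDeGeneSets <- function(de_list, z_min = 1, top_n = 100) {
    lapply(de_list, function(de) {
        d <- de[de$z > z_min, , drop = FALSE]
        d <- d[order(-d$log2fc, d$gene), , drop = FALSE]
        if (nrow(d) < top_n)
            warning("only ", nrow(d), " genes pass z > ", z_min)
        head(d$gene, top_n)
    })
}

#' Expression-matched background gene set
#'
#' Non-differentially-expressed genes whose mean E across cells is at least
#' the global mean of per-gene mean expression, removing the conservation
#' bias of lowly expressed genes.  The global mean is recomputed on the
#' input matrix.
#'
#' @param m an [ExpressionMatrix-class] in E units.
#' @param de_gene_sets list of DE gene-id vectors (excluded from the
#'   background).
#' @return character vector of background gene ids, with attribute
#'   \code{global_mean}.
#' @export
expressionMatchedBackground <- function(m, de_gene_sets) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "E")
    gm <- rowMeans(exprValues(m))
    global_mean <- mean(gm)
    de <- unique(unlist(de_gene_sets))
    bg <- names(gm)[gm >= global_mean & !names(gm) %in% de]
    structure(bg, global_mean = global_mean)
}
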