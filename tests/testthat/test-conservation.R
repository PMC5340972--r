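test_that("moderated t recovers planted bulk signatures", {
    set.seed(31)
    types <- c("T", "NK", "myeloid")
    n_per <- 4
    groups <- rep(types, each = n_per)
    n_genes <- 3 * 120 + 200
    x <- matrix(rnorm(n_genes * length(groups), 6, 0.5), n_genes,
                length(groups),
                dimnames = list(sprintf("g%04d", seq_len(n_genes)), NULL))
    planted <- split(seq_len(3 * 120), rep(1:3, each = 120))
    for (t in 1:3)
        x[planted[[t]], groups == types[t]] <-
            x[planted[[t]], groups == types[t]] + 3   # fold 8 on log2 scale
    sig <- deriveSignatureGenes(x, groups, prefilter = 5)
    for (t in 1:3) {
        got <- signatureGenes(sig)[[types[t]]]$gene
        expect_length(got, 100)
        expect_gte(sum(got %in% rownames(x)[planted[[t]]]), 95)
    }
})

test_that("moderated t reduces to ordinary t when the prior is removed", {
    set.seed(32)
    x <- matrix(rnorm(20 * 8, 6, 1), 20, 8,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    groups <- rep(c("A", "B"), each = 4)
    sig <- deriveSignatureGenes(x, groups, prefilter = -Inf,
                                adj_p_cutoff = 0.999999, top_n = 20,
                                prior_df = 0)
    # rebuild the ordinary two-sample pooled t-test p-values
    ords <- apply(x, 1, function(r)
        t.test(r[groups == "A"], r[groups == "B"],
               var.equal = TRUE)$p.value)
    d <- signatureGenes(sig)$A
    adj <- p.adjust(pmin(ords, 1), "BH")
    up <- names(ords)[rowMeans(x[, groups == "A"]) >
                      rowMeans(x[, groups == "B"])]
    keep <- intersect(names(sort(-adj[up])), d$gene)
    # every reported adjusted z maps back to the BH-adjusted ordinary p
    for (g in d$gene) {
        p_back <- 2 * pnorm(-abs(d$adj_z[d$gene == g]))
        expect_lt(abs(p_back - adj[g]), 1e-9)
    }
})

test_that("moderated t ranking agrees with the reference limma fit", {
    set.seed(33)
    x <- matrix(rnorm(300 * 8, 8, 1), 300, 8,
                dimnames = list(sprintf("g%03d", 1:300), NULL))
    groups <- rep(c("A", "B"), each = 4)
    x[1:40, groups == "A"] <- x[1:40, groups == "A"] + 4
    sig <- suppressWarnings(
        deriveSignatureGenes(x, groups, prefilter = -Inf, top_n = 40))
    design <- cbind(1, as.numeric(groups == "A"))
    fit <- limma::eBayes(limma::lmFit(x, design))
    top <- rownames(limma::topTable(fit, coef = 2, number = 40,
                                    sort.by = "logFC", p.value = 0.01))
    got <- signatureGenes(sig)$A$gene
    expect_gte(length(intersect(got, top)), 30)
})

test_that("ortholog proportions and their permutation test behave", {
    tab <- data.frame(gene = sprintf("g%d", 1:4),
                      ortholog_human = c(TRUE, TRUE, TRUE, FALSE))
    expect_equal(as.numeric(
        orthologProportion(sprintf("g%d", 1:4), tab, "human")), 0.75)
    expect_equal(as.numeric(
        orthologProportion(sprintf("g%d", 1:3), tab, "human")), 1)
    expect_identical(attr(orthologProportion(
        c("g1", "g2", "missing"), tab, "human"), "n_dropped"), 1L)

    props <- list(T_TM = c(human = 0.76), NK_TM = c(human = 0.36))
    big <- generateAnnotationTables(100, props, seed = 34)
    pT <- orthologProportion(big$gene[big$gene_set == "T_TM"], big,
                             "human")
    pN <- orthologProportion(big$gene[big$gene_set == "NK_TM"], big,
                             "human")
    expect_lt(abs(as.numeric(pT) - 0.76), 3 * sqrt(0.76 * 0.24 / 100))
    expect_lt(abs(as.numeric(pN) - 0.36), 3 * sqrt(0.36 * 0.64 / 100))

    # perfect separation at n = 10 per set: p near the hypergeometric floor
    sep <- data.frame(gene = sprintf("s%02d", 1:20),
                      ortholog_human = rep(c(TRUE, FALSE), each = 10))
    res <- permutationTestProportions(sprintf("s%02d", 1:10),
                                      sprintf("s%02d", 11:20),
                                      sep, "human", n_perm = 10000,
                                      seed = 35)
    expect_lte(res$p, 0.001)
    # identical composition: two-sided p cannot be small
    same <- data.frame(gene = sprintf("t%02d", 1:20),
                       ortholog_human = rep(c(TRUE, FALSE), 10))
    res2 <- permutationTestProportions(sprintf("t%02d", 1:10),
                                       sprintf("t%02d", 11:20),
                                       same, "human", n_perm = 2000,
                                       seed = 36)
    expect_gte(res2$p, 0.5)
    expect_error(permutationTestProportions(
        sprintf("s%02d", 1:10), sprintf("s%02d", 8:20), sep, "human"),
        "disjoint")
})

test_that("paired Wilcoxon across species matches sign enumeration", {
    expect_equal(pairedWilcoxonAcrossSpecies(rep(0.5, 8), rep(0.5, 8)), 1)
    a <- c(0.9, 0.8, 0.85, 0.95, 0.7, 0.88, 0.92, 0.81)
    b <- a - c(0.2, 0.1, 0.15, 0.12, 0.3, 0.11, 0.21, 0.14)
    p <- pairedWilcoxonAcrossSpecies(a, b)
    expect_equal(p, 2 / 2^8)
    expect_lt(abs(p - oracleSignedRank(a, b)), 1e-10)
    set.seed(37)
    a2 <- runif(8); b2 <- a2 + rnorm(8, 0, 0.1)
    expect_lt(abs(pairedWilcoxonAcrossSpecies(a2, b2) -
                  oracleSignedRank(a2, b2)), 1e-10)
})

test_that("identity and dN/dS comparisons use rank-sum with NA accounting", {
    tab <- data.frame(gene = sprintf("g%02d", 1:20),
                      identity_human = c(runif(10, 55, 65),
                                         runif(10, 75, 85)),
                      dnds = c(runif(10, 0.05, 0.15),
                               c(runif(8, 0.25, 0.35), NA, NA)))
    A <- sprintf("g%02d", 1:10); B <- sprintf("g%02d", 11:20)
    res <- identityComparison(A, B, tab, "human")
    expect_lt(res$median_a, res$median_b)
    expect_lt(res$p, 0.01)
    same <- identityComparison(A, A, tab, "human")
    expect_equal(same$p, 1)

    dn <- dndsComparison(A, B, tab)
    expect_lt(dn$median_a, dn$median_b)
    expect_identical(unname(dn$n_missing["b"]), 2L)
    expect_identical(dn$n_b, 8L)

    # exact small-n agreement with the enumeration oracle
    small <- data.frame(gene = sprintf("s%d", 1:8),
                        identity_human = c(61.2, 58.7, 70.1, 64.4,
                                           80.3, 77.9, 72.5, 69.8))
    r <- identityComparison(sprintf("s%d", 1:4), sprintf("s%d", 5:8),
                            small, "human")
    expect_lt(abs(r$p - oracleRankSum(small$identity_human[1:4],
                                      small$identity_human[5:8])), 1e-10)

    # planted strong separation at n = 50
    set.seed(38)
    big <- data.frame(gene = sprintf("b%03d", 1:100),
                      identity_human = c(rnorm(50, 60, 5),
                                         rnorm(50, 80, 5)))
    rb <- identityComparison(sprintf("b%03d", 1:50),
                             sprintf("b%03d", 51:100), big, "human")
    expect_lt(rb$p, 1e-6)
})

test_that("top cluster gene lists and matched background follow the filters", {
    set.seed(39)
    de <- data.frame(gene = sprintf("g%03d", 1:150),
                     log2fc = runif(150, 0, 6),
                     z = c(rep(1.0, 10), runif(140, 1.01, 6)),
                     adj_z = runif(150, 0, 6))
    sets <- zebrafishDeGeneSets(list(C1 = de), z_min = 1, top_n = 100)
    expect_length(sets$C1, 100)
    expect_false(any(de$gene[de$z == 1.0] %in% sets$C1))
    # ordering equals an independent sort
    ord <- de[de$z > 1, ]
    ord <- ord[order(-ord$log2fc, ord$gene), ]
    expect_identical(sets$C1, head(ord$gene, 100))
    expect_warning(zebrafishDeGeneSets(list(C1 = de[1:50, ]),
                                       top_n = 100), "pass")

    v <- matrix(c(0, 0, 0,   2, 4, 6,   1, 1, 1,   6, 2, 1), 4, 3,
                byrow = TRUE,
                dimnames = list(c("gz", "ga", "gb", "gc"),
                                c("c1", "c2", "c3")))
    m <- ExpressionMatrix(v, "E")
    bg <- expressionMatchedBackground(m, list(C1 = "gc"))
    expect_equal(attr(bg, "global_mean"), mean(c(0, 4, 1, 3)))
    expect_false("gz" %in% bg)       # mean 0 below global mean
    expect_false("gc" %in% bg)       # DE genes never in background
    expect_true("ga" %in% bg)
})

test_that("planted lowest-conservation species is minimal for every set", {
    species <- c("human", "mouse", "chicken", "lamprey")
    props <- list(T_TM = setNames(c(0.8, 0.75, 0.7, 0.2), species),
                  NK_TM = setNames(c(0.5, 0.45, 0.4, 0.1), species))
    tab <- generateAnnotationTables(150, props, seed = 40)
    for (s in names(props)) {
        genes <- tab$gene[tab$gene_set == s]
        pv <- vapply(species, function(sp)
            as.numeric(orthologProportion(genes, tab, sp)), numeric(1))
        expect_identical(names(which.min(pv)), "lamprey")
    }
})
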