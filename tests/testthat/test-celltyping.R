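test_that("marker scores are set means of E and guard missing genes", {
    v <- matrix(c(2, 4, 0, 0, 1, 3), 3, 2,
                dimnames = list(c("cd4", "cd8a", "spi1b"), c("c1", "c2")))
    m <- ExpressionMatrix(v, "E")
    sc <- markerScore(m, list(T = c("cd4", "cd8a"), My = "spi1b"))
    expect_equal(sc["c1", "T"], 3)
    expect_equal(sc["c1", "My"], 0)
    set.seed(8)
    v2 <- matrix(runif(12), 6, 2,
                 dimnames = list(sprintf("g%d", 1:6), c("a", "b")))
    sc2 <- markerScore(ExpressionMatrix(v2, "E"),
                       list(S = sprintf("g%d", 1:6)))
    expect_equal(unname(sc2[, "S"]), unname(colMeans(v2)))
    expect_warning(markerScore(m, list(T = c("cd4", "notagene"))),
                   "absent")
    expect_error(markerScore(m, list(T = "nope")), "no genes")
})

test_that("identity assignment requires a unique score above threshold", {
    sc <- rbind(c1 = c(T = 3.0, NK = 0.5, My = 0.2),
                c2 = c(T = 3.0, NK = 2.0, My = 0.0),
                c3 = c(T = 1.0, NK = 1.0, My = 1.0))
    lab <- assignIdentity(sc)
    expect_identical(unname(lab), c("T", "unassigned", "unassigned"))
    expect_true(all(assignIdentity(sc, threshold = Inf) == "unassigned"))
    sc2 <- rbind(c1 = c(T = 3, NK = 0, My = 0))
    expect_identical(unname(assignIdentity(sc2, threshold = -Inf)),
                     "unassigned")   # several sets exceed -Inf
})

test_that("differential expression separates planted signal from null", {
    set.seed(13)
    n <- 20
    tpm <- matrix(rexp(200 * 2 * n, 1 / 20), 200, 2 * n,
                  dimnames = list(sprintf("g%03d", 1:200),
                                  sprintf("c%03d", 1:(2 * n))))
    labels <- rep(c("A", "B"), each = n)
    # planted gene: E = 5 in all of A, zero in all of B
    tpm["g001", ] <- c(rep(2^5 - 1, n), rep(0, n))
    # identical gene in both groups
    tpm["g002", ] <- rep(7, 2 * n)
    de <- differentialExpression(ExpressionMatrix(tpm), labels, "A")
    g1 <- de[de$gene == "g001", ]
    expect_gt(g1$log2fc, 2)
    expect_gt(g1$adj_z, 3)
    g2 <- de[de$gene == "g002", ]
    expect_lt(abs(g2$log2fc), 1e-9)
    expect_lt(abs(g2$z), 1e-9)
    expect_true(all(abs(de$adj_z) <= abs(de$z) + 1e-9))

    # label symmetry: swapping groups negates fold-change and z
    deB <- differentialExpression(ExpressionMatrix(tpm), labels, "B")
    expect_equal(de$log2fc, -deB$log2fc, tolerance = 1e-9)
    expect_equal(de$z, -deB$z, tolerance = 1e-6)

    expect_error(differentialExpression(
        ExpressionMatrix(tpm[, 1:22]), c(rep("A", 2), rep("B", 20)), "A"),
        "at least 3")
})

test_that("no gene clears the signature thresholds under a permuted null", {
    set.seed(14)
    tpm <- matrix(rexp(200 * 30, 1 / 20), 200, 30,
                  dimnames = list(sprintf("g%03d", 1:200),
                                  sprintf("c%02d", 1:30)))
    labels <- sample(rep(c("A", "B"), each = 15))
    de <- differentialExpression(ExpressionMatrix(tpm), labels, "A")
    expect_identical(sum(de$adj_z > 3 & de$log2fc > 2), 0L)
})

test_that("signature construction keeps strict thresholds and disjointness", {
    de1 <- data.frame(gene = c("a", "b", "c", "d"),
                      log2fc = c(2.0, 3.0, 5.0, 4.0),
                      z = c(6, 4, 6, 5),
                      adj_z = c(5.0, 3.5, 3.0, 4.0))
    de2 <- data.frame(gene = c("d", "e"),
                      log2fc = c(3.5, 2.5),
                      z = c(5, 5),
                      adj_z = c(4.0, 3.2))
    sig <- buildSignatures(list(T1 = de1, T2 = de2))
    g1 <- signatureGenes(sig)$T1
    expect_false("a" %in% g1$gene)   # fc exactly 2: excluded (strict)
    expect_false("c" %in% g1$gene)   # adj z exactly 3: excluded
    expect_true("b" %in% g1$gene)
    expect_false("d" %in% g1$gene)   # qualifies for both: dropped from all
    expect_false("d" %in% signatureGenes(sig)$T2$gene)
    expect_true("e" %in% signatureGenes(sig)$T2$gene)
})

test_that("planted markers are recovered by DE on the synthetic dataset", {
    sce <- generateExpressionDataset(
        syntheticConfig(n_cells = 90, n_genes = 400,
                        population_proportions = c(0.45, 0.35, 0.2),
                        seed = 15))
    tpm <- asExpressionMatrix(sce)
    truth <- as.character(sce$true_type)
    de_list <- lapply(levels(sce$true_type), function(ty)
        differentialExpression(tpm, truth, ty))
    names(de_list) <- levels(sce$true_type)
    sig <- buildSignatures(de_list)
    mo <- SummarizedExperiment::rowData(sce)$marker_of
    for (ty in levels(sce$true_type)) {
        planted <- rownames(sce)[which(mo == ty)]
        got <- signatureGenes(sig)[[ty]]$gene
        expect_gte(sum(planted %in% got), 25)
    }
})

test_that("signature scores are min-max standardized per signature", {
    sig <- SignatureSet(list(S = data.frame(gene = c("g1", "g2"),
                                            log2fc = c(3, 3),
                                            adj_z = c(4, 4))))
    v <- matrix(c(2, 2, 6, 6), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
    sc <- signatureScore(ExpressionMatrix(v, "E"), sig)
    expect_equal(unname(sc[, "S"]), c(0, 1))
    v3 <- matrix(c(1, 1, 2, 2, 3, 3), 2, 3,
                 dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
    expect_equal(unname(signatureScore(ExpressionMatrix(v3, "E"),
                                       sig)[, "S"]),
                 c(0, 0.5, 1))
    flat <- matrix(1, 2, 3, dimnames = dimnames(v3))
    expect_equal(unname(signatureScore(ExpressionMatrix(flat, "E"),
                                       sig)[, "S"]),
                 c(0, 0, 0))
    # monotonicity under random raw scores
    set.seed(16)
    vr <- matrix(runif(20), 2, 10,
                 dimnames = list(c("g1", "g2"), sprintf("c%d", 1:10)))
    raw <- colMeans(vr)
    std <- signatureScore(ExpressionMatrix(vr, "E"), sig)[, "S"]
    expect_identical(order(raw), order(std))
})

test_that("cross-species enrichment matches the exact hypergeometric oracle", {
    genes_de <- sprintf("zde%02d", 1:10)
    genes_bg <- sprintf("zbg%02d", 1:10)
    map <- setNames(c(sprintf("H%02d", 1:10), sprintf("X%02d", 1:10)),
                    c(genes_de, genes_bg))
    res <- crossSpeciesEnrichment(genes_de, genes_bg, map,
                                  sprintf("H%02d", 1:10))
    expect_lt(abs(res$p - oracleFisher(10, 0, 0, 10)), 1e-10)
    expect_lt(abs(res$p - fisher.test(res$table)$p.value), 1e-12)

    map2 <- setNames(rep(c("H1", "H2"), 10), c(genes_de, genes_bg))
    sig2 <- "H1"
    r2 <- crossSpeciesEnrichment(genes_de[1:10], genes_bg[1:10],
                                 map2, sig2)
    expect_equal(r2$odds_ratio, 1)
    expect_equal(r2$p, 1)

    # DE genes never in the signature: sample odds ratio is zero
    r3 <- crossSpeciesEnrichment(genes_de, genes_bg, map,
                                 sprintf("X%02d", 1:5))
    expect_equal(r3$odds_ratio, 0)
    r4 <- crossSpeciesEnrichment(genes_de, genes_bg, map, "Hnone")
    expect_true(r4$degenerate)
    expect_equal(r4$p, 1)
    expect_error(crossSpeciesEnrichment(c("x", "y"), c("y", "z"), map,
                                        "H01"), "disjoint")
})

test_that("SSC comparisons report median differences and exact p-values", {
    set.seed(17)
    ssc <- c(rnorm(30, 100, 5), rnorm(30, 100, 5))
    lab <- rep(c("1", "2"), each = 30)
    res <- sscComparison(ssc, lab)
    r12 <- res[res$group_a == "1" & res$group_b == "2", ]
    expect_lt(abs(r12$percent_diff), 15)
    expect_gt(r12$p, 0.05)

    ssc2 <- c(rep(125, 5) + (0:4) * 1e-3, rep(100, 5) + (0:4) * 1e-3)
    lab2 <- rep(c("a", "b"), each = 5)
    res2 <- sscComparison(ssc2, lab2)
    rab <- res2[res2$group_a == "a" & res2$group_b == "b", ]
    expect_equal(rab$percent_diff, (125.002 / 100.002 - 1) * 100)
    expect_lt(abs(rab$p - oracleRankSum(ssc2[1:5], ssc2[6:10])), 1e-10)
})
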