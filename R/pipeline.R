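#' Default pipeline run configuration
#'
#' Every stage parameter defaults to the analysis' canonical value: QC at
#' 500 detected genes / 10,000 mapped reads, four principal coordinates,
#' marker score threshold 1, signature thresholds log2FC > 2 and adjusted
#' z > 3, recombinant pads 20/7/50 N, V(D)J filters at 90/90/90 with the
#' no-stop rule, top-100 cluster gene lists at z > 1, 10,000 permutations,
#' detection at >0 TPM in 1\% of cells, ubiquity at 10\%, and a 5 TPM
#' expression threshold for binary marker calls.
#'
#' @param seed global seed; every stage derives its own substream from it.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
    list(
        seed = as.integer(seed),
        stages = list(synthetic = TRUE, qc = TRUE, cluster = TRUE,
                      celltype = TRUE, vdj = TRUE, conservation = TRUE,
                      paralogs = TRUE),
        synthetic = list(),          # overrides for syntheticConfig()
        qc = list(min_genes = 500, min_reads = 10000),
        cluster = list(n_coords = 4, k_candidates = 2:8,
                       clamp_negative = FALSE),
        celltype = list(score_threshold = 1, fc_min = 2, adjz_min = 3,
                        tpm_expression_threshold = 5),
        vdj = list(n_v = 4, n_j = 3, n_cells = 12, read_len = 60,
                   n_background = 50, n_vdj = 50, error_rate = 0.01,
                   k = 25, min_overlap = 31, min_reads = 2,
                   min_identity = 90, min_recovery = 0.9, min_qcov = 0.9,
                   pads = c(20L, 7L, 50L)),
        conservation = list(
            n_genes_per_set = 100,
            species = c("human", "mouse", "chicken", "xenopus", "fugu",
                        "medaka", "stickleback", "lamprey"),
            props = list(T_TM = 0.76, NK_TM = 0.36,
                         T_cyto = 0.70, NK_cyto = 0.70),
            lamprey_scale = 0.3,
            n_perm = 10000,
            z_min = 1, top_n = 100),
        paralogs = list(n_recent_pairs = 37, n_early_pairs = 129,
                        divergence_prob_recent = 0.62,
                        divergence_prob_early = 0.94,
                        min_detect_frac = 0.01, ubiquity_frac = 0.10))
}

# merge user overrides into the default configuration (shallow per stage)
.mergeConfig <- function(config) {
    base <- defaultRunConfig(if (!is.null(config$seed)) config$seed else 1L)
    for (nm in names(config)) {
        if (is.list(base[[nm]]) && is.list(config[[nm]]))
            base[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
        else base[[nm]] <- config[[nm]]
    }
    base
}

#' Run the full synthetic-data pipeline
#'
#' Executes the stages in dependency order on synthetic data: generation,
#' quality control, log transform + empirical-Bayes batch adjustment +
#' correlation dissimilarity + classical MDS + Ward clustering with
#' silhouette-selected k, marker-score cell typing with signature
#' construction and SSC comparisons, per-cell V(D)J detection with
#' association tests, ortholog-conservation statistics on planted
#' annotation tables, and paralog-pair classification.  All randomness
#' derives from the global seed; rerunning with the same configuration
#' reproduces the report exactly.
#'
#' @param config a configuration list (see [defaultRunConfig()]) or the
#'   path to a YAML file holding one.
#' @param out_dir optional directory; when given, a JSON run report and key
#'   TSV artifacts are written there.
#' @return the run report: a nested list of per-stage parameters and key
#'   outputs.
#' @export
runPipeline <- function(config = defaultRunConfig(), out_dir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- .mergeConfig(config)
    seed <- cfg$seed
    report <- list(seed = seed)
    st <- cfg$stages

    sce <- NULL; qc <- NULL; E <- NULL; adjE <- NULL; clu <- NULL
    ids <- NULL; de_clusters <- NULL

    if (isTRUE(st$synthetic)) {
        scfg <- do.call(syntheticConfig,
                        utils::modifyList(list(seed = seed + 1L),
                                          cfg$synthetic))
        sce <- generateExpressionDataset(scfg)
        report$synthetic <- list(
            n_cells = ncol(sce), n_genes = nrow(sce),
            population_sizes = as.list(table(sce$true_type)))
    }

    if (isTRUE(st$qc) && !is.null(sce)) {
        tpm <- asExpressionMatrix(sce, "tpm", "TPM")
        reads <- setNames(sce$mapped_reads, colnames(sce))
        qc <- qcFilter(tpm, reads, cfg$qc$min_genes, cfg$qc$min_reads)
        report$qc <- list(n_input = qc$report$n_input,
                          n_removed = qc$report$n_removed,
                          n_retained = qc$report$n_retained,
                          mean_detected_genes =
                              qc$report$mean_detected_genes)
    }

    if (isTRUE(st$cluster) && !is.null(qc)) {
        keep <- qc$report$per_cell$cell[qc$report$per_cell$pass]
        E <- logTransform(qc$matrix)
        batch <- sce$batch[match(keep, colnames(sce))]
        adjE <- ebBatchAdjust(E, batch,
                              clamp_negative = cfg$cluster$clamp_negative)
        D <- pccDissimilarity(adjE)
        emb <- classicalMDS(D, k = cfg$cluster$n_coords)
        clu <- wardCluster(emb, n_coords = cfg$cluster$n_coords,
                           k_candidates = cfg$cluster$k_candidates)
        report$cluster <- list(
            k = clu$k,
            silhouette = as.list(clu$silhouette),
            cluster_sizes = as.list(table(clu$labels)),
            leading_eigenvalues = emb$eigenvalues[1:6])
    }

    if (isTRUE(st$celltype) && !is.null(E)) {
        sets <- markerSetsFromTruth(sce)
        scores <- markerScore(E, sets)
        ids <- assignIdentity(scores, cfg$celltype$score_threshold)
        assigned <- ids[ids != "unassigned"]
        de_types <- lapply(names(sets), function(ty) {
            if (sum(assigned == ty) < 3) return(NULL)
            cells <- names(ids)
            differentialExpression(
                ExpressionMatrix(exprValues(qc$matrix)[, names(assigned)],
                                 "TPM"),
                assigned, ty)
        })
        names(de_types) <- names(sets)
        de_types <- Filter(Negate(is.null), de_types)
        sigs <- buildSignatures(de_types, cfg$celltype$fc_min,
                                cfg$celltype$adjz_min)
        sscores <- signatureScore(E, sigs)
        ssc <- sscComparison(sce$ssc[match(names(ids), colnames(sce))],
                             if (!is.null(clu)) clu$labels else
                                 as.character(ids))
        report$celltype <- list(
            assigned_counts = as.list(table(ids)),
            signature_sizes = lapply(signatureGenes(sigs), nrow),
            ssc = ssc)

        if (!is.null(clu)) {
            de_clusters <- lapply(sort(unique(clu$labels)), function(k)
                differentialExpression(qc$matrix,
                                       as.character(clu$labels),
                                       as.character(k)))
            names(de_clusters) <- paste0("C", sort(unique(clu$labels)))
        }
    }

    if (isTRUE(st$vdj) && !is.null(sce)) {
        v <- cfg$vdj
        segs <- generateGermlineSegments(v$n_v, v$n_j, seed = seed + 2L)
        ref <- buildRecombinantReference(segs, pads = v$pads)
        # balanced evaluable subset: half VDJ-positive truth, half negative
        pos <- which(sce$has_vdj); neg <- which(!sce$has_vdj)
        n_half <- min(length(pos), length(neg), ceiling(v$n_cells / 2))
        sel <- c(head(pos, n_half), head(neg, n_half))
        sub <- sce[, sel]
        readsets <- generateCellReads(sub, segs, read_len = v$read_len,
                                      n_background = v$n_background,
                                      n_vdj = v$n_vdj,
                                      error_rate = v$error_rate,
                                      seed = seed + 3L)
        det <- detectVdjAcrossCells(readsets, segs, k = v$k,
                                    min_overlap = v$min_overlap,
                                    min_reads = v$min_reads,
                                    min_identity = v$min_identity,
                                    min_recovery = v$min_recovery,
                                    min_qcov = v$min_qcov)
        truth <- sub$has_vdj
        assoc <- NULL
        if (!is.null(clu)) {
            lab <- clu$labels[match(det$cell,
                                    qc$report$per_cell$cell[
                                        qc$report$per_cell$pass])]
            ok <- !is.na(lab)
            # T-marker analogue transcript: first planted T marker gene
            tgene <- rownames(sce)[which(rowData(sce)$marker_of ==
                                         levels(sce$true_type)[1])][1]
            tv <- assay(sce, "tpm")[tgene, det$cell]
            t_cluster <- as.integer(names(which.max(
                table(clu$labels[match(
                    colnames(sce)[sce$true_type ==
                                  levels(sce$true_type)[1]],
                    qc$report$per_cell$cell[qc$report$per_cell$pass])]))))
            assoc <- associateVdj(det$positive[ok], lab[ok], tv[ok],
                                  t_cluster,
                                  cfg$celltype$tpm_expression_threshold)
        }
        report$vdj <- list(
            n_reference_entries = length(ref),
            n_evaluated = nrow(det),
            sensitivity = if (any(truth)) mean(det$positive[truth]) else NA,
            specificity = if (any(!truth)) mean(!det$positive[!truth])
                          else NA,
            association = assoc)
    }

    if (isTRUE(st$conservation)) {
        cv <- cfg$conservation
        props <- lapply(cv$props, function(p) {
            pr <- setNames(rep(p, length(cv$species)), cv$species)
            pr["lamprey"] <- p * cv$lamprey_scale
            pr
        })
        ident_means <- list(T_TM = 75, NK_TM = 60, T_cyto = 70,
                            NK_cyto = 70)[names(props)]
        dnds_means <- setNames(
            ifelse(grepl("^NK", names(props)), 0.3, 0.15), names(props))
        ann <- generateAnnotationTables(cv$n_genes_per_set, props,
                                        identity_means = ident_means,
                                        dnds_means = dnds_means,
                                        seed = seed + 4L)
        setOf <- function(s) ann$gene[ann$gene_set == s]
        perm <- permutationTestProportions(setOf("T_TM"), setOf("NK_TM"),
                                           ann, "human",
                                           n_perm = cv$n_perm,
                                           seed = seed + 5L)
        perSpecies <- function(s) vapply(cv$species, function(sp)
            as.numeric(orthologProportion(setOf(s), ann, sp)), numeric(1))
        pA <- perSpecies("T_TM"); pB <- perSpecies("NK_TM")
        pw <- pairedWilcoxonAcrossSpecies(pA, pB)
        idc <- identityComparison(setOf("T_TM"), setOf("NK_TM"), ann,
                                  "human")
        dnd <- dndsComparison(setOf("T_TM"), setOf("NK_TM"), ann)
        zsets <- NULL; bg <- NULL
        if (!is.null(de_clusters)) {
            zsets <- zebrafishDeGeneSets(de_clusters, cv$z_min, cv$top_n)
            bg <- expressionMatchedBackground(
                if (!is.null(adjE)) logTransform(qc$matrix) else E, zsets)
        }
        report$conservation <- list(
            tm_proportion_T_human = unname(pA["human"]),
            tm_proportion_NK_human = unname(pB["human"]),
            permutation_p = perm$p,
            paired_wilcoxon_p = pw,
            identity_medians = c(idc$median_a, idc$median_b),
            identity_p = idc$p,
            dnds_medians = c(dnd$median_a, dnd$median_b),
            dnds_p = dnd$p,
            zebrafish_top_set_sizes =
                if (!is.null(zsets)) lapply(zsets, length) else NULL,
            background_size = if (!is.null(bg)) length(bg) else NULL)
    }

    if (isTRUE(st$paralogs)) {
        pv <- cfg$paralogs
        fam <- generateParalogFamilies(pv$n_recent_pairs, pv$n_early_pairs,
                                       pv$divergence_prob_recent,
                                       pv$divergence_prob_early,
                                       seed = seed + 6L)
        patterns <- c(setNames(fam$planted_pattern_a, fam$gene_a),
                      setNames(fam$planted_pattern_b, fam$gene_b))
        cls <- classifyPairs(fam, patterns)
        report$paralogs <- list(
            summary = cls$summary,
            neofunctionalization_recent_pct =
                cls$summary["recent", "neofunctionalization_pct"],
            neofunctionalization_early_pct =
                cls$summary["early", "neofunctionalization_pct"])
    }

    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(report,
                             file.path(out_dir, "run_report.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
        if (!is.null(qc))
            write.table(qc$report$per_cell,
                        file.path(out_dir, "qc_report.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report
}
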