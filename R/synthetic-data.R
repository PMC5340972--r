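#' Configuration for the synthetic single-cell expression generator
#'
#' Bundles and validates every knob of [generateExpressionDataset()].  The
#' defaults describe a spleen-derived lymphoid/myeloid sort: three cell
#' populations (T, NK-like, myeloid-like) in proportions 0.65/0.31/0.04 over
#' 300 cells, profiled on two plates (batches), with negative-binomial counts,
#' logistic dropout, and per-type side-scatter (SSC) locations increasing from
#' T through NK-like to myeloid-like cells.
#'
#' @param n_cells total number of cells.
#' @param population_proportions fractions for (T, NK-like, myeloid-like);
#'   must sum to 1.  Cell counts are apportioned by largest remainder with
#'   ties broken toward the earlier population.
#' @param n_genes number of genes.
#' @param n_markers_per_type number of planted marker genes per population.
#' @param marker_fold multiplicative boost of a marker's expression in its
#'   own population (off-population expression is scaled down to 0.1\% of
#'   baseline so marker scores discriminate).
#' @param n_batches number of batches (plates/fish); cells are assigned
#'   round-robin within each population so batches are balanced.
#' @param batch_shift_sd SD (log2 units) of the per-gene multiplicative
#'   batch effect.
#' @param dropout_midpoint,dropout_slope logistic dropout model: a gene with
#'   mean expression m = log2(mean TPM + 1) is zeroed in a cell with
#'   probability \code{plogis(dropout_slope * (dropout_midpoint - m))}.
#'   Set \code{dropout_midpoint = -Inf} for no dropout.
#' @param library_size_mean,library_size_sd mean and SD of per-cell mapped
#'   reads; drawn log-normal with moment-matched parameters.
#' @param nb_size negative-binomial size (inverse dispersion) of counts.
#' @param ssc_location_per_type per-type SSC location (arbitrary FACS units).
#' @param ssc_scale SD of SSC around the type location.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(n_cells = 60, seed = 1)
#' @export
syntheticConfig <- function(n_cells = 300,
                            population_proportions = c(T = 0.65,
                                                       NK = 0.31,
                                                       myeloid = 0.04),
                            n_genes = 2000,
                            n_markers_per_type = 30,
                            marker_fold = 32,
                            n_batches = 2,
                            batch_shift_sd = 0.4,
                            dropout_midpoint = 6,
                            dropout_slope = 1,
                            library_size_mean = 8e5,
                            library_size_sd = 3e5,
                            nb_size = 2,
                            ssc_location_per_type = c(T = 100, NK = 125,
                                                      myeloid = 180),
                            ssc_scale = 10,
                            seed = 1L) {
    stopifnot(abs(sum(population_proportions) - 1) < 1e-9,
              length(population_proportions) == 3L,
              n_cells > 0, n_genes > 0, n_markers_per_type > 0,
              n_batches > 0, batch_shift_sd >= 0,
              library_size_mean > 0, library_size_sd > 0, nb_size > 0,
              length(ssc_location_per_type) == 3L)
    if (is.null(names(population_proportions)))
        names(population_proportions) <- c("T", "NK", "myeloid")
    cfg <- list(n_cells = as.integer(n_cells),
                population_proportions = population_proportions,
                n_genes = as.integer(n_genes),
                n_markers_per_type = as.integer(n_markers_per_type),
                marker_fold = marker_fold,
                n_batches = as.integer(n_batches),
                batch_shift_sd = batch_shift_sd,
                dropout_midpoint = dropout_midpoint,
                dropout_slope = dropout_slope,
                library_size_mean = library_size_mean,
                library_size_sd = library_size_sd,
                nb_size = nb_size,
                ssc_location_per_type = ssc_location_per_type,
                ssc_scale = ssc_scale,
                seed = as.integer(seed))
    class(cfg) <- "SyntheticConfig"
    cfg
}

#' Generate a synthetic gene x cell expression dataset with planted truth
#'
#' Simulates an indexed-sort single-cell RNA-seq experiment: counts are drawn
#' negative-binomial around population-specific mean profiles (marker genes
#' elevated only in their own population), TPM is derived from counts and
#' fixed per-gene effective lengths, a multiplicative per-batch per-gene
#' effect is applied, and zeros are introduced by a logistic dropout model in
#' mean log-expression.  TPM columns are renormalized to 1e6 after dropout.
#' True population labels, batch, SSC, mapped reads, and a has-VDJ flag (one
#' recombined TCR-beta transcript per T cell) are recorded as ground truth.
#'
#' @param config a [syntheticConfig()] list.
#' @return A [SingleCellExperiment::SingleCellExperiment] with assays
#'   \code{counts} and \code{tpm}; \code{colData} columns \code{batch},
#'   \code{true_type}, \code{ssc}, \code{mapped_reads}, \code{has_vdj};
#'   \code{rowData} columns \code{marker_of} and \code{eff_length}.
#' @examples
#' sce <- generateExpressionDataset(syntheticConfig(n_cells = 40,
#'                                                  n_genes = 300, seed = 1))
#' @export
generateExpressionDataset <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    withSeed(config$seed, {
        nG <- config$n_genes; nC <- config$n_cells
        types <- names(config$population_proportions)
        sizes <- largestRemainder(nC, config$population_proportions)
        true_type <- factor(rep(types, sizes), levels = types)

        gene_id <- sprintf("gene%05d", seq_len(nG))
        cell_id <- sprintf("cell%04d", seq_len(nC))
        eff_len <- sample(500:5000, nG, replace = TRUE)
        lambda <- rlnorm(nG, meanlog = 0.5, sdlog = 1.2)

        stopifnot(3L * config$n_markers_per_type <= nG)
        marker_idx <- split(seq_len(3L * config$n_markers_per_type),
                            rep(seq_len(3L), each = config$n_markers_per_type))
        marker_of <- rep(NA_character_, nG)
        for (t in seq_along(types)) marker_of[marker_idx[[t]]] <- types[t]

        profiles <- matrix(lambda, nG, 3L,
                           dimnames = list(gene_id, types))
        for (t in seq_along(types)) {
            idx <- marker_idx[[t]]
            profiles[idx, ] <- profiles[idx, ] * 0.001
            profiles[idx, t] <- lambda[idx] * config$marker_fold
        }

        # balanced batch assignment within each population
        batch <- unlist(lapply(sizes, function(s)
            rep_len(seq_len(config$n_batches), s)), use.names = FALSE)
        batch_fac <- matrix(2^rnorm(nG * config$n_batches, 0,
                                    config$batch_shift_sd),
                            nG, config$n_batches)

        # log-normal library sizes, moment matched
        m <- config$library_size_mean; s <- config$library_size_sd
        sdlog <- sqrt(log(1 + (s / m)^2))
        meanlog <- log(m) - sdlog^2 / 2
        libsize <- rlnorm(nC, meanlog, sdlog)

        counts <- matrix(0, nG, nC, dimnames = list(gene_id, cell_id))
        for (j in seq_len(nC)) {
            w <- profiles[, as.integer(true_type[j])] * batch_fac[, batch[j]]
            rate <- w * eff_len
            mu <- libsize[j] * rate / sum(rate)
            counts[, j] <- rnbinom(nG, mu = mu, size = config$nb_size)
        }

        tpm <- counts / eff_len
        tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6

        # logistic dropout vs mean log2 expression
        if (is.finite(config$dropout_midpoint)) {
            mexpr <- log2(rowMeans(tpm) + 1)
            pdrop <- plogis(config$dropout_slope *
                            (config$dropout_midpoint - mexpr))
            drop <- matrix(rbinom(nG * nC, 1, rep(pdrop, nC)) == 1, nG, nC)
            counts[drop] <- 0
            tpm[drop] <- 0
            cs <- colSums(tpm)
            cs[cs == 0] <- 1
            tpm <- sweep(tpm, 2, cs, "/") * 1e6
        }

        ssc <- rnorm(nC, config$ssc_location_per_type[as.integer(true_type)],
                     config$ssc_scale)
        has_vdj <- true_type == types[1]

        SingleCellExperiment(
            assays = list(counts = counts, tpm = tpm),
            rowData = DataFrame(marker_of = marker_of, eff_length = eff_len,
                                row.names = gene_id),
            colData = DataFrame(batch = factor(batch),
                                true_type = true_type,
                                ssc = ssc,
                                mapped_reads = colSums(counts),
                                has_vdj = has_vdj,
                                row.names = cell_id),
            metadata = list(config = config))
    })
}

#' Extract an assay of a dataset as an ExpressionMatrix
#'
#' @param sce a SingleCellExperiment from [generateExpressionDataset()].
#' @param assay_name \code{"tpm"} (unit TPM) or any E-unit assay.
#' @param unit the unit tag to attach.
#' @return An [ExpressionMatrix-class].
#' @export
asExpressionMatrix <- function(sce, assay_name = "tpm", unit = "TPM") {
    ExpressionMatrix(assay(sce, assay_name), unit = unit)
}

# sample one base that never completes a stop codon (TAA/TAG/TGA) ending at
# the current position, in any frame
.stopFreeSequence <- function(len, prefix = "") {
    bases <- c("A", "C", "G", "T")
    out <- character(len)
    last2 <- substring(prefix, max(1L, nchar(prefix) - 1L), nchar(prefix))
    for (i in seq_len(len)) {
        ok <- bases[!paste0(last2, bases) %in% c("TAA", "TAG", "TGA")]
        b <- sample(ok, 1L)
        out[i] <- b
        last2 <- paste0(substring(last2, nchar(last2)), b)
    }
    paste(out, collapse = "")
}

# percent identity of the global alignment of two sequences
.globalPid <- function(a, b) {
    pid(pairwiseAlignment(a, b, type = "global"), type = "PID1")
}

#' Generate germline V and J segments for simulation
#'
#' Produces random V and J nucleotide sequences free of stop codons in every
#' reading frame (so a recombined transcript can be open through V and J) and
#' mutually dissimilar (pairwise global identity < 90\%) so that germline
#' annotation of contigs is unambiguous.  Every J segment begins with "CC" so
#' that codons spanning a segment boundary can never form a stop.
#'
#' @param n_v,n_j number of V and J segments (>= 1).
#' @param len_v,len_j segment lengths (nt).
#' @param seed RNG seed.
#' @param max_tries retries per segment before giving up on the identity
#'   constraint.
#' @return A [SegmentSet-class]; all V frame offsets are 0.
#' @examples
#' segs <- generateGermlineSegments(2, 3, seed = 7)
#' @export
generateGermlineSegments <- function(n_v, n_j, len_v = 60, len_j = 30,
                                     seed = 1L, max_tries = 50L) {
    stopifnot(n_v >= 1, n_j >= 1, len_v >= 9, len_j >= 9)
    withSeed(seed, {
        draw <- function(n, len, prefix, label) {
            seqs <- character(0)
            for (i in seq_len(n)) {
                ok <- FALSE
                for (try in seq_len(max_tries)) {
                    cand <- paste0(prefix,
                                   .stopFreeSequence(len - nchar(prefix),
                                                     prefix = prefix))
                    if (!length(seqs) ||
                        all(vapply(seqs, .globalPid, numeric(1),
                                   b = cand) < 90)) {
                        seqs <- c(seqs, cand); ok <- TRUE; break
                    }
                }
                if (!ok)
                    stop("could not generate ", label,
                         " segments below 90% pairwise identity")
            }
            seqs
        }
        v <- draw(n_v, len_v, "", "V")
        j <- draw(n_j, len_j, "CC", "J")
        names(v) <- sprintf("V%02d", seq_len(n_v))
        names(j) <- sprintf("J%02d", seq_len(n_j))
        SegmentSet(v, j, vFrame = 0L)
    })
}

#' Simulate per-cell read sets with planted TCR-beta recombinants
#'
#' Every cell receives \code{n_background} read pairs drawn from random decoy
#' transcripts.  Cells flagged \code{has_vdj} additionally receive
#' \code{n_vdj} read pairs drawn uniformly from one recombined transcript
#' V + junction + J, where the junction is 0-10 non-templated bases (length
#' uniform; bases uniform, resampled under the constraint that the
#' recombinant carries no stop codon in the V reading frame).  Substitution
#' errors are applied per base at \code{error_rate}.
#'
#' @param dataset SingleCellExperiment from [generateExpressionDataset()].
#' @param segments a [SegmentSet-class].
#' @param read_len read length (nt); must not exceed the shortest possible
#'   recombinant.
#' @param n_background,n_vdj read-pair counts per cell.
#' @param error_rate per-base substitution rate, in [0, 0.1].
#' @param seed RNG seed.
#' @param max_junction maximum junction length (default 10).
#' @return A list of read sets, one per cell: \code{cell_id}, \code{pairs}
#'   (data.frame read1/read2/origin), and \code{truth} (v, j, junction) for
#'   VDJ-positive cells.
#' @export
generateCellReads <- function(dataset, segments, read_len = 60,
                              n_background = 200, n_vdj = 50,
                              error_rate = 0.01, seed = 1L,
                              max_junction = 10L) {
    if (error_rate < 0 || error_rate > 0.1)
        stop("error_rate must be in [0, 0.1]")
    vseq <- as.character(vSegments(segments))
    jseq <- as.character(jSegments(segments))
    vfr <- vFrames(segments)
    min_recomb <- min(nchar(vseq)) + min(nchar(jseq))
    if (read_len > min_recomb)
        stop("read_len exceeds the shortest possible recombinant (",
             min_recomb, " nt)")

    withSeed(seed, {
        decoys <- randomDNA(20L, 500L)
        bases <- c("A", "C", "G", "T")

        addErrors <- function(reads) {
            if (error_rate == 0 || !length(reads)) return(reads)
            vapply(reads, function(r) {
                n <- nchar(r)
                hit <- which(runif(n) < error_rate)
                if (!length(hit)) return(r)
                ch <- strsplit(r, "")[[1]]
                for (p in hit)
                    ch[p] <- sample(setdiff(bases, ch[p]), 1L)
                paste(ch, collapse = "")
            }, character(1), USE.NAMES = FALSE)
        }

        drawPairs <- function(template, n) {
            L <- nchar(template)
            s1 <- sample.int(L - read_len + 1L, n, replace = TRUE)
            s2 <- sample.int(L - read_len + 1L, n, replace = TRUE)
            r1 <- substring(template, s1, s1 + read_len - 1L)
            r2 <- revcompChar(substring(template, s2, s2 + read_len - 1L))
            data.frame(read1 = addErrors(r1), read2 = addErrors(r2))
        }

        makeJunction <- function(vname, jname) {
            len <- sample.int(max_junction + 1L, 1L) - 1L
            v <- vseq[vname]; j <- jseq[jname]
            if (len == 0L) return("")
            for (try in 1:100) {
                jn <- paste(sample(bases, len, replace = TRUE),
                            collapse = "")
                if (!hasStopInFrame(paste0(v, jn, j), vfr[vname]))
                    return(jn)
            }
            strrep("C", len)  # a C in every codon: never a stop
        }

        cd <- colData(dataset)
        empty <- data.frame(read1 = character(0), read2 = character(0),
                            origin = character(0))
        lapply(seq_len(ncol(dataset)), function(i) {
            pieces <- list(empty)
            if (n_background > 0) {
                bg <- do.call(rbind, lapply(
                    sample(decoys, n_background, replace = TRUE),
                    drawPairs, n = 1L))
                bg$origin <- "background"
                pieces <- c(pieces, list(bg))
            }
            truth <- NULL
            if (isTRUE(cd$has_vdj[i]) && n_vdj > 0) {
                vn <- sample(names(vseq), 1L)
                jn <- sample(names(jseq), 1L)
                junc <- makeJunction(vn, jn)
                recomb <- paste0(vseq[vn], junc, jseq[jn])
                vd <- drawPairs(recomb, n_vdj)
                vd$origin <- "vdj"
                pieces <- c(pieces, list(vd))
                truth <- list(v = vn, j = jn, junction = junc,
                              recombinant = recomb)
            }
            list(cell_id = rownames(cd)[i],
                 pairs = do.call(rbind, pieces), truth = truth)
        })
    })
}

#' Generate per-gene-set annotation tables with planted conservation
#'
#' Builds a gene annotation table (one row per gene) for a collection of
#' gene sets (for example T-cell versus NK-cell specific genes split by
#' membrane localization), planting per-species ortholog presence as
#' Bernoulli draws, percent sequence identity as truncated normals, and a
#' dN/dS value per gene.
#'
#' @param n_genes_per_set genes per set (scalar or named per-set vector).
#' @param planted_ortholog_props named list: set -> named numeric vector of
#'   per-species ortholog probabilities in [0, 1].
#' @param identity_means named list: set -> per-species mean percent identity
#'   (scalar recycled); SD 5, truncated to [0, 100].
#' @param dnds_means named numeric: per-set mean dN/dS; SD 0.1, truncated
#'   at 0.
#' @param localization named character: set -> localization class
#'   ("TM_or_secreted" or "cytoplasmic_or_nuclear").  Defaults by suffix:
#'   sets ending in "_TM" are TM_or_secreted.
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene}, \code{gene_set},
#'   \code{localization}, \code{dnds}, and per species
#'   \code{ortholog_<sp>} (logical) and \code{identity_<sp>} (numeric, NA
#'   where no ortholog).
#' @export
generateAnnotationTables <- function(n_genes_per_set,
                                     planted_ortholog_props,
                                     identity_means = NULL,
                                     dnds_means = NULL,
                                     localization = NULL,
                                     seed = 1L) {
    sets <- names(planted_ortholog_props)
    stopifnot(!is.null(sets))
    species <- names(planted_ortholog_props[[1]])
    stopifnot(!is.null(species))
    for (s in sets) {
        pr <- planted_ortholog_props[[s]]
        stopifnot(identical(names(pr), species), all(pr >= 0 & pr <= 1))
    }
    n <- rep_len(n_genes_per_set, length(sets))
    names(n) <- sets
    if (is.null(localization))
        localization <- setNames(ifelse(grepl("_TM$", sets),
                                        "TM_or_secreted",
                                        "cytoplasmic_or_nuclear"), sets)
    if (is.null(dnds_means))
        dnds_means <- setNames(rep(0.2, length(sets)), sets)

    withSeed(seed, {
        rows <- lapply(sets, function(s) {
            ng <- n[[s]]
            d <- data.frame(
                gene = sprintf("%s_g%04d", s, seq_len(ng)),
                gene_set = s,
                localization = localization[[s]],
                dnds = pmax(rnorm(ng, dnds_means[[s]], 0.1), 0))
            im <- if (is.null(identity_means)) 70 else identity_means[[s]]
            im <- rep_len(im, length(species))
            for (k in seq_along(species)) {
                sp <- species[k]
                pres <- runif(ng) < planted_ortholog_props[[s]][sp]
                idv <- pmin(pmax(rnorm(ng, im[k], 5), 0), 100)
                idv[!pres] <- NA_real_
                d[[paste0("ortholog_", sp)]] <- pres
                d[[paste0("identity_", sp)]] <- idv
            }
            d
        })
        do.call(rbind, rows)
    })
}

#' Taxon vocabularies for duplication-age classification
#'
#' The duplication-node taxa treated as "recent" (ray-finned fish and its
#' descendants) and "early" (bony vertebrates and its ancestors).
#' @export
RECENT_TAXA <- c("Actinopterygii", "Neopterygii", "Otophysa",
                 "Clupeocephala", "Danio rerio")

#' @rdname RECENT_TAXA
#' @export
EARLY_TAXA <- c("Euteleostomi", "Bilateria", "Chordata", "Vertebrata")

#' Generate paralog pairs with planted expression-pattern divergence
#'
#' Each pair is stamped with a duplication-node taxon from either the recent
#' (ray-finned-fish clade) or early (bony-vertebrate-and-older) vocabulary
#' and given planted expression-pattern labels: with the class-specific
#' divergence probability the two genes receive distinct informative
#' patterns, otherwise the same pattern.
#'
#' @param n_recent_pairs,n_early_pairs pair counts per age class.
#' @param divergence_prob_recent,divergence_prob_early probabilities in
#'   [0, 1] that a pair's two genes have diverged patterns.
#' @param seed RNG seed.
#' @return data.frame: \code{gene_a}, \code{gene_b}, \code{taxon},
#'   \code{planted_pattern_a}, \code{planted_pattern_b},
#'   \code{planted_diverged}.
#' @export
generateParalogFamilies <- function(n_recent_pairs = 37,
                                    n_early_pairs = 129,
                                    divergence_prob_recent = 0.62,
                                    divergence_prob_early = 0.94,
                                    seed = 1L) {
    stopifnot(divergence_prob_recent >= 0, divergence_prob_recent <= 1,
              divergence_prob_early >= 0, divergence_prob_early <= 1)
    informative <- c("C1-specific", "C2-specific", "C3-specific",
                     "C1-depleted", "C2-depleted", "C3-depleted")
    withSeed(seed, {
        onePair <- function(i, taxa, pdiv, tag) {
            diverged <- runif(1) < pdiv
            if (diverged) {
                pats <- sample(informative, 2L)
            } else {
                pats <- rep(sample(informative, 1L), 2L)
            }
            data.frame(gene_a = sprintf("%s_pair%04d_a", tag, i),
                       gene_b = sprintf("%s_pair%04d_b", tag, i),
                       taxon = sample(taxa, 1L),
                       planted_pattern_a = pats[1],
                       planted_pattern_b = pats[2],
                       planted_diverged = diverged)
        }
        rows <- c(lapply(seq_len(n_recent_pairs), onePair,
                         taxa = RECENT_TAXA,
                         pdiv = divergence_prob_recent, tag = "rec"),
                  lapply(seq_len(n_early_pairs), onePair,
                         taxa = EARLY_TAXA,
                         pdiv = divergence_prob_early, tag = "ear"))
        do.call(rbind, rows)
    })
}
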