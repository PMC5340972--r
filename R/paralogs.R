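#' Classify a duplication-node taxon as recent or early
#'
#' Recent duplications have their most recent common ancestor at the
#' ray-finned fish node (Actinopterygii) or any of its child nodes
#' (Neopterygii, Otophysa, Clupeocephala, Danio rerio); early duplications
#' map to bony vertebrates (Euteleostomi) or any of its parent taxa
#' (Bilateria, Chordata, Vertebrata).
#'
#' @param taxon character vector of duplication-node taxon labels.
#' @return character vector, \code{"recent"} or \code{"early"}.
#' @examples
#' classifyDuplicationAge(c("Clupeocephala", "Bilateria"))
#' @export
classifyDuplicationAge <- function(taxon) {
    out <- ifelse(taxon %in% RECENT_TAXA, "recent",
                  ifelse(taxon %in% EARLY_TAXA, "early", NA_character_))
    if (anyNA(out))
        stop("unknown duplication-node taxon: ",
             paste(unique(taxon[is.na(out)]), collapse = ", "))
    out
}

#' Unique recent-only and early-only duplicated gene sets
#'
#' Genes can appear in both recently and early duplicated pairs (multiple
#' duplication events); such overlap genes are removed from both classes so
#' the classes can be compared cleanly.
#'
#' @param table data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{taxon}.
#' @return list: \code{recent_only}, \code{early_only}, \code{overlap}
#'   (gene-id vectors) and \code{counts}.
#' @export
excludeOverlapGenes <- function(table) {
    age <- classifyDuplicationAge(table$taxon)
    recent <- unique(c(table$gene_a[age == "recent"],
                       table$gene_b[age == "recent"]))
    early <- unique(c(table$gene_a[age == "early"],
                      table$gene_b[age == "early"]))
    overlap <- intersect(recent, early)
    recent_only <- setdiff(recent, overlap)
    early_only <- setdiff(early, overlap)
    list(recent_only = recent_only,
         early_only = early_only,
         overlap = overlap,
         counts = c(recent_only = length(recent_only),
                    early_only = length(early_only),
                    overlap = length(overlap),
                    union = length(union(recent, early))))
}

#' Genes detected in the dataset
#'
#' A gene is detected when its TPM is strictly positive in at least
#' \code{ceiling(min_frac * n_cells)} cells.
#'
#' @param m an [ExpressionMatrix-class] in TPM units.
#' @param min_frac minimal fraction of cells (default 0.01).
#' @return character vector of detected gene ids.
#' @export
detectedGenes <- function(m, min_frac = 0.01) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "TPM")
    v <- exprValues(m)
    need <- ceiling(min_frac * ncol(v))
    rownames(v)[rowSums(v > 0) >= need]
}

#' Per-gene detection fractions by cluster
#'
#' @param m an [ExpressionMatrix-class] in TPM units.
#' @param labels cluster label per cell.
#' @return numeric matrix, genes x clusters, fraction of cells with
#'   TPM > 0.
#' @export
detectionFractions <- function(m, labels) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "TPM")
    v <- exprValues(m)
    labels <- as.character(labels)
    vapply(sort(unique(labels)), function(g)
        rowMeans(v[, labels == g, drop = FALSE] > 0),
        numeric(nrow(v)))
}

#' Assign an expression-pattern label to each gene
#'
#' Labels follow a strict precedence: (1) membership in a cluster's top
#' differentially expressed genes gives "<cluster>-specific"; (2) membership
#' in the top genes of the reversed contrast (both other clusters versus
#' this one) gives "<cluster>-depleted"; (3) detection (TPM > 0) in at least
#' \code{min_frac} of the cells of every cluster gives "ubiquitous";
#' otherwise "none".
#'
#' @param genes gene ids to label.
#' @param specific_sets named list of per-cluster top gene vectors (must be
#'   disjoint).
#' @param depleted_sets named list of per-cluster depleted-top gene vectors
#'   (same cluster names).
#' @param detect_frac genes x clusters detection-fraction matrix
#'   ([detectionFractions()]).
#' @param min_frac ubiquity threshold (default 0.10).
#' @return named character vector of pattern labels.
#' @export
assignExpressionPattern <- function(genes, specific_sets, depleted_sets,
                                    detect_frac, min_frac = 0.10) {
    all_specific <- unlist(specific_sets)
    if (anyDuplicated(all_specific))
        stop("specific top lists must be disjoint across clusters")
    cl_names <- names(specific_sets)
    out <- setNames(rep("none", length(genes)), genes)
    for (g in genes) {
        hit <- cl_names[vapply(specific_sets, function(s) g %in% s,
                               logical(1))]
        if (length(hit) == 1) { out[g] <- paste0(hit, "-specific"); next }
        hit <- cl_names[vapply(depleted_sets, function(s) g %in% s,
                               logical(1))]
        if (length(hit) >= 1) { out[g] <- paste0(hit[1], "-depleted"); next }
        if (g %in% rownames(detect_frac) &&
            all(detect_frac[g, ] >= min_frac))
            out[g] <- "ubiquitous"
    }
    out
}

#' Classify paralog pairs by expression-pattern conservation
#'
#' Pairs where either gene is uninformative ("none") are excluded from the
#' rate, as are pairs where both genes are ubiquitous; pairs of one
#' ubiquitous gene and one informative gene are kept only when the
#' informative gene is specific to or depleted from the major clusters (the
#' first two cluster labels).  Remaining pairs are conserved when both
#' genes carry the same pattern and diverged otherwise; the
#' neofunctionalization percentage is diverged / (diverged + conserved) x
#' 100, overall and per duplication-age class.
#'
#' @param table data.frame with \code{gene_a}, \code{gene_b}, \code{taxon}.
#' @param patterns named character vector of pattern labels per gene
#'   ([assignExpressionPattern()] or planted truth).
#' @param major_clusters cluster names counted as "major" for the
#'   ubiquitous+other rule (default the first two found in the patterns).
#' @return list: \code{pairs} (per-pair data.frame with \code{status}),
#'   \code{summary} (per age class: n_diverged, n_conserved,
#'   neofunctionalization_pct), \code{excluded} counts.
#' @export
classifyPairs <- function(table, patterns, major_clusters = c("C1", "C2")) {
    age <- classifyDuplicationAge(table$taxon)
    pa <- unname(patterns[table$gene_a])
    pb <- unname(patterns[table$gene_b])
    if (anyNA(pa) || anyNA(pb))
        stop("patterns missing for some pair genes")

    majorInformative <- function(p)
        p %in% c(paste0(major_clusters, "-specific"),
                 paste0(major_clusters, "-depleted"))
    status <- character(nrow(table))
    for (i in seq_len(nrow(table))) {
        a <- pa[i]; b <- pb[i]
        if (a == "none" || b == "none") {
            status[i] <- "excluded_none"
        } else if (a == "ubiquitous" && b == "ubiquitous") {
            status[i] <- "excluded_both_ubiquitous"
        } else if (a == "ubiquitous" || b == "ubiquitous") {
            other <- if (a == "ubiquitous") b else a
            status[i] <- if (majorInformative(other)) "diverged"
                         else "excluded_ubiquitous_minor"
        } else {
            status[i] <- if (a == b) "conserved" else "diverged"
        }
    }

    pairs <- data.frame(table[, c("gene_a", "gene_b", "taxon")],
                        age = age, pattern_a = pa, pattern_b = pb,
                        status = status, row.names = NULL)
    summarize <- function(sel) {
        d <- sum(status[sel] == "diverged")
        c_ <- sum(status[sel] == "conserved")
        c(n_diverged = d, n_conserved = c_,
          neofunctionalization_pct =
              if (d + c_ > 0) 100 * d / (d + c_) else NA_real_)
    }
    summary <- rbind(all = summarize(rep(TRUE, nrow(table))),
                     recent = summarize(age == "recent"),
                     early = summarize(age == "early"))
    excluded <- table(status[!status %in% c("conserved", "diverged")])
    list(pairs = pairs, summary = as.data.frame(summary),
         excluded = excluded)
}
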