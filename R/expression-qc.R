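#' Log-transform a TPM matrix to E units
#'
#' Expression is quantified as E = log2(TPM + 1).  The unit tag guards
#' against double transformation.
#'
#' @param m an [ExpressionMatrix-class] in TPM units.
#' @return An [ExpressionMatrix-class] in E units.
#' @examples
#' m <- ExpressionMatrix(matrix(c(0, 1, 7, 3), 2, 2,
#'      dimnames = list(c("g1","g2"), c("c1","c2"))))
#' exprValues(logTransform(m))  # log2(x + 1)
#' @export
logTransform <- function(m) {
    stopifnot(is(m, "ExpressionMatrix"))
    if (exprUnit(m) != "TPM")
        stop("input is already in E units (unit tag '", exprUnit(m), "')")
    ExpressionMatrix(log2(exprValues(m) + 1), unit = "E")
}

#' Cell quality-control filter
#'
#' Removes cells with fewer than \code{min_genes} detected genes (a gene is
#' detected when its TPM is strictly greater than zero) or fewer than
#' \code{min_reads} reads mapped to transcripts.  Boundaries are strict
#' "fewer than": a cell at exactly 500 genes and 10,000 reads is retained.
#'
#' @param m an [ExpressionMatrix-class] in TPM units.
#' @param reads_per_cell named numeric vector of transcript-mapped reads,
#'   names matching the matrix cell ids (order-free).
#' @param min_genes,min_reads exclusion thresholds.
#' @return list with \code{matrix} (the filtered [ExpressionMatrix-class])
#'   and \code{report}: per-cell data.frame (\code{cell},
#'   \code{detected_genes}, \code{mapped_reads}, \code{pass},
#'   \code{failure_reasons}) plus aggregate counts \code{n_input},
#'   \code{n_removed}, \code{n_retained}, \code{mean_detected_genes}.
#' @export
qcFilter <- function(m, reads_per_cell, min_genes = 500, min_reads = 10000) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "TPM")
    v <- exprValues(m)
    cells <- colnames(v)
    if (is.null(names(reads_per_cell)) ||
        !setequal(names(reads_per_cell), cells))
        stop("reads_per_cell names must match the matrix cell ids")
    reads <- reads_per_cell[cells]

    detected <- colSums(v > 0)
    few_genes <- detected < min_genes
    few_reads <- reads < min_reads
    pass <- !few_genes & !few_reads
    reasons <- mapply(function(g, r) {
        paste(c(if (g) sprintf("detected genes < %d", min_genes),
                if (r) sprintf("mapped reads < %d", min_reads)),
              collapse = "; ")
    }, few_genes, few_reads)

    per_cell <- data.frame(cell = cells,
                           detected_genes = as.integer(detected),
                           mapped_reads = as.numeric(reads),
                           pass = pass,
                           failure_reasons = reasons,
                           row.names = NULL)
    report <- list(per_cell = per_cell,
                   n_input = length(cells),
                   n_removed = sum(!pass),
                   n_retained = sum(pass),
                   mean_detected_genes = mean(detected[pass]))
    list(matrix = ExpressionMatrix(v[, pass, drop = FALSE], unit = "TPM"),
         report = report)
}

#' Correlation of the average single-cell profile with a bulk profile
#'
#' Averages the per-cell E-unit profiles and computes the Pearson
#' correlation with an independent bulk profile over the shared genes.
#'
#' @param m an [ExpressionMatrix-class] in E units.
#' @param bulk named numeric vector of bulk E values.
#' @return Pearson correlation coefficient (scalar).
#' @export
pseudobulkCorrelation <- function(m, bulk) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "E",
              !is.null(names(bulk)))
    shared <- intersect(rownames(exprValues(m)), names(bulk))
    if (length(shared) < 3)
        stop("fewer than 3 shared genes between matrix and bulk profile")
    prof <- rowMeans(exprValues(m)[shared, , drop = FALSE])
    b <- bulk[shared]
    if (sd(prof) == 0 || sd(b) == 0)
        stop("zero-variance profile; correlation undefined")
    unname(cor(prof, b))
}

#' Write / read a gene x cell matrix as TSV
#'
#' Plain TSV with a header row of cell ids and gene ids in the first column,
#' as produced and consumed across the pipeline.
#'
#' @param m an [ExpressionMatrix-class].
#' @param path file path.
#' @export
writeMatrixTSV <- function(m, path) {
    stopifnot(is(m, "ExpressionMatrix"))
    v <- exprValues(m)
    df <- data.frame(gene = rownames(v), v, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatrixTSV
#' @param unit unit tag to attach on read.
#' @export
readMatrixTSV <- function(path, unit = "TPM") {
    df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    v <- as.matrix(df[, -1, drop = FALSE])
    rownames(v) <- df[[1]]
    ExpressionMatrix(v, unit = unit)
}

#' Write a matrix in MatrixMarket triplet format
#'
#' @param m an [ExpressionMatrix-class].
#' @param path .mtx file path; gene and cell ids are written alongside as
#'   \code{<path>.genes} and \code{<path>.cells}.
#' @export
writeMatrixMTX <- function(m, path) {
    v <- exprValues(m)
    nz <- which(v != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 paste(nrow(v), ncol(v), nrow(nz))), con)
    if (nrow(nz))
        writeLines(paste(nz[, 1], nz[, 2], v[nz]), con)
    writeLines(rownames(v), paste0(path, ".genes"))
    writeLines(colnames(v), paste0(path, ".cells"))
    invisible(path)
}

#' Write per-cell read sets as gzipped FASTQ
#'
#' One read1/read2 FASTQ pair per cell, named
#' \code{<cell>_1.fastq.gz} / \code{<cell>_2.fastq.gz}.
#'
#' @param readsets list from [generateCellReads()].
#' @param dir output directory (created if needed).
#' @export
writeReadSetsFastq <- function(readsets, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (rs in readsets) {
        for (mate in 1:2) {
            f <- gzfile(file.path(dir, sprintf("%s_%d.fastq.gz",
                                               rs$cell_id, mate)), "w")
            reads <- rs$pairs[[paste0("read", mate)]]
            if (length(reads))
                writeLines(paste0("@", rs$cell_id, ":", seq_along(reads),
                                  "/", mate, "\n", reads, "\n+\n",
                                  strrep("I", nchar(reads))), f)
            close(f)
        }
    }
    invisible(dir)
}
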