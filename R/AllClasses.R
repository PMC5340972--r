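#' @import methods
#' @importFrom Biostrings DNAStringSet reverseComplement pairwiseAlignment
#'   nmatch nmismatch pid pattern subject
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment assay assays colData rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom stats cor dist hclust cutree rnbinom rlnorm rnorm runif rbinom
#'   fisher.test wilcox.test p.adjust pnorm qnorm pt var median sd quantile
#'   setNames plogis uniroot
#' @importFrom utils head combn write.table read.table
NULL

#' Gene-by-cell expression matrix with an explicit unit tag
#'
#' A thin container around a numeric gene x cell matrix that records whether
#' the values are raw TPM (transcripts per million; columns of expressed
#' genes sum to 1e6) or E units, defined as \code{log2(TPM + 1)}.  The tag
#' prevents accidental double log-transformation and lets downstream
#' operations assert the unit they need.
#'
#' @slot values numeric matrix, genes in rows (rownames = gene ids), cells in
#'   columns (colnames = cell ids).
#' @slot unit character(1), \code{"TPM"} or \code{"E"}.
#'
#' @seealso [ExpressionMatrix()], [logTransform()]
#' @export
setClass("ExpressionMatrix",
    representation(values = "matrix", unit = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character(0)
    if (length(object@unit) != 1L || !object@unit %in% c("TPM", "E"))
        msg <- c(msg, "unit must be one of 'TPM', 'E'")
    v <- object@values
    if (!is.numeric(v))
        msg <- c(msg, "values must be a numeric matrix")
    if ((nrow(v) > 0 && is.null(rownames(v))) ||
        (ncol(v) > 0 && is.null(colnames(v))))
        msg <- c(msg, "values must carry gene rownames and cell colnames")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicated gene ids")
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicated cell ids")
    if (identical(object@unit, "TPM") && is.numeric(v) && length(v) &&
        min(v) < 0)
        msg <- c(msg, "negative TPM values are not allowed")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric gene x cell matrix with dimnames.
#' @param unit \code{"TPM"} (default) or \code{"E"}.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 1, 7, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' ExpressionMatrix(m, "TPM")
#' @export
ExpressionMatrix <- function(values, unit = c("TPM", "E")) {
    unit <- match.arg(unit)
    new("ExpressionMatrix", values = as.matrix(values), unit = unit)
}

#' @describeIn ExpressionMatrix-class the underlying numeric matrix
#' @param x an ExpressionMatrix
#' @export
exprValues <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    x@values
}

#' @describeIn ExpressionMatrix-class the unit tag ("TPM" or "E")
#' @export
exprUnit <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    x@unit
}

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix [", object@unit, "]: ",
        nrow(object@values), " genes x ", ncol(object@values), " cells\n",
        sep = "")
})

#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' Germline V and J segment collection
#'
#' Holds the germline Variable and Joining segment nucleotide sequences used
#' both to simulate recombined TCR-beta transcripts and to detect them.  Each
#' V segment carries a reading-frame offset (0, 1 or 2) giving the position
#' within the segment where translation starts; the offset anchors the
#' stop-codon check on assembled contigs.
#'
#' @slot v [Biostrings::DNAStringSet] of V segments (named).
#' @slot j [Biostrings::DNAStringSet] of J segments (named).
#' @slot vFrame integer vector, per-V reading frame offset in 0:2.
#'
#' @seealso [SegmentSet()], [generateGermlineSegments()],
#'   [buildRecombinantReference()]
#' @export
setClass("SegmentSet",
    representation(v = "DNAStringSet", j = "DNAStringSet",
                   vFrame = "integer"))

setValidity("SegmentSet", function(object) {
    msg <- character(0)
    if (length(object@v) < 1L || length(object@j) < 1L)
        msg <- c(msg, "need at least one V and one J segment")
    nm <- c(names(object@v), names(object@j))
    if (is.null(names(object@v)) || is.null(names(object@j)) ||
        anyDuplicated(nm))
        msg <- c(msg, "segment names must be present and unique")
    alph <- Biostrings::uniqueLetters(c(object@v, object@j))
    if (!all(alph %in% c("A", "C", "G", "T")))
        msg <- c(msg, "segment sequences must be over {A,C,G,T}")
    if (length(object@vFrame) != length(object@v) ||
        !all(object@vFrame %in% 0:2))
        msg <- c(msg, "vFrame must give an offset in 0:2 per V segment")
    if (length(msg)) msg else TRUE
})

#' Construct a SegmentSet
#'
#' @param v,j named character vectors or DNAStringSets of V and J segments.
#' @param vFrame integer reading-frame offsets for the V segments
#'   (recycled; default 0).
#' @return A [SegmentSet-class].
#' @export
SegmentSet <- function(v, j, vFrame = 0L) {
    v <- DNAStringSet(v); j <- DNAStringSet(j)
    vFrame <- as.integer(rep_len(vFrame, length(v)))
    new("SegmentSet", v = v, j = j, vFrame = vFrame)
}

#' @describeIn SegmentSet-class the V segments as a DNAStringSet
#' @param x a SegmentSet
#' @export
vSegments <- function(x) x@v

#' @describeIn SegmentSet-class the J segments as a DNAStringSet
#' @export
jSegments <- function(x) x@j

#' @describeIn SegmentSet-class per-V reading frame offsets
#' @export
vFrames <- function(x) setNames(x@vFrame, names(x@v))

setMethod("show", "SegmentSet", function(object) {
    cat("SegmentSet: ", length(object@v), " V and ", length(object@j),
        " J germline segments\n", sep = "")
})

#' Synthetic recombinant V x J reference
#'
#' All pairwise combinations of the germline V and J segments, each padded
#' with ambiguity bases: a run of N at the 5' end standing in for the unknown
#' leader, N's between V and J for a possible D segment and non-templated
#' junction bases, and N's at the 3' end for constant-region sequence.
#'
#' @slot sequences character vector of padded recombinants, named "V|J".
#' @slot vNames,jNames character, the component segment names per entry.
#' @slot pads integer(3): 5' pad, junction pad, 3' pad lengths.
#'
#' @seealso [buildRecombinantReference()]
#' @export
setClass("RecombinantReference",
    representation(sequences = "character", vNames = "character",
                   jNames = "character", pads = "integer"))

setValidity("RecombinantReference", function(object) {
    msg <- character(0)
    n <- length(object@sequences)
    if (length(object@vNames) != n || length(object@jNames) != n)
        msg <- c(msg, "vNames/jNames must align with sequences")
    if (length(object@pads) != 3L || any(object@pads < 0L))
        msg <- c(msg, "pads must be three nonnegative integers")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RecombinantReference", function(object) {
    cat("RecombinantReference: ", length(object@sequences),
        " V x J recombinants (pads ", paste(object@pads, collapse = "/"),
        " N)\n", sep = "")
})

#' @describeIn RecombinantReference-class number of recombinant entries
#' @param x a RecombinantReference
#' @export
setMethod("length", "RecombinantReference", function(x) length(x@sequences))

#' @describeIn RecombinantReference-class the padded sequences (named "V|J")
#' @export
refSequences <- function(x) x@sequences

#' Ranked cell-type-specific gene signatures
#'
#' A named collection of per-type gene lists, each ordered by decreasing
#' fold-change and carrying the differential-expression evidence (log2
#' fold-change and multiplicity-adjusted z-score) that admitted each gene.
#' Lists are disjoint across types: genes qualifying for two or more types
#' are removed from all.
#'
#' @slot signatures named list of data.frames with columns
#'   \code{gene}, \code{log2fc}, \code{adj_z}.
#'
#' @seealso [buildSignatures()], [signatureScore()]
#' @export
setClass("SignatureSet", representation(signatures = "list"))

setValidity("SignatureSet", function(object) {
    msg <- character(0)
    if (is.null(names(object@signatures)))
        msg <- c(msg, "signatures must be a named list")
    ok <- vapply(object@signatures, function(d)
        is.data.frame(d) && all(c("gene", "log2fc", "adj_z") %in% names(d)),
        logical(1))
    if (!all(ok))
        msg <- c(msg, "each signature needs gene/log2fc/adj_z columns")
    g <- unlist(lapply(object@signatures, `[[`, "gene"))
    if (anyDuplicated(g))
        msg <- c(msg, "signature gene lists must be disjoint across types")
    if (length(msg)) msg else TRUE
})

#' Construct a SignatureSet
#' @param signatures named list of data.frames (gene, log2fc, adj_z).
#' @return A [SignatureSet-class].
#' @export
SignatureSet <- function(signatures) {
    new("SignatureSet", signatures = signatures)
}

#' @describeIn SignatureSet-class the per-type gene tables
#' @param x a SignatureSet
#' @export
signatureGenes <- function(x) x@signatures

setMethod("show", "SignatureSet", function(object) {
    cat("SignatureSet with", length(object@signatures), "cell types:\n")
    for (nm in names(object@signatures))
        cat("  ", nm, ": ", nrow(object@signatures[[nm]]), " genes\n",
            sep = "")
})

#' @describeIn SignatureSet-class number of signatures
#' @export
setMethod("length", "SignatureSet", function(x) length(x@signatures))
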