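#' Correlation dissimilarity between cells
#'
#' Cell-to-cell similarity is the Pearson correlation of full transcriptional
#' profiles; 1 - PCC is the dissimilarity handed to classical MDS.
#'
#' @param m an [ExpressionMatrix-class] in E units.
#' @return symmetric numeric matrix (zero diagonal, entries in [0, 2]) with
#'   cell ids as dimnames.
#' @export
pccDissimilarity <- function(m) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "E")
    v <- exprValues(m)
    if (ncol(v) < 2) stop("need at least 2 cells")
    sds <- apply(v, 2, sd)
    if (any(sds == 0))
        stop("constant expression profile for cell(s): ",
             paste(colnames(v)[sds == 0], collapse = ", "))
    d <- 1 - cor(v)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    d
}

#' Classical multidimensional scaling (principal coordinates analysis)
#'
#' Torgerson's method: the dissimilarity matrix is squared and double
#' centered, B = -1/2 J D^2 J, and the leading eigenvectors of B scaled by
#' the square roots of their (nonnegative) eigenvalues give the coordinates.
#' Axes with negative eigenvalues are returned as zero columns, so the
#' embedding always has exactly \code{k} columns.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param k number of coordinates, 1 <= k < nrow(d).
#' @return list with \code{points} (n x k coordinate matrix, centered
#'   columns) and \code{eigenvalues} (all n, descending).
#' @export
classicalMDS <- function(d, k) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (k < 1 || k >= n) stop("need 1 <= k < number of points")
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (d^2) %*% J
    B <- (B + t(B)) / 2
    eig <- eigen(B, symmetric = TRUE)
    pts <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
    for (i in seq_len(k)) {
        if (eig$values[i] > 0)
            pts[, i] <- eig$vectors[, i] * sqrt(eig$values[i])
    }
    list(points = pts, eigenvalues = eig$values)
}

#' Empirical-Bayes location-scale batch adjustment
#'
#' Parametric empirical-Bayes adjustment of per-gene batch effects on
#' log-scale expression.  Per gene and batch, a location (additive) and
#' scale (multiplicative) effect are estimated on standardized data, shrunk
#' toward common priors (normal location, inverse-gamma scale, hyperpriors
#' by method of moments), and removed.  Genes with zero variance across all
#' cells pass through unchanged; genes whose within-batch residual variance
#' is zero receive an exact location-only adjustment.
#'
#' @param m an [ExpressionMatrix-class] in E units.
#' @param batch factor or vector of batch labels, one per cell.
#' @param clamp_negative set negative adjusted values to zero (as needed by
#'   downstream methods requiring nonnegative input).  Default FALSE.
#' @param allow_single_batch with a single batch, return the input unchanged
#'   instead of erroring.
#' @param tol convergence tolerance of the EB iteration.
#' @return An [ExpressionMatrix-class] in E units.
#' @export
ebBatchAdjust <- function(m, batch, clamp_negative = FALSE,
                          allow_single_batch = FALSE, tol = 1e-8) {
    stopifnot(is(m, "ExpressionMatrix"), exprUnit(m) == "E")
    v <- exprValues(m)
    batch <- as.factor(batch)
    if (length(batch) != ncol(v))
        stop("batch must have one label per cell")
    nb <- table(batch)
    if (nlevels(batch) < 2) {
        if (allow_single_batch) return(m)
        stop("need at least 2 batches (or allow_single_batch = TRUE)")
    }
    if (any(nb < 2))
        stop("each batch needs at least 2 cells; offending: ",
             paste(names(nb)[nb < 2], collapse = ", "))

    N <- ncol(v)
    levs <- levels(batch)
    batch_means <- vapply(levs, function(b)
        rowMeans(v[, batch == b, drop = FALSE]), numeric(nrow(v)))
    grand <- as.vector(batch_means %*% (as.numeric(nb[levs]) / N))
    resid <- v - batch_means[, as.integer(batch)]
    var_pooled <- rowSums(resid^2) / N
    total_var <- apply(v, 1, var)

    out <- v
    est <- total_var > 1e-12          # anything to adjust at all
    loc_only <- est & var_pooled <= 1e-12
    eb <- est & var_pooled > 1e-12

    # degenerate genes: batch effect exactly identified, subtract batch means
    if (any(loc_only)) {
        shift <- batch_means[loc_only, , drop = FALSE] - grand[loc_only]
        out[loc_only, ] <- v[loc_only, , drop = FALSE] -
            shift[, as.integer(batch), drop = FALSE]
    }

    if (any(eb)) {
        sdp <- sqrt(var_pooled[eb])
        Z <- (v[eb, , drop = FALSE] - grand[eb]) / sdp
        adjZ <- Z
        for (b in levs) {
            sel <- batch == b
            n_b <- sum(sel)
            Zb <- Z[, sel, drop = FALSE]
            g_hat <- rowMeans(Zb)
            d_hat <- rowSums((Zb - g_hat)^2) / (n_b - 1)

            g_bar <- mean(g_hat); t2 <- var(g_hat)
            m_d <- mean(d_hat); s2_d <- var(d_hat)
            # inverse-gamma hyperpriors by method of moments
            a_pr <- (2 * s2_d + m_d^2) / s2_d
            b_pr <- (m_d * s2_d + m_d^3) / s2_d

            g_star <- g_hat; d_star <- d_hat
            for (it in 1:200) {
                g_new <- (n_b * t2 * g_hat + d_star * g_bar) /
                         (n_b * t2 + d_star)
                sum2 <- rowSums((Zb - g_new)^2)
                d_new <- (b_pr + 0.5 * sum2) / (n_b / 2 + a_pr - 1)
                if (max(abs(g_new - g_star), abs(d_new - d_star)) < tol) {
                    g_star <- g_new; d_star <- d_new; break
                }
                g_star <- g_new; d_star <- d_new
            }
            adjZ[, sel] <- (Zb - g_star) / sqrt(d_star)
        }
        out[eb, ] <- adjZ * sdp + grand[eb]
    }

    if (clamp_negative) out[out < 0] <- 0
    ExpressionMatrix(out, unit = "E")
}

#' Mean silhouette coefficient
#'
#' @param labels integer cluster labels.
#' @param d a dist object or distance matrix over the same points.
#' @return mean silhouette width over all points.
#' @export
meanSilhouette <- function(labels, d) {
    sil <- cluster::silhouette(as.integer(labels), dist = as.dist(d))
    mean(sil[, "sil_width"])
}

#' Ward clustering on leading principal coordinates
#'
#' Agglomerative hierarchical clustering with Ward's criterion (Ward.D2, on
#' Euclidean distances) applied to the first \code{n_coords} coordinates of
#' an embedding.  For each candidate number of clusters the dendrogram is
#' cut and the mean silhouette coefficient computed in the same coordinate
#' space; the returned labels are at the silhouette-maximizing k (ties go to
#' the smallest k).
#'
#' @param embedding a list from [classicalMDS()] or a coordinate matrix.
#' @param n_coords number of leading coordinates to cluster on.
#' @param k_candidates candidate cluster numbers.
#' @return list: \code{labels} (integer per cell), \code{k},
#'   \code{silhouette} (named mean silhouette per candidate k),
#'   \code{hclust} (the linkage object).
#' @export
wardCluster <- function(embedding, n_coords = 4, k_candidates = 2:8) {
    X <- if (is.list(embedding)) embedding$points else embedding
    if (n_coords > ncol(X))
        stop("n_coords exceeds the embedding dimension")
    X <- X[, seq_len(n_coords), drop = FALSE]
    n <- nrow(X)
    keep <- k_candidates[k_candidates >= 2 & k_candidates <= n - 1]
    if (length(keep) < length(k_candidates))
        warning("candidate k range truncated to 2..", n - 1)
    if (!length(keep)) stop("no valid candidate k")
    dd <- dist(X)
    hc <- hclust(dd, method = "ward.D2")
    sil <- vapply(keep, function(k)
        meanSilhouette(cutree(hc, k), dd), numeric(1))
    names(sil) <- keep
    best <- keep[which.max(sil)]   # which.max takes the first (smallest k)
    list(labels = unname(cutree(hc, best)), k = best,
         silhouette = sil, hclust = hc)
}
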