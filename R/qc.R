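#' @importFrom stats hclust as.dist kmeans
NULL

#' Replicate clustering by pairwise correlation
#'
#' Computes the pairwise Pearson (or Spearman) correlation of per-fragment
#' occupancy across samples and clusters samples by average-linkage
#' hierarchical clustering on the distance `1 - r`.
#'
#' @param track An [OccupancyTrack-class] with at least 2 samples, or a
#'   numeric matrix (fragments x samples).
#' @param method `"pearson"` (default; the log-ratio scale is already
#'   variance-stabilized) or `"spearman"`.
#' @return A list with `correlation` (symmetric matrix) and `dendrogram`
#'   (an `hclust` object with deterministic leaf order).
#' @export
sampleCorrelationCluster <- function(track, method = c("pearson",
                                                       "spearman")) {
    method <- match.arg(method)
    m <- if (is(track, "OccupancyTrack")) assay(track, "occupancy")
         else as.matrix(track)
    if (ncol(m) < 2) stop("at least 2 samples are required")
    v <- apply(m, 2, var)
    if (any(v < 1e-24))
        stop("degenerate sample(s) with zero variance: ",
             paste(colnames(m)[v < 1e-24], collapse = ", "))
    r <- cor(m, method = method)
    hc <- hclust(as.dist(1 - r), method = "average")
    list(correlation = r, dendrogram = hc)
}

# k-means++ seeding: spread initial centers by squared-distance sampling
.kmeansPP <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in seq_len(k - 1) + 1) {
        pick <- if (all(d2 == 0)) sample.int(n, 1)
                else sample.int(n, 1, prob = d2)
        centers[j, ] <- x[pick, ]
        d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                           byrow = TRUE))^2))
    }
    centers
}

#' Cluster genes by per-condition occupancy profile
#'
#' k-means on the per-condition mean occupancy columns with k-means++
#' seeding and multiple restarts; the minimum-inertia solution is kept.
#' Labels are relabeled canonically by descending cluster mean occupancy,
#' so cluster 1 is always the highest-occupancy cluster.
#'
#' @param table A [GeneOccupancyTable-class] (its `mean_*` columns are the
#'   features) or a numeric feature matrix.
#' @param k number of clusters (default 3).
#' @param seed RNG seed.
#' @param nRestarts independent k-means++ restarts (default 50).
#' @return A list with `cluster` (named integer vector), `centers`, and
#'   `inertia` (total within-cluster sum of squares).
#' @export
geneKmeans <- function(table, k = 3L, seed = 1L, nRestarts = 50L) {
    if (is(table, "GeneOccupancyTable")) {
        cols <- grep("^mean_", colnames(table), value = TRUE)
        x <- as.matrix(as.data.frame(table[, cols, drop = FALSE]))
        rownames(x) <- table$gene_id
    } else x <- as.matrix(table)
    x <- x[stats::complete.cases(x), , drop = FALSE]
    if (k > nrow(x)) stop("k exceeds the number of complete gene profiles")
    if (k < 1) stop("k must be >= 1")
    set.seed(as.integer(seed))
    best <- NULL
    for (r in seq_len(nRestarts)) {
        fit <- suppressWarnings(
            kmeans(x, centers = .kmeansPP(x, k), iter.max = 100))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss)
            best <- fit
    }
    # canonical labels: descending mean of the centroid coordinates
    ord <- order(rowMeans(best$centers), decreasing = TRUE)
    relabel <- match(seq_len(k), ord)
    cl <- stats::setNames(relabel[best$cluster], rownames(x))
    list(cluster = cl, centers = best$centers[ord, , drop = FALSE],
         inertia = best$tot.withinss)
}
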