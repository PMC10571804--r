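#' @importFrom stats p.adjust
NULL

#' Mean per-gene occupancy
#'
#' For every gene and fusion sample, the unweighted mean occupancy over
#' the GATC fragments that overlap the gene span by at least 1 bp. The
#' fragment is the observation unit of DamID, so fragments are not
#' length-weighted. Genes covered by no fragment get `NA`, never 0.
#'
#' @param track An [OccupancyTrack-class].
#' @param genes Gene `GRanges` (with `gene_id`).
#' @return Numeric matrix, genes x samples, rownames = `gene_id`.
#' @export
geneMeanOccupancy <- function(track, genes) {
    stopifnot(is(track, "OccupancyTrack"))
    fr <- rowRanges(track)
    if (any(end(genes) > GenomeInfoDb::seqlengths(fr)[
            as.character(seqnames(genes))], na.rm = TRUE))
        stop("annotation error: gene extends beyond chromosome bounds")
    occ <- assay(track, "occupancy")
    hits <- findOverlaps(genes, fr)
    out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(occ),
                  dimnames = list(genes$gene_id, colnames(occ)))
    if (length(hits)) {
        q <- S4Vectors::queryHits(hits)
        sums <- rowsum(occ[S4Vectors::subjectHits(hits), , drop = FALSE], q)
        n <- tabulate(q, nbins = length(genes))
        idx <- as.integer(rownames(sums))
        out[idx, ] <- sums / n[idx]
    }
    out
}

#' Count GATC sites inside gene spans
#'
#' A GATC (DpnI cut) site is a boundary between two consecutive fragments.
#' Counts the sites strictly inside each gene span; a gene lying within a
#' single fragment has 0.
#'
#' @param genes Gene `GRanges`.
#' @param fmap Sorted fragment `GRanges` tiling each chromosome.
#' @return Integer vector, one count per gene.
#' @export
countGatcSites <- function(genes, fmap) {
    fmap <- sort(fmap)
    # cut sites in 0-based coordinates: the start boundary of every
    # fragment that is not the first on its chromosome
    chr <- as.character(seqnames(fmap))
    first <- !duplicated(chr)
    sites <- split(start(fmap)[!first] - 1L, chr[!first])
    gchr <- as.character(seqnames(genes))
    n <- integer(length(genes))
    for (ch in unique(gchr)) {
        s <- sites[[ch]]
        i <- which(gchr == ch)
        if (is.null(s) || !length(s)) next
        # strict interior of 0-based [start-1, end): site b with
        # start-1 < b < end  <=>  start <= b <= end-1
        n[i] <- findInterval(end(genes)[i] - 1L, s) -
                findInterval(start(genes)[i] - 1L, s)
    }
    stats::setNames(n, genes$gene_id)
}

#' Permutation FDR for per-gene occupancy
#'
#' For each fusion sample, compares every gene's mean occupancy with the
#' mean of `nPerm` random fragment sets of the same size drawn from the
#' whole track (with replacement; set sizes are tiny relative to the
#' fragment pool). The one-sided empirical p-value is add-one smoothed,
#' `p = (1 + #{null >= observed}) / (nPerm + 1)`, then Benjamini-Hochberg
#' adjusted across genes within the sample.
#'
#' @param track An [OccupancyTrack-class].
#' @param genes Gene `GRanges`.
#' @param nPerm number of permutations, at least 100.
#' @param seed RNG seed.
#' @param adjust apply the BH step-up within each sample (default `TRUE`);
#'   `FALSE` returns the raw smoothed permutation p-values.
#' @return Numeric matrix of FDR (or raw p) values, genes x samples; `NA`
#'   for genes with no overlapping fragment.
#' @export
occupancyFdr <- function(track, genes, nPerm = 1000L, seed = 1L,
                         adjust = TRUE) {
    stopifnot(is(track, "OccupancyTrack"))
    if (nPerm < 100) stop("nPerm must be at least 100")
    set.seed(as.integer(seed))
    occ <- assay(track, "occupancy")
    obs <- geneMeanOccupancy(track, genes)
    k <- tabulate(S4Vectors::queryHits(findOverlaps(genes, rowRanges(track))),
                  nbins = length(genes))
    nf <- nrow(occ)
    fdr <- matrix(NA_real_, nrow = length(genes), ncol = ncol(occ),
                  dimnames = dimnames(obs))
    for (s in seq_len(ncol(occ))) {
        v <- occ[, s]
        p <- rep(NA_real_, length(genes))
        for (kk in sort(unique(k[k > 0]))) {
            nullMeans <- rowMeans(matrix(v[sample.int(nf, nPerm * kk,
                                                      replace = TRUE)],
                                         nrow = nPerm))
            gi <- which(k == kk)
            nullSorted <- sort(nullMeans)
            nGe <- nPerm - findInterval(obs[gi, s] - 1e-12, nullSorted)
            p[gi] <- (1 + nGe) / (nPerm + 1)
        }
        fdr[, s] <- if (adjust) p.adjust(p, method = "BH") else p
    }
    fdr
}

#' Assemble the per-gene occupancy table
#'
#' Convenience wrapper running [geneMeanOccupancy()], [countGatcSites()]
#' and [occupancyFdr()] and binding the results into a single table with
#' per-condition mean occupancy columns.
#'
#' @param track An [OccupancyTrack-class].
#' @param genes Gene `GRanges` with `gene_id` and `biotype`.
#' @param fmap Fragment `GRanges` (defaults to the track's rowRanges).
#' @param nPerm permutations for the FDR.
#' @param seed RNG seed for the permutations.
#' @return A [GeneOccupancyTable-class].
#' @export
geneOccupancy <- function(track, genes, fmap = rowRanges(track),
                          nPerm = 1000L, seed = 1L) {
    occ <- geneMeanOccupancy(track, genes)
    fdr <- occupancyFdr(track, genes, nPerm = nPerm, seed = seed)
    colnames(fdr) <- sub("^occ_", "fdr_", colnames(occ))
    cond <- colData(track)$condition
    tbl <- DataFrame(gene_id = genes$gene_id,
                     biotype = genes$biotype,
                     n_gatc_sites = countGatcSites(genes, fmap),
                     n_fragments = tabulate(
                         S4Vectors::queryHits(findOverlaps(genes,
                                                           rowRanges(track))),
                         nbins = length(genes)))
    tbl <- cbind(tbl, DataFrame(occ))
    for (cc in unique(cond))
        tbl[[paste0("mean_", cc)]] <-
            rowMeans(occ[, cond == cc, drop = FALSE])
    tbl <- cbind(tbl, DataFrame(fdr))
    metadata(tbl) <- list(conditions = unique(cond),
                          samples = colnames(occ), n_perm = nPerm)
    new("GeneOccupancyTable", tbl)
}

#' Filter Pol II-bound genes by per-sample FDR
#'
#' A gene counts as bound when its permutation FDR is below `alpha` in
#' every replicate of at least one condition group (replicate-consistent
#' reading of a per-sample screen).
#'
#' @param table A [GeneOccupancyTable-class].
#' @param alpha per-sample FDR threshold (default 0.05).
#' @return The bound subset of `table`; `metadata()` gains
#'   `n_analyzed` and `n_bound`.
#' @export
filterBoundGenes <- function(table, alpha = 0.05) {
    stopifnot(is(table, "GeneOccupancyTable"))
    fdrc <- grep("^fdr_", colnames(table), value = TRUE)
    if (!length(fdrc)) stop("no FDR columns present; run occupancyFdr first")
    cond <- sub("^fdr_(.*)_\\d+$", "\\1", fdrc)
    pass <- rep(FALSE, nrow(table))
    for (cc in unique(cond)) {
        cols <- fdrc[cond == cc]
        m <- as.matrix(as.data.frame(table[, cols, drop = FALSE]))
        ok <- rowSums(m < alpha, na.rm = FALSE) == length(cols)
        ok[is.na(ok)] <- FALSE
        pass <- pass | ok
    }
    if (!any(pass))
        warning("no genes pass the bound-gene FDR screen at alpha = ", alpha)
    out <- table[pass, ]
    md <- metadata(table)
    md$n_analyzed <- nrow(table)
    md$n_bound <- sum(pass)
    md$alpha_bound <- alpha
    metadata(out) <- md
    out
}
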