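#' Library-size normalization to reads per million
#'
#' Scales every sample to a common library size of 1e6 (reads per million),
#' the first step in filtering out non-specific Dam binding before taking
#' fusion/Dam-only ratios. Zero counts stay zero.
#'
#' @param x A [TadaCountSet-class].
#' @return `x` with an added `"rpm"` assay.
#' @examples
#' sim <- simulateTada(SimConfig(genomeLength = 1e5, nChromosomes = 1L,
#'                               nGenes = 20L, libsize = 5e4))
#' x <- normalizeLibrary(sim$counts)
#' colSums(SummarizedExperiment::assay(x, "rpm"))
#' @export
normalizeLibrary <- function(x) {
    stopifnot(is(x, "TadaCountSet"))
    cnt <- assay(x, "counts")
    tot <- colSums(cnt)
    if (any(tot == 0))
        stop("degenerate sample(s) with zero total counts: ",
             paste(colnames(cnt)[tot == 0], collapse = ", "))
    assay(x, "rpm") <- sweep(cnt, 2, tot / 1e6, "/")
    x
}

#' Per-fragment Pol II occupancy: log2(fusion / Dam-only)
#'
#' Pairs each Dam-Pol II sample with the Dam-only sample of the same
#' condition and replicate index and computes
#' `log2((fusion_rpm + pseudocount) / (dam_rpm + pseudocount))` per GATC
#' fragment. The pseudocount keeps every value finite at empty fragments.
#'
#' @param x A [TadaCountSet-class]; [normalizeLibrary()] is applied first
#'   if the `"rpm"` assay is absent.
#' @param pseudocount positive stabilizer on the RPM scale (default 0.5).
#' @return An [OccupancyTrack-class] with one column per fusion replicate.
#' @export
occupancyRatio <- function(x, pseudocount = 0.5) {
    stopifnot(is(x, "TadaCountSet"))
    if (pseudocount <= 0) stop("pseudocount must be positive")
    if (!"rpm" %in% assayNames(x)) x <- normalizeLibrary(x)
    rpm <- assay(x, "rpm")
    cd <- as.data.frame(colData(x))
    fus <- which(cd$construct == "dam_polii")
    dam <- which(cd$construct == "dam_only")
    fusKey <- paste(cd$condition[fus], cd$replicate[fus])
    damKey <- paste(cd$condition[dam], cd$replicate[dam])
    bad <- c(setdiff(fusKey, damKey), setdiff(damKey, fusKey))
    if (length(bad))
        stop("unpaired (condition, replicate) sample(s): ",
             paste(unique(bad), collapse = ", "))
    m <- match(fusKey, damKey)
    occ <- log2((rpm[, fus, drop = FALSE] + pseudocount) /
                (rpm[, dam[m], drop = FALSE] + pseudocount))
    colnames(occ) <- sprintf("occ_%s_%d", cd$condition[fus],
                             cd$replicate[fus])
    se <- SummarizedExperiment(
        assays = SimpleList(occupancy = occ),
        rowRanges = rowRanges(x),
        colData = DataFrame(condition = cd$condition[fus],
                            replicate = cd$replicate[fus],
                            fusion_sample = colnames(rpm)[fus],
                            dam_sample = colnames(rpm)[dam[m]],
                            row.names = colnames(occ)))
    new("OccupancyTrack", se)
}
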