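# Shared fixture builders. Everything is generated in code; no binary data.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
})

# small, fast world for unit tests (~1.7k fragments, 60 genes)
miniConfig <- function(seed = 1L, ...) {
    args <- list(genomeLength = 3e5, nChromosomes = 2L, nGenes = 60L,
                 geneLengthMean = 1500, libsize = 3e5, seed = seed)
    args <- utils::modifyList(args, list(...))
    do.call(SimConfig, args)
}

# fragments from 0-based cut positions on one chromosome of length L
fragmentsFromCuts <- function(L, cuts, chrom = "chr1") {
    bounds <- c(0, sort(cuts), L)
    gr <- GRanges(chrom, IRanges(start = bounds[-length(bounds)] + 1,
                                 end = bounds[-1]))
    seqlengths(gr) <- setNames(L, chrom)
    gr$fragment_id <- sprintf("frag_%06d", seq_along(gr))
    gr
}

# OccupancyTrack straight from a fragment x sample occupancy matrix
makeTrack <- function(occ, fmap,
                      condition = rep("control", ncol(occ)),
                      replicate = seq_len(ncol(occ))) {
    rownames(occ) <- NULL
    names(fmap) <- NULL
    colnames(occ) <- sprintf("occ_%s_%d", condition, replicate)
    se <- SummarizedExperiment(
        assays = SimpleList(occupancy = occ),
        rowRanges = fmap,
        colData = DataFrame(condition = condition, replicate = replicate,
                            row.names = colnames(occ)))
    new("OccupancyTrack", se)
}

# genes GRanges from 1-based starts/ends
makeGenes <- function(starts, ends, chrom = "chr1", L = NULL,
                      biotype = "protein_coding") {
    gr <- GRanges(chrom, IRanges(start = starts, end = ends))
    if (!is.null(L)) seqlengths(gr) <- setNames(rep(L, length(unique(chrom))),
                                                unique(chrom))
    gr$gene_id <- sprintf("gene_%03d", seq_along(gr))
    gr$biotype <- rep_len(biotype, length(gr))
    gr
}

# minimal 4-sample (1 replicate) count set with given column totals
makeCountSet <- function(counts, fmap = NULL) {
    nf <- nrow(counts)
    if (is.null(fmap))
        fmap <- fragmentsFromCuts(nf * 100, seq_len(nf - 1) * 100)
    des <- data.frame(
        construct = c("dam_only", "dam_polii", "dam_only", "dam_polii"),
        condition = c("control", "control", "shi", "shi"),
        replicate = 1L)
    colnames(counts) <- sprintf("%s_%s_%d", des$construct, des$condition,
                                des$replicate)
    TadaCountSet(counts, fmap, des)
}
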