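#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

.BIOTYPES <- c("protein_coding", "lncRNA", "antisense_lncRNA", "snoRNA",
               "miRNA", "snRNA", "pseudogene", "tRNA")
.CONSTRUCTS <- c("dam_only", "dam_polii")
.CONDITIONS <- c("control", "shi")

#' Simulation configuration for a synthetic TaDa experiment
#'
#' Holds every parameter of the synthetic targeted-DamID world: the reduced
#' genome, the GATC site density, the gene complement and its biotype mix,
#' the Pol II occupancy signal, the fraction and size of condition effects,
#' and the sequencing noise model.
#'
#' @slot genomeLength integer, length of each chromosome in bp.
#' @slot nChromosomes integer, number of chromosomes.
#' @slot gatcSpacingMean numeric, expected distance between consecutive GATC
#'   sites in bp (256 for a uniform 4-mer).
#' @slot nGenes integer, number of genes to place.
#' @slot geneLengthMean numeric, expected gene length in bp (log-normal).
#' @slot biotypeWeights named numeric, proportion of genes per biotype;
#'   must sum to 1.
#' @slot fracAltered numeric in [0,1], fraction of genes given a condition
#'   effect on Pol II occupancy.
#' @slot effectSize numeric, absolute occupancy shift of altered genes in
#'   log2 units.
#' @slot occupancyMean,occupancySd numeric, mean and SD (log2 units over the
#'   accessibility background) of per-gene Pol II occupancy.
#' @slot accessibilitySd numeric, log-normal sigma of per-fragment Dam-only
#'   accessibility.
#' @slot dispersion numeric, negative-binomial size parameter (inverse
#'   overdispersion; `Inf` gives Poisson counts).
#' @slot libsize numeric, expected reads per sample.
#' @slot nReplicates integer, replicates per genotype group.
#' @slot seed integer, master seed for the ordered RNG stream
#'   (map, then genes, then counts).
#' @export
setClass("SimConfig", representation(
    genomeLength    = "numeric",
    nChromosomes    = "integer",
    gatcSpacingMean = "numeric",
    nGenes          = "integer",
    geneLengthMean  = "numeric",
    biotypeWeights  = "numeric",
    fracAltered     = "numeric",
    effectSize      = "numeric",
    occupancyMean   = "numeric",
    occupancySd     = "numeric",
    accessibilitySd = "numeric",
    dispersion      = "numeric",
    libsize         = "numeric",
    nReplicates     = "integer",
    seed            = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@genomeLength < 1) msg <- c(msg, "genomeLength must be positive")
    if (object@nChromosomes < 1) msg <- c(msg, "nChromosomes must be positive")
    if (object@gatcSpacingMean <= 0)
        msg <- c(msg, "gatcSpacingMean must be positive")
    if (object@nGenes < 1) msg <- c(msg, "nGenes must be positive")
    if (object@geneLengthMean <= 0)
        msg <- c(msg, "geneLengthMean must be positive")
    if (abs(sum(object@biotypeWeights) - 1) > 1e-9)
        msg <- c(msg, "biotypeWeights must sum to 1")
    if (any(object@biotypeWeights < 0))
        msg <- c(msg, "biotypeWeights must be non-negative")
    if (is.null(names(object@biotypeWeights)) ||
        any(!nzchar(names(object@biotypeWeights))))
        msg <- c(msg, "biotypeWeights must be named by biotype")
    if (object@fracAltered < 0 || object@fracAltered > 1)
        msg <- c(msg, "fracAltered must lie in [0, 1]")
    if (object@occupancySd < 0) msg <- c(msg, "occupancySd must be >= 0")
    if (object@accessibilitySd < 0)
        msg <- c(msg, "accessibilitySd must be >= 0")
    if (object@dispersion <= 0)
        msg <- c(msg, "dispersion (NB size) must be positive")
    if (object@libsize <= 0) msg <- c(msg, "libsize must be positive")
    if (object@nReplicates < 1) msg <- c(msg, "nReplicates must be >= 1")
    if (abs(object@seed) >= 2^31 - 4)
        msg <- c(msg, "seed must fit a 32-bit integer (with room for offsets)")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe a scaled-down fly-muscle TaDa experiment: four
#' chromosome arms of 4 Mb, GATC sites every 256 bp on average, 2000 genes
#' with the biotype mix observed among Pol II-bound genes in muscle, 6% of
#' genes altered by 2 log2 units, three replicates per genotype group and
#' 2 million reads per sample.
#'
#' @param genomeLength bp per chromosome.
#' @param nChromosomes number of chromosomes.
#' @param gatcSpacingMean expected inter-GATC distance (bp).
#' @param nGenes number of genes.
#' @param geneLengthMean expected gene length (bp).
#' @param biotypeWeights named proportions per biotype (must sum to 1).
#' @param fracAltered fraction of genes with a condition effect.
#' @param effectSize absolute log2 occupancy shift of altered genes.
#' @param occupancyMean,occupancySd log2 occupancy distribution of genes.
#' @param accessibilitySd log-normal sigma of Dam-only accessibility.
#' @param dispersion negative-binomial size (inverse overdispersion;
#'   `Inf` = Poisson).
#' @param libsize expected reads per sample.
#' @param nReplicates replicates per group.
#' @param seed master RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(nGenes = 200L, genomeLength = 4e5, seed = 7L)
#' cfg
#' @export
SimConfig <- function(genomeLength = 1e7,
                      nChromosomes = 4L,
                      gatcSpacingMean = 256,
                      nGenes = 2000L,
                      geneLengthMean = 4000,
                      biotypeWeights = publishedBiotypeWeights(),
                      fracAltered = 0.06,
                      effectSize = 2,
                      occupancyMean = 5,
                      occupancySd = 1,
                      accessibilitySd = 0.5,
                      dispersion = 20,
                      libsize = 2e6,
                      nReplicates = 3L,
                      seed = 1L) {
    new("SimConfig",
        genomeLength = as.numeric(genomeLength),
        nChromosomes = as.integer(nChromosomes),
        gatcSpacingMean = as.numeric(gatcSpacingMean),
        nGenes = as.integer(nGenes),
        geneLengthMean = as.numeric(geneLengthMean),
        biotypeWeights = biotypeWeights,
        fracAltered = as.numeric(fracAltered),
        effectSize = as.numeric(effectSize),
        occupancyMean = as.numeric(occupancyMean),
        occupancySd = as.numeric(occupancySd),
        accessibilitySd = as.numeric(accessibilitySd),
        dispersion = as.numeric(dispersion),
        libsize = as.numeric(libsize),
        nReplicates = as.integer(nReplicates),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: synthetic TaDa experiment\n")
    cat(sprintf("  genome: %d chromosome(s) x %g bp; GATC every ~%g bp\n",
                object@nChromosomes, object@genomeLength,
                object@gatcSpacingMean))
    cat(sprintf("  genes: %d (mean length %g bp), %d biotypes\n",
                object@nGenes, object@geneLengthMean,
                length(object@biotypeWeights)))
    cat(sprintf("  signal: occupancy N(%g, %g) log2; %.1f%% altered by +/-%g\n",
                object@occupancyMean, object@occupancySd,
                100 * object@fracAltered, object@effectSize))
    cat(sprintf("  counts: NB size %g, libsize %g, %d replicates/group, seed %d\n",
                object@dispersion, object@libsize, object@nReplicates,
                object@seed))
})

#' Per-fragment count container for the four-genotype TaDa design
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are GATC
#' fragments (intervals between consecutive GATC sites) and whose columns
#' are samples. `colData` must describe the four-genotype design:
#' `construct` (`dam_only` or `dam_polii`), `condition` (`control` or
#' `shi`), and `replicate` (integer within group). The `"counts"` assay
#' holds raw reads; [normalizeLibrary()] adds an `"rpm"` assay.
#'
#' @seealso [TadaCountSet()], [normalizeLibrary()], [occupancyRatio()]
#' @export
setClass("TadaCountSet", contains = "RangedSummarizedExperiment")

setValidity("TadaCountSet", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- colData(object)
    need <- c("construct", "condition", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss)) {
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    } else {
        if (!all(cd$construct %in% .CONSTRUCTS))
            msg <- c(msg, "construct must be 'dam_only' or 'dam_polii'")
        if (!all(cd$condition %in% .CONDITIONS))
            msg <- c(msg, "condition must be 'control' or 'shi'")
    }
    if ("counts" %in% assayNames(object)) {
        cnt <- assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    }
    fr <- rowRanges(object)
    if (length(fr) > 1L && !S4Vectors::isSorted(fr))
        msg <- c(msg, "fragments must be sorted by (chrom, start)")
    if (length(msg)) msg else TRUE
})

#' Construct a TadaCountSet
#'
#' @param counts integer matrix, fragments x samples.
#' @param fragments `GRanges` of GATC fragments, sorted, non-overlapping,
#'   with a `fragment_id` metadata column (added if absent).
#' @param sampleData `data.frame`/`DataFrame` with columns `construct`,
#'   `condition`, `replicate`; one row per sample column.
#' @return A [TadaCountSet-class].
#' @export
TadaCountSet <- function(counts, fragments, sampleData) {
    if (is.null(fragments$fragment_id))
        fragments$fragment_id <- sprintf("frag_%06d", seq_along(fragments))
    if (is.null(rownames(counts))) rownames(counts) <- fragments$fragment_id
    se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                               rowRanges = fragments,
                               colData = DataFrame(sampleData))
    new("TadaCountSet", se)
}

setMethod("show", "TadaCountSet", function(object) {
    callNextMethod()
    cd <- colData(object)
    tab <- table(paste(cd$construct, cd$condition, sep = "/"))
    cat("design:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
        "\n")
})

#' Per-fragment Pol II occupancy tracks
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding the
#' `"occupancy"` assay: log2(Dam-fusion / Dam-only) per GATC fragment, one
#' column per fusion replicate, with `colData` columns `condition` and
#' `replicate`. Values are finite everywhere (a pseudocount guarantees
#' this).
#'
#' @seealso [occupancyRatio()]
#' @export
setClass("OccupancyTrack", contains = "RangedSummarizedExperiment")

setValidity("OccupancyTrack", function(object) {
    msg <- character()
    if (!"occupancy" %in% assayNames(object))
        msg <- c(msg, "assay 'occupancy' is required")
    else if (!all(is.finite(assay(object, "occupancy"))))
        msg <- c(msg, "occupancy values must all be finite")
    cd <- colData(object)
    miss <- setdiff(c("condition", "replicate"), colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Per-gene occupancy results
#'
#' A `DataFrame` subclass with one row per gene: `gene_id`, `biotype`,
#' `n_gatc_sites` (GATC sites strictly inside the gene span),
#' `n_fragments`, one `occ_<condition>_<rep>` column per fusion sample,
#' `mean_control` / `mean_shi` per-condition means, and one
#' `fdr_<condition>_<rep>` permutation FDR column per sample. Genes covered
#' by no fragment carry `NA` occupancy, never 0.
#'
#' @seealso [geneOccupancy()], [filterBoundGenes()], [callDifferential()]
#' @export
setClass("GeneOccupancyTable", contains = "DFrame")

setValidity("GeneOccupancyTable", function(object) {
    msg <- character()
    need <- c("gene_id", "biotype", "n_gatc_sites")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        msg <- c(msg, paste0("missing column(s): ",
                             paste(miss, collapse = ", ")))
    fdrc <- grep("^fdr_", colnames(object), value = TRUE)
    if (length(fdrc)) {
        v <- unlist(as.list(object[, fdrc, drop = FALSE]), use.names = FALSE)
        v <- v[!is.na(v)]
        if (length(v) && (min(v) < 0 || max(v) > 1))
            msg <- c(msg, "FDR values must lie in [0, 1]")
    }
    if ("n_gatc_sites" %in% colnames(object) &&
        any(object$n_gatc_sites < 0, na.rm = TRUE))
        msg <- c(msg, "n_gatc_sites must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Differential Pol II binding results
#'
#' A `DataFrame` subclass with one row per tested gene: per-condition mean
#' occupancies `x` (control) and `y` (shi), the signed orthogonal residual
#' to the principal-component regression line, its standard score `z`
#' (positive = increased Pol II binding in the inactive condition),
#' `min_fdr`, `n_gatc_sites`, the conjunctive `significant` call and its
#' `direction`. `metadata()` carries the fitted line and gate counts.
#'
#' @seealso [callDifferential()]
#' @export
setClass("DifferentialTable", contains = "DFrame")

setValidity("DifferentialTable", function(object) {
    msg <- character()
    need <- c("gene_id", "biotype", "x", "y", "residual", "z",
              "n_gatc_sites", "min_fdr", "significant", "direction")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        msg <- c(msg, paste0("missing column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        bad <- object$significant & !(object$direction %in% c("up", "down"))
        if (any(bad, na.rm = TRUE))
            msg <- c(msg, "significant genes must have direction up/down")
    }
    if (length(msg)) msg else TRUE
})
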