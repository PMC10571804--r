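#' @importFrom stats rexp rlnorm rnorm rnbinom rpois runif
NULL

# Ordered sub-seeds for the three simulation stages so partial reruns
# (e.g. regenerating counts on a fixed map) stay reproducible.
.seedMap    <- function(config) config@seed
.seedGenes  <- function(config) config@seed + 1L
.seedCounts <- function(config) config@seed + 2L

#' Simulate a GATC fragment map
#'
#' Models DpnI digestion of a genome: GATC sites fall with exponential
#' (memoryless) inter-site distances of the configured mean, matching the
#' expected 1/256 bp density of a uniform 4-mer. Fragments are the
#' intervals between consecutive sites and tile every chromosome without
#' gaps or overlaps.
#'
#' @param config A [SimConfig-class].
#' @return A sorted `GRanges` of fragments with metadata column
#'   `fragment_id`.
#' @examples
#' fmap <- simulateFragmentMap(SimConfig(genomeLength = 1e5,
#'                                       nChromosomes = 1L))
#' head(fmap)
#' @export
simulateFragmentMap <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (config@genomeLength < 1)
        stop("invalid config: zero-length chromosome")
    set.seed(.seedMap(config))
    L <- config@genomeLength
    chroms <- sprintf("chr%d", seq_len(config@nChromosomes))
    grl <- lapply(chroms, function(ch) {
        # over-draw exponential gaps, then trim to the chromosome
        nDraw <- ceiling(L / config@gatcSpacingMean * 1.25) + 50L
        cuts <- cumsum(rexp(nDraw, rate = 1 / config@gatcSpacingMean))
        while (cuts[length(cuts)] < L)
            cuts <- c(cuts, cuts[length(cuts)] +
                          cumsum(rexp(nDraw, 1 / config@gatcSpacingMean)))
        cuts <- unique(floor(cuts[cuts < L]))
        cuts <- cuts[cuts >= 1]
        bounds <- c(0, cuts, L)                 # 0-based cut positions
        GRanges(ch, IRanges(start = bounds[-length(bounds)] + 1,
                            end = bounds[-1]))
    })
    gr <- suppressWarnings(do.call(c, grl))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(rep(L, length(chroms)),
                                                    chroms)
    gr$fragment_id <- sprintf("frag_%06d", seq_along(gr))
    gr
}

#' Simulate a gene annotation and its ground truth
#'
#' Places non-overlapping genes (log-normal lengths) across the
#' chromosomes, assigns biotypes by the configured weights, draws each
#' gene's true log2 Pol II occupancy over the accessibility background,
#' and marks a random `fracAltered` fraction as condition-altered by
#' `+/- effectSize` log2 units (direction chosen at random per gene).
#'
#' @param config A [SimConfig-class].
#' @param fmap Fragment map from [simulateFragmentMap()].
#' @return A list with `genes` (a `GRanges` with `gene_id`, `biotype`) and
#'   `truth` (a `DataFrame` with `gene_id`, `biotype`,
#'   `true_occupancy_control`, `true_delta`, `direction`).
#' @export
simulateGenes <- function(config, fmap) {
    stopifnot(is(config, "SimConfig"))
    if (length(fmap) == 0L) stop("fragment map is empty")
    set.seed(.seedGenes(config))
    chroms <- GenomeInfoDb::seqlevels(fmap)
    chrLen <- GenomeInfoDb::seqlengths(fmap)
    n <- config@nGenes
    chrLen <- stats::setNames(as.numeric(chrLen), names(chrLen))
    # allocate genes to chromosomes proportionally to length
    alloc <- floor(n * chrLen / sum(chrLen))
    rem <- n - sum(alloc)
    if (rem > 0) {
        extra <- order(n * chrLen / sum(chrLen) - alloc,
                       decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1L
    }
    sdl <- 0.5   # log-normal sdlog of gene length
    grl <- lapply(seq_along(chroms), function(i) {
        ni <- alloc[i]
        if (ni == 0L) return(GRanges())
        len <- pmax(200, round(rlnorm(ni, log(config@geneLengthMean) -
                                          sdl^2 / 2, sdl)))
        slack <- chrLen[i] - sum(len)
        if (slack < ni + 1)
            stop("gene placement error: genes do not fit on ", chroms[i],
                 " without overlap")
        gaps <- rexp(ni + 1)
        gaps <- floor(gaps / sum(gaps) * slack)
        starts <- cumsum(gaps[seq_len(ni)] + c(0, len[-ni])) + 1
        GRanges(chroms[i], IRanges(start = starts, width = len),
                strand = sample(c("+", "-"), ni, replace = TRUE))
    })
    genes <- suppressWarnings(do.call(c, grl))
    GenomeInfoDb::seqlevels(genes) <- chroms
    GenomeInfoDb::seqlengths(genes) <- chrLen
    genes$gene_id <- sprintf("gene_%05d", seq_along(genes))
    genes$biotype <- sample(names(config@biotypeWeights), length(genes),
                            replace = TRUE, prob = config@biotypeWeights)
    if (!all(overlapsAny(genes, fmap)))
        stop("gene placement error: a gene overlaps no fragment")

    occ <- rnorm(length(genes), config@occupancyMean, config@occupancySd)
    nAlt <- round(config@fracAltered * length(genes))
    delta <- numeric(length(genes))
    direction <- rep("none", length(genes))
    if (nAlt > 0) {
        idx <- sample(length(genes), nAlt)
        sgn <- sample(c(1, -1), nAlt, replace = TRUE)
        delta[idx] <- sgn * config@effectSize
        direction[idx] <- ifelse(sgn > 0, "up", "down")
    }
    truth <- DataFrame(gene_id = genes$gene_id,
                       biotype = genes$biotype,
                       true_occupancy_control = occ,
                       true_delta = delta,
                       direction = direction)
    list(genes = genes, truth = truth)
}

# expected count matrix columns for the four-genotype design
.designFrame <- function(nReplicates) {
    expand.grid(replicate = seq_len(nReplicates),
                condition = .CONDITIONS,
                construct = .CONSTRUCTS,
                stringsAsFactors = FALSE)[, c("construct", "condition",
                                              "replicate")]
}

#' Simulate fragment counts for all four genotypes
#'
#' Dam-only samples measure chromatin accessibility: each fragment gets a
#' log-normal accessibility weight times its length, and expected counts
#' are the library size shared out by weight. Dam-Pol II samples multiply
#' each genic fragment's weight by `2^occupancy` (plus `true_delta` in the
#' inactive condition), then renormalize so every sample has the same
#' expected library size. Counts are negative-binomial with the configured
#' size parameter (Poisson when `dispersion = Inf`); replicates are
#' independent draws.
#'
#' @param config A [SimConfig-class].
#' @param fmap Fragment map.
#' @param genes Gene `GRanges` from [simulateGenes()].
#' @param truth Truth table from [simulateGenes()].
#' @return A [TadaCountSet-class] with `2 * 2 * nReplicates` samples.
#' @export
simulateCounts <- function(config, fmap, genes, truth) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(.seedCounts(config))
    nf <- length(fmap)
    acc <- rlnorm(nf, 0, config@accessibilitySd)
    w <- acc * width(fmap)

    # fragment -> gene (max-overlap wins for straddling fragments)
    hits <- findOverlaps(fmap, genes)
    ovw <- width(IRanges::pintersect(fmap[S4Vectors::queryHits(hits)],
                                     genes[S4Vectors::subjectHits(hits)]))
    ord <- order(S4Vectors::queryHits(hits), -ovw)
    hits <- hits[ord]
    keep <- !duplicated(S4Vectors::queryHits(hits))
    fragGene <- rep(NA_integer_, nf)
    fragGene[S4Vectors::queryHits(hits)[keep]] <-
        S4Vectors::subjectHits(hits)[keep]

    occCtrl <- numeric(nf)
    occShi <- numeric(nf)
    genic <- !is.na(fragGene)
    occCtrl[genic] <- truth$true_occupancy_control[fragGene[genic]]
    occShi[genic] <- occCtrl[genic] + truth$true_delta[fragGene[genic]]

    muDam <- config@libsize * w / sum(w)
    muFus <- list(control = config@libsize * w * 2^occCtrl / sum(w * 2^occCtrl),
                  shi     = config@libsize * w * 2^occShi  / sum(w * 2^occShi))

    des <- .designFrame(config@nReplicates)
    counts <- matrix(0L, nrow = nf, ncol = nrow(des))
    for (j in seq_len(nrow(des))) {
        mu <- if (des$construct[j] == "dam_only") muDam
              else muFus[[des$condition[j]]]
        counts[, j] <- if (is.finite(config@dispersion))
            rnbinom(nf, mu = mu, size = config@dispersion)
        else rpois(nf, lambda = mu)
    }
    colnames(counts) <- sprintf("%s_%s_%d", des$construct, des$condition,
                                des$replicate)
    TadaCountSet(counts, fmap, des)
}

#' Simulate a complete TaDa experiment
#'
#' Runs the three simulation stages in their fixed RNG order
#' (fragment map, then genes, then counts).
#'
#' @param config A [SimConfig-class].
#' @return A list with `fragments`, `genes`, `truth`, and `counts`
#'   (a [TadaCountSet-class]).
#' @examples
#' sim <- simulateTada(SimConfig(genomeLength = 2e5, nChromosomes = 2L,
#'                               nGenes = 50L, libsize = 1e5))
#' sim$counts
#' @export
simulateTada <- function(config) {
    fmap <- simulateFragmentMap(config)
    gs <- simulateGenes(config, fmap)
    counts <- simulateCounts(config, fmap, gs$genes, gs$truth)
    list(fragments = fmap, genes = gs$genes, truth = gs$truth,
         counts = counts)
}
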