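#' @importFrom rtracklayer import export
NULL

# Internal coordinates follow the Bioconductor GRanges convention
# (1-based, closed). rtracklayer centralizes all conversion to and from
# the 0-based half-open BED/bedGraph convention and 1-based closed GFF3.

#' Read and write GATC fragment maps as BED
#'
#' BED files are 0-based half-open; `GRanges` in memory are 1-based
#' closed. The BED name column carries the fragment id.
#'
#' @param fmap fragment `GRanges` with `fragment_id`.
#' @param path file path.
#' @return `writeFragmentsBed` returns `path` invisibly;
#'   `readFragmentsBed` returns a sorted fragment `GRanges`.
#' @export
writeFragmentsBed <- function(fmap, path) {
    gr <- fmap
    gr$name <- gr$fragment_id
    gr$fragment_id <- NULL
    export(gr, path, format = "BED")
    invisible(path)
}

#' @rdname writeFragmentsBed
#' @export
readFragmentsBed <- function(path) {
    gr <- import(path, format = "BED")
    gr <- sort(gr)
    gr$fragment_id <- gr$name
    gr$name <- NULL
    strand(gr) <- "*"
    gr
}

#' Read and write gene annotations as GFF3
#'
#' GFF3 is 1-based closed. Genes carry `ID` and the biotype in the
#' `gene_biotype` attribute.
#'
#' @param genes gene `GRanges` with `gene_id` and `biotype`.
#' @param path file path.
#' @return `writeGenesGff3` returns `path` invisibly; `readGenesGff3`
#'   returns a gene `GRanges`.
#' @export
writeGenesGff3 <- function(genes, path) {
    gr <- genes
    gr$type <- "gene"
    gr$ID <- gr$gene_id
    gr$gene_biotype <- gr$biotype
    gr$source <- "tadaDiff"
    gr$gene_id <- NULL
    gr$biotype <- NULL
    export(gr, path, format = "GFF3")
    invisible(path)
}

#' @rdname writeGenesGff3
#' @export
readGenesGff3 <- function(path) {
    gr <- import(path, format = "GFF3")
    gr <- gr[gr$type == "gene"]
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                   strand = strand(gr))
    out$gene_id <- gr$ID
    out$biotype <- gr$gene_biotype
    GenomeInfoDb::seqlengths(out) <-
        GenomeInfoDb::seqlengths(gr)[GenomeInfoDb::seqlevels(out)]
    out
}

#' Write per-replicate occupancy tracks as bedGraph
#'
#' One bedGraph (0-based half-open) per fusion sample, named
#' `occupancy_<condition>_<replicate>.bedGraph`.
#'
#' @param track An [OccupancyTrack-class].
#' @param dir output directory (created if needed).
#' @return Invisible character vector of the written paths.
#' @export
writeOccupancyBedGraph <- function(track, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    occ <- assay(track, "occupancy")
    cd <- colData(track)
    paths <- character(ncol(occ))
    for (j in seq_len(ncol(occ))) {
        gr <- GenomicRanges::granges(rowRanges(track))
        gr$score <- occ[, j]
        paths[j] <- file.path(dir, sprintf("occupancy_%s_%d.bedGraph",
                                           cd$condition[j],
                                           cd$replicate[j]))
        export(gr, paths[j], format = "bedGraph")
    }
    invisible(paths)
}

#' Read a single bedGraph track
#'
#' @param path bedGraph file.
#' @return `GRanges` with a `score` column.
#' @export
readBedGraph <- function(path) {
    sort(import(path, format = "bedGraph"))
}

#' Read and write the fragment count matrix as TSV
#'
#' The TSV holds `fragment_id`, `chrom`, `start`, `end` (0-based
#' half-open, stated in a header comment) plus one column per sample named
#' `<construct>_<condition>_<replicate>`, from which sample metadata is
#' reparsed on reading.
#'
#' @param x A [TadaCountSet-class].
#' @param path file path.
#' @return `writeCountMatrix` returns `path` invisibly; `readCountMatrix`
#'   returns a [TadaCountSet-class].
#' @export
writeCountMatrix <- function(x, path) {
    fr <- rowRanges(x)
    df <- data.frame(fragment_id = fr$fragment_id,
                     chrom = as.character(seqnames(fr)),
                     start = start(fr) - 1L,     # BED convention
                     end = end(fr),
                     assay(x, "counts"),
                     check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("# tadaDiff count matrix; coordinates 0-based",
                     "half-open (BED); counts: raw reads per GATC fragment"),
               con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(path) {
    df <- read.delim(path, comment.char = "#", check.names = FALSE)
    need <- c("fragment_id", "chrom", "start", "end")
    if (!all(need %in% colnames(df)))
        stop("parse error in ", path, ": missing ",
             paste(setdiff(need, colnames(df)), collapse = ", "))
    sampleCols <- setdiff(colnames(df), need)
    m <- regmatches(sampleCols,
                    regexec("^(dam_only|dam_polii)_(control|shi)_(\\d+)$",
                            sampleCols))
    bad <- sampleCols[lengths(m) == 0]
    if (length(bad))
        stop("parse error in ", path, ": unrecognized sample column(s): ",
             paste(bad, collapse = ", "))
    des <- data.frame(construct = vapply(m, `[`, "", 2),
                      condition = vapply(m, `[`, "", 3),
                      replicate = as.integer(vapply(m, `[`, "", 4)))
    gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end))
    gr$fragment_id <- df$fragment_id
    o <- order(gr)
    cnt <- as.matrix(df[, sampleCols, drop = FALSE])[o, , drop = FALSE]
    TadaCountSet(cnt, gr[o], des)
}

#' Write a results table as TSV
#'
#' @param x a `data.frame` or `DataFrame`.
#' @param path file path.
#' @param comment optional header comment naming units/conventions.
#' @return `path`, invisibly.
#' @export
writeResultTsv <- function(x, path, comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste("#", comment), con)
    write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
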