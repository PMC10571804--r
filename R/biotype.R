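#' @importFrom utils read.delim write.table
NULL

#' Published biotype counts of Pol II-bound and inactivity-altered genes
#'
#' Loads the packaged per-biotype counts of genes bound by Pol II in
#' larval muscle (2010 analyzed) and of the subset altered by muscle
#' inactivation (121), as reported for the muscle TaDa experiment.
#'
#' @return A `data.frame` with `biotype`, `analyzed_n`, `altered_n`.
#' @examples
#' publishedBiotypeCounts()
#' @export
publishedBiotypeCounts <- function() {
    read.delim(system.file("extdata", "polii_biotype_counts.tsv",
                           package = "tadaDiff"),
               stringsAsFactors = FALSE)
}

#' Biotype proportions among Pol II-bound genes
#'
#' The analyzed-gene biotype mix from [publishedBiotypeCounts()], normalized to sum
#' to 1; the default `biotypeWeights` of [SimConfig()].
#'
#' @return Named numeric vector of proportions.
#' @export
publishedBiotypeWeights <- function() {
    tc <- publishedBiotypeCounts()
    stats::setNames(tc$analyzed_n / sum(tc$analyzed_n), tc$biotype)
}

#' Expand published biotype counts into per-gene sets
#'
#' Builds synthetic per-gene tables (placeholder gene ids, real biotype
#' composition) from the packaged counts, for exercising
#' [biotypeTable()] on the published composition.
#'
#' @param counts a counts `data.frame` as returned by [publishedBiotypeCounts()].
#' @return A list with `analyzed` and `altered` data.frames
#'   (`gene_id`, `biotype`), the altered set a subset of the analyzed set.
#' @export
publishedGeneSets <- function(counts = publishedBiotypeCounts()) {
    analyzed <- data.frame(
        gene_id = sprintf("g%04d", seq_len(sum(counts$analyzed_n))),
        biotype = rep(counts$biotype, counts$analyzed_n),
        stringsAsFactors = FALSE)
    altIdx <- unlist(mapply(function(bt, n) {
        which(analyzed$biotype == bt)[seq_len(n)]
    }, counts$biotype, counts$altered_n, SIMPLIFY = FALSE))
    list(analyzed = analyzed, altered = analyzed[sort(altIdx), ])
}

.biotypeVocab <- function() c(.BIOTYPES, "other")

.canonBiotype <- function(b) {
    b <- as.character(b)
    ifelse(b %in% .BIOTYPES, b, "other")
}

#' Biotype composition of analyzed versus altered genes
#'
#' Tabulates counts and percentages (one decimal) per biotype within the
#' analyzed gene set and within the altered subset, over a fixed
#' eight-biotype vocabulary plus an "other" catch-all, with a totals row.
#'
#' @param analyzed data.frame with `gene_id` and `biotype` for every
#'   analyzed gene.
#' @param altered data.frame for the altered subset; must be contained in
#'   `analyzed` by `gene_id`.
#' @return A `data.frame` with columns `biotype`, `analyzed_n`,
#'   `analyzed_pct`, `altered_n`, `altered_pct`; last row `Total`.
#' @examples
#' sets <- publishedGeneSets()
#' biotypeTable(sets$analyzed, sets$altered)
#' @export
biotypeTable <- function(analyzed, altered) {
    if (!all(altered$gene_id %in% analyzed$gene_id))
        stop("consistency error: altered gene(s) absent from analyzed set: ",
             paste(utils::head(setdiff(altered$gene_id, analyzed$gene_id), 5),
                   collapse = ", "))
    vocab <- .biotypeVocab()
    na <- base::table(factor(.canonBiotype(analyzed$biotype), vocab))
    nt <- base::table(factor(.canonBiotype(altered$biotype), vocab))
    pct <- function(n, tot) if (tot == 0) rep(0, length(n))
                            else round(100 * n / tot, 1)
    out <- data.frame(biotype = vocab,
                      analyzed_n = as.integer(na),
                      analyzed_pct = pct(as.integer(na), sum(na)),
                      altered_n = as.integer(nt),
                      altered_pct = pct(as.integer(nt), sum(nt)),
                      stringsAsFactors = FALSE)
    out <- out[out$analyzed_n > 0 | out$altered_n > 0 |
               out$biotype != "other", ]
    rbind(out, data.frame(biotype = "Total",
                          analyzed_n = sum(na),
                          analyzed_pct = if (sum(na)) 100 else 0,
                          altered_n = sum(nt),
                          altered_pct = if (sum(nt)) 100 else 0))
}

#' Biotype enrichment fold among altered genes
#'
#' The percentage of a biotype among altered genes divided by its
#' percentage among analyzed genes. A fold of 3 for lncRNAs means lncRNAs
#' are three times more prevalent among inactivity-altered genes than
#' among all Pol II-bound genes.
#'
#' @param biotype biotype label to test.
#' @param analyzed,altered per-gene data.frames as in [biotypeTable()].
#' @return A list with `fold` (raw ratio) and `rounded`.
#' @examples
#' sets <- publishedGeneSets()
#' enrichmentFold("lncRNA", sets$analyzed, sets$altered)
#' @export
enrichmentFold <- function(biotype, analyzed, altered) {
    pAna <- mean(.canonBiotype(analyzed$biotype) == biotype)
    if (pAna == 0) stop("biotype '", biotype, "' absent from analyzed set")
    if (nrow(altered) == 0 ||
        !any(.canonBiotype(altered$biotype) == biotype)) {
        warning("biotype '", biotype, "' absent from altered set; fold 0")
        return(list(fold = 0, rounded = 0))
    }
    pAlt <- mean(.canonBiotype(altered$biotype) == biotype)
    fold <- pAlt / pAna
    list(fold = fold, rounded = round(fold))
}
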