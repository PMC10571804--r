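#' Length-adjusted larval motion range
#'
#' Summarizes a crawl recording as `(Lmax - Lmin) / Lmax`, where the L's
#' are the larval body lengths measured per frame: the maximal relative
#' body-length change during crawling. A fully immobile larva scores 0; a
#' larva contracting to half its length scores 0.5.
#'
#' @param lengths numeric vector of per-frame body lengths (mm), at least
#'   2 frames, all positive.
#' @return Dimensionless ratio in [0, 1).
#' @examples
#' motionRange(c(4.0, 5.0))   # 0.2
#' @export
motionRange <- function(lengths) {
    if (length(lengths) < 2)
        stop("at least 2 frames are required")
    if (any(!is.finite(lengths)) || any(lengths <= 0))
        stop("all lengths must be positive and finite")
    (max(lengths) - min(lengths)) / max(lengths)
}

#' Per-nucleus acetylation/methylation ratio
#'
#' Ratio of total H3K9ac (activating) to total H3K27me3 (repressive)
#' fluorescence per muscle nucleus; a higher ratio indicates a shift
#' towards open, transcription-permissive chromatin. Raw channel totals
#' are used by default; volume normalization divides both channels by the
#' nuclear volume (and thus cancels, kept as an explicit option for
#' per-volume reporting).
#'
#' @param nuclei data.frame with columns `nucleus_id`, `h3k9ac`,
#'   `h3k27me3`, and (if `volumeNormalized`) `volume`.
#' @param volumeNormalized divide both channels by `volume` first.
#' @return Named numeric vector of ratios, one per nucleus.
#' @export
aceMeRatio <- function(nuclei, volumeNormalized = FALSE) {
    need <- c("nucleus_id", "h3k9ac", "h3k27me3")
    if (volumeNormalized) need <- c(need, "volume")
    miss <- setdiff(need, colnames(nuclei))
    if (length(miss))
        stop("missing column(s): ", paste(miss, collapse = ", "))
    ac <- nuclei$h3k9ac
    me <- nuclei$h3k27me3
    if (volumeNormalized) {
        if (any(nuclei$volume <= 0)) stop("volumes must be positive")
        ac <- ac / nuclei$volume
        me <- me / nuclei$volume
    }
    if (any(me <= 0))
        stop("undefined ratio: zero methylation signal in nucleus ",
             paste(nuclei$nucleus_id[me <= 0], collapse = ", "))
    stats::setNames(ac / me, nuclei$nucleus_id)
}

#' Descriptive summary per experimental group
#'
#' Mean, sample SD (n - 1) and n of a per-unit metric within each group
#' (typically genotype x temperature); no pooling across groups. Groups
#' with a single unit report `NA` SD.
#'
#' @param values numeric metric per unit (larva or nucleus).
#' @param groups grouping factor/character aligned with `values`.
#' @return data.frame with `group`, `n`, `mean`, `sd`.
#' @examples
#' groupSummary(c(0.1, 0.2, 0.3), rep("shi_18", 3))
#' @export
groupSummary <- function(values, groups) {
    stopifnot(length(values) == length(groups))
    ok <- !is.na(groups)
    if (any(!ok)) {
        warning("dropping ", sum(!ok), " unit(s) with missing group")
        values <- values[ok]; groups <- groups[ok]
    }
    gl <- unique(as.character(groups))
    out <- do.call(rbind, lapply(gl, function(g) {
        v <- values[groups == g]
        data.frame(group = g, n = length(v), mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else NA_real_)
    }))
    rownames(out) <- NULL
    out
}
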