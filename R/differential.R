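#' Orthogonal regression by principal component analysis
#'
#' Fits the line through the centroid of the (x, y) scatter along the
#' first principal eigenvector of its 2x2 covariance — the direction that
#' minimizes the summed squared perpendicular distances. The direction is
#' oriented with a positive x component.
#'
#' @param x,y numeric vectors: per-gene mean occupancy in the two
#'   conditions (x = control, y = inactive).
#' @return A list with `centroid` (length-2), `direction` (unit length-2),
#'   and, when the line is not vertical, `slope` and `intercept`.
#' @examples
#' fit <- pcaRegression(x = c(0, 1, 2), y = c(1, 3, 5))
#' fit$slope; fit$intercept
#' @export
pcaRegression <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("at least 3 finite points are required")
    ctr <- c(mean(x), mean(y))
    cv <- stats::cov(cbind(x, y))
    eg <- eigen(cv, symmetric = TRUE)
    if ((eg$values[1] - eg$values[2]) <= 1e-12 * max(eg$values[1], 1e-300))
        stop("degenerate geometry: isotropic scatter (equal eigenvalues); ",
             "inspect the occupancy scatter before regressing")
    d <- eg$vectors[, 1]
    if (d[1] < 0) d <- -d
    out <- list(centroid = ctr, direction = d)
    if (abs(d[1]) > 1e-12) {
        out$slope <- d[2] / d[1]
        out$intercept <- ctr[2] - out$slope * ctr[1]
    }
    out
}

#' Residual z-scores around the orthogonal regression line
#'
#' The residual is the signed perpendicular distance of each point to the
#' line, positive when y lies above it (higher occupancy in the inactive
#' condition). z is the residual divided by the sample SD (n - 1) of the
#' residuals; the residual mean is 0 by the centroid construction.
#'
#' @param x,y numeric vectors of per-gene occupancies.
#' @param line fit from [pcaRegression()].
#' @return A list with `residual` and `z`, each aligned with `x`.
#' @export
residualZscores <- function(x, y, line) {
    d <- line$direction
    nrm <- c(-d[2], d[1])        # unit normal pointing to y-above-line
    if (nrm[2] < 0) nrm <- -nrm
    r <- (x - line$centroid[1]) * nrm[1] + (y - line$centroid[2]) * nrm[2]
    s <- sd(r[is.finite(r)])
    if (!is.finite(s) || s < 1e-12)
        stop("degenerate scatter: residual SD is zero (collinear input)")
    list(residual = r, z = r / s)
}

#' Call genes with significantly altered Pol II binding
#'
#' The bespoke differential caller: per-condition mean occupancies give
#' one (control, inactive) point per gene; an orthogonal (PCA) regression
#' line is fitted through the scatter; each gene's signed perpendicular
#' residual is standardized to a z-score. A gene is significant when all
#' three gates pass: smallest per-sample occupancy FDR `< fdrCut`,
#' `|z| > zCut` (two-tailed), and more than `gatcCut` GATC sites in its
#' span. Positive z means increased Pol II binding in the inactive
#' condition.
#'
#' @param table A [GeneOccupancyTable-class], normally the bound subset
#'   from [filterBoundGenes()] — the regression is meant to run on bound
#'   genes only.
#' @param fdrCut FDR gate (default 0.01).
#' @param zCut two-tailed z gate (default 1.96).
#' @param gatcCut strict GATC-site gate: requires `n_gatc_sites > gatcCut`
#'   (default 1).
#' @param fdrFrom `"occupancy"` (default) gates on the smallest per-sample
#'   occupancy FDR; `"zscore"` instead BH-adjusts two-sided normal
#'   p-values of the z-scores and gates on those.
#' @param conditions length-2 character, the (x, y) condition order
#'   (default `c("control", "shi")`).
#' @return A [DifferentialTable-class]; `metadata()` holds the fitted
#'   `line` and the gate `counts`.
#' @export
callDifferential <- function(table, fdrCut = 0.01, zCut = 1.96,
                             gatcCut = 1L,
                             fdrFrom = c("occupancy", "zscore"),
                             conditions = c("control", "shi")) {
    stopifnot(is(table, "GeneOccupancyTable"))
    fdrFrom <- match.arg(fdrFrom)
    xcol <- paste0("mean_", conditions[1])
    ycol <- paste0("mean_", conditions[2])
    fdrc <- grep("^fdr_", colnames(table), value = TRUE)
    need <- c(xcol, ycol, "n_gatc_sites")
    miss <- setdiff(need, colnames(table))
    if (length(miss) || !length(fdrc))
        stop("schema error: missing column(s): ",
             paste(c(miss, if (!length(fdrc)) "fdr_*"), collapse = ", "))
    keep <- is.finite(table[[xcol]]) & is.finite(table[[ycol]])
    tbl <- table[keep, ]
    x <- tbl[[xcol]]; y <- tbl[[ycol]]
    line <- pcaRegression(x, y)
    rz <- residualZscores(x, y, line)
    minFdr <- do.call(pmin,
                      c(as.list(as.data.frame(tbl[, fdrc, drop = FALSE])),
                        na.rm = TRUE))
    gateFdr <- if (fdrFrom == "occupancy") minFdr
               else p.adjust(2 * stats::pnorm(-abs(rz$z)), method = "BH")
    sig <- (gateFdr < fdrCut) & (abs(rz$z) > zCut) &
           (tbl$n_gatc_sites > gatcCut)
    out <- DataFrame(gene_id = tbl$gene_id,
                     biotype = tbl$biotype,
                     x = x, y = y,
                     residual = rz$residual,
                     z = rz$z,
                     n_gatc_sites = tbl$n_gatc_sites,
                     min_fdr = minFdr,
                     significant = sig,
                     direction = ifelse(rz$z > 0, "up", "down"))
    counts <- list(n_tested = nrow(out),
                   n_significant = sum(sig),
                   per_biotype = base::table(out$biotype[sig]))
    md <- metadata(table)
    md$line <- line
    md$counts <- counts
    md$cutoffs <- list(fdr = fdrCut, z = zCut, gatc = gatcCut,
                       fdr_from = fdrFrom)
    out <- new("DifferentialTable", out)
    metadata(out) <- md
    out
}
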