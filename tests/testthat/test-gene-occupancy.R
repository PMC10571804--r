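test_that("gene means average overlapping fragments, NA when uncovered", {
    fmap <- fragmentsFromCuts(1000, c(200, 500))
    occ <- matrix(c(1, 3, -0.7), ncol = 1)
    tr <- makeTrack(occ, fmap)
    genes <- makeGenes(starts = c(50, 600, 980), ends = c(450, 900, 995),
                       L = 1000)
    m <- geneMeanOccupancy(tr, genes)
    expect_equal(unname(m[1, 1]), 2.0)       # fragments 1 and 2
    expect_equal(unname(m[2, 1]), -0.7)      # single fragment
    expect_equal(unname(m[3, 1]), -0.7)
})

test_that("gene beyond chromosome bounds raises an annotation error", {
    fmap <- fragmentsFromCuts(1000, c(200, 500))
    tr <- makeTrack(matrix(0, 3, 1), fmap)
    genes <- suppressWarnings(makeGenes(starts = 900, ends = 1200,
                                        L = 1000))
    expect_error(geneMeanOccupancy(tr, genes), "bounds")
})

test_that("gene means agree with a brute-force fragment-by-gene oracle", {
    cfg <- miniConfig(seed = 31L)
    fmap <- simulateFragmentMap(cfg)
    set.seed(101)
    occ <- matrix(rnorm(length(fmap) * 2), ncol = 2)
    tr <- makeTrack(occ, fmap)
    gstart <- sort(sample(2.8e5, 50))
    genes <- makeGenes(starts = gstart, ends = pmin(gstart + 1999, 3e5),
                       L = 3e5)
    m <- geneMeanOccupancy(tr, genes)
    fr1 <- fmap[seqnames(fmap) == "chr1"]
    o1 <- occ[as.character(seqnames(fmap)) == "chr1", , drop = FALSE]
    for (i in seq_along(genes)) {           # quadratic oracle
        ov <- start(fr1) <= end(genes)[i] & end(fr1) >= start(genes)[i]
        expected <- colMeans(o1[ov, , drop = FALSE])
        expect_equal(unname(m[i, ]), unname(expected), tolerance = 1e-12)
    }
})

test_that("gene means do not depend on fragment order", {
    fmap <- fragmentsFromCuts(1000, c(200, 500))
    occ <- matrix(c(1, 3, 5), ncol = 1)
    genes <- makeGenes(starts = 100, ends = 900, L = 1000)
    m1 <- geneMeanOccupancy(makeTrack(occ, fmap), genes)
    perm <- c(3, 1, 2)
    m2 <- geneMeanOccupancy(makeTrack(occ[perm, , drop = FALSE],
                                      fmap[perm]), genes)
    expect_equal(m1, m2)
})

test_that("GATC site counts are internal fragment boundaries", {
    fmap <- fragmentsFromCuts(1000, c(200, 500))
    genes <- makeGenes(starts = c(1, 250, 150), ends = c(1000, 450, 600),
                       L = 1000)
    n <- countGatcSites(genes, fmap)
    expect_equal(unname(n), c(2L, 0L, 2L))
})

test_that("GATC counts match a linear-scan oracle on random placements", {
    cfg <- miniConfig(seed = 32L)
    fmap <- simulateFragmentMap(cfg)
    set.seed(55)
    gstart <- sort(sample(2.9e5, 80))
    genes <- makeGenes(starts = gstart, ends = pmin(gstart + 4999, 3e5),
                       L = 3e5)
    n <- countGatcSites(genes, fmap)
    fr1 <- fmap[seqnames(fmap) == "chr1"]
    cuts <- start(fr1)[-1] - 1L              # 0-based interior boundaries
    for (i in seq_along(genes)) {
        expected <- sum(cuts > start(genes)[i] - 1L & cuts < end(genes)[i])
        expect_equal(unname(n[i]), expected)
    }
})

test_that("the top gene hits the add-one smoothing floor", {
    fmap <- fragmentsFromCuts(20000, seq(100, 19900, by = 100))
    set.seed(9)
    occ <- matrix(rnorm(length(fmap)), ncol = 1)
    occ[5:8] <- 1e6      # practically unreachable by random null sets
    tr <- makeTrack(occ, fmap)
    genes <- makeGenes(starts = 420, ends = 780, L = 20000) # fragments 5:8
    p <- occupancyFdr(tr, genes, nPerm = 200L, seed = 4L, adjust = FALSE)
    expect_equal(unname(p[1, 1]), 1 / 201)
})

test_that("permutation p-values are uniform on a shuffled track", {
    for (s in 1:3) {
        cfg <- SimConfig(seed = s)
        sim <- simulateTada(cfg)
        tr <- occupancyRatio(normalizeLibrary(sim$counts))
        occ <- assay(tr, "occupancy")
        set.seed(1000 + s)
        shuf <- occ[sample(nrow(occ)), 1, drop = FALSE]
        trS <- makeTrack(shuf, rowRanges(tr))
        p <- occupancyFdr(trS, sim$genes, nPerm = 1000L, seed = 2L,
                          adjust = FALSE)[, 1]
        ks <- suppressWarnings(ks.test(p[!is.na(p)], "punif"))
        expect_gt(ks$p.value, 0.01)
    }
})

test_that("BH adjustment is monotone in the raw p-value ranks", {
    cfg <- miniConfig(seed = 41L)
    sim <- simulateTada(cfg)
    tr <- occupancyRatio(normalizeLibrary(sim$counts))
    p <- occupancyFdr(tr, sim$genes, nPerm = 200L, seed = 3L,
                      adjust = FALSE)[, 1]
    fdr <- occupancyFdr(tr, sim$genes, nPerm = 200L, seed = 3L)[, 1]
    ord <- order(p)
    expect_true(all(diff(fdr[ord]) >= -1e-12))
    expect_true(all(fdr >= p - 1e-12))
})

test_that("bound-gene screen keeps all/none at the FDR extremes", {
    cfg <- miniConfig(seed = 42L)
    sim <- simulateTada(cfg)
    tr <- occupancyRatio(normalizeLibrary(sim$counts))
    tbl <- geneOccupancy(tr, sim$genes, nPerm = 100L, seed = 1L)
    fdrc <- grep("^fdr_", colnames(tbl), value = TRUE)
    setFdr <- function(tbl, val) {
        d <- as(tbl, "DFrame")
        for (cc in fdrc) d[[cc]] <- rep(val, nrow(d))
        new("GeneOccupancyTable", d)
    }
    all0 <- setFdr(tbl, 0)
    expect_equal(nrow(filterBoundGenes(all0)), nrow(tbl))
    all1 <- setFdr(tbl, 1)
    expect_warning(out <- filterBoundGenes(all1), "no genes")
    expect_equal(nrow(out), 0L)
})

test_that("permutation FDR requires a sane permutation count", {
    cfg <- miniConfig(seed = 43L)
    sim <- simulateTada(cfg)
    tr <- occupancyRatio(normalizeLibrary(sim$counts))
    expect_error(occupancyFdr(tr, sim$genes, nPerm = 50L), "100")
})
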