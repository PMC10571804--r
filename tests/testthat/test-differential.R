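test_that("points on y = x give the diagonal direction", {
    x <- c(0, 1, 2, 3)
    fit <- pcaRegression(x, x)
    expect_equal(fit$direction, c(1, 1) / sqrt(2), tolerance = 1e-9)
    expect_equal(fit$slope, 1, tolerance = 1e-9)
})

test_that("a noiseless line y = 2x + 1 is reproduced exactly", {
    x <- seq(-3, 3, length.out = 20)
    fit <- pcaRegression(x, 2 * x + 1)
    expect_equal(fit$slope, 2, tolerance = 1e-9)
    expect_equal(fit$intercept, 1, tolerance = 1e-9)
})

test_that("the PCA line matches an angle-grid orthogonal-least-squares oracle", {
    set.seed(23)
    x <- rnorm(200, sd = 2)
    y <- 1.3 * x + rnorm(200, sd = 0.8)
    fit <- pcaRegression(x, y)
    # oracle: scan 1e4 candidate angles, minimize summed squared
    # perpendicular distance to the line through the centroid
    cx <- x - mean(x); cy <- y - mean(y)
    theta <- seq(0, pi, length.out = 10001)[-10001]
    ssq <- vapply(theta, function(t) {
        sum((-sin(t) * cx + cos(t) * cy)^2)
    }, numeric(1))
    best <- theta[which.min(ssq)]
    fitAngle <- atan2(fit$direction[2], fit$direction[1]) %% pi
    dev <- abs(fitAngle - best)
    dev <- min(dev, pi - dev)
    expect_lt(dev * 180 / pi, 0.1)
})

test_that("collinear input trips the degenerate-scatter error", {
    x <- c(0, 1, 2, 3)
    fit <- pcaRegression(x, x)
    expect_error(residualZscores(x, x, fit), "degenerate")
})

test_that("isotropic scatter trips the equal-eigenvalue error", {
    x <- c(1, -1, 0, 0)
    y <- c(0, 0, 1, -1)       # exactly isotropic covariance
    expect_error(pcaRegression(x, y), "isotropic")
})

test_that("symmetric offsets give equal and opposite z-scores", {
    base <- seq(0, 10, length.out = 10)
    fit <- pcaRegression(base, base)          # fix the y = x line
    d <- 0.4
    # vertical offset d*sqrt(2) is perpendicular distance d from y = x
    x <- c(2, 8);  y <- c(2 + d * sqrt(2), 8 - d * sqrt(2))
    rz <- residualZscores(x, y, fit)
    expect_equal(rz$residual, c(d, -d), tolerance = 1e-9)
    expect_equal(rz$z[1], -rz$z[2], tolerance = 1e-9)
})

test_that("z-scores match the explicit point-line distance formula", {
    set.seed(24)
    x <- rnorm(150); y <- 0.8 * x + rnorm(150, sd = 0.5)
    fit <- pcaRegression(x, y)
    rz <- residualZscores(x, y, fit)
    # oracle: signed distance to a*x + b*y + c = 0 with the line written
    # from slope/intercept, positive above the line
    a <- -fit$slope; b <- 1; c <- -fit$intercept
    dist <- (a * x + b * y + c) / sqrt(a^2 + b^2)
    expect_equal(rz$residual, dist, tolerance = 1e-9)
    expect_equal(rz$z, dist / sd(dist), tolerance = 1e-9)
    expect_lt(abs(mean(rz$residual)), 1e-9)   # centroid construction
})

test_that("z is unchanged by adding a constant to both axes", {
    set.seed(25)
    x <- rnorm(100); y <- x + rnorm(100, sd = 0.3)
    z1 <- residualZscores(x, y, pcaRegression(x, y))$z
    z2 <- residualZscores(x + 5, y + 5, pcaRegression(x + 5, y + 5))$z
    expect_lt(max(abs(z1 - z2)), 1e-9)
})

test_that("swapping the condition axes negates every z", {
    set.seed(26)
    x <- rnorm(100, sd = 1.5); y <- x + rnorm(100, sd = 0.4)
    z1 <- residualZscores(x, y, pcaRegression(x, y))$z
    z2 <- residualZscores(y, x, pcaRegression(y, x))$z
    expect_equal(z1, -z2, tolerance = 1e-9)
})

test_that("Gaussian residuals put ~95% of genes inside |z| <= 1.96", {
    set.seed(27)
    n <- 5000
    x <- rnorm(n, sd = 2); y <- x + rnorm(n, sd = 0.5)
    z <- residualZscores(x, y, pcaRegression(x, y))$z
    expect_lt(abs(mean(abs(z) <= 1.96) * 100 - 95), 1.5)
})

# hand-built gene table: 40 concordant genes plus two clear outliers
.mkGeneTable <- function(nGatcUp = 5L, fdrUp = 0.001) {
    set.seed(30)
    n <- 40
    x <- seq(-2, 6, length.out = n)
    y <- x + rnorm(n, sd = 0.05)
    x <- c(x, 2, 3); y <- c(y, 2 + 3, 3 - 3)   # outliers up/down
    tbl <- S4Vectors::DataFrame(
        gene_id = sprintf("g%03d", seq_along(x)),
        biotype = rep(c("protein_coding", "lncRNA"), length.out = length(x)),
        n_gatc_sites = c(rep(10L, n), nGatcUp, 7L),
        mean_control = x, mean_shi = y,
        fdr_control_1 = c(rep(0.001, n), fdrUp, 0.002),
        fdr_shi_1 = c(rep(0.001, n), fdrUp, 0.002))
    new("GeneOccupancyTable", tbl)
}

test_that("the three significance gates act conjunctively", {
    d <- callDifferential(.mkGeneTable(), conditions = c("control", "shi"))
    up <- d[d$gene_id == "g041", ]; dn <- d[d$gene_id == "g042", ]
    expect_gt(up$z, 1.96); expect_lt(dn$z, -1.96)
    expect_true(up$significant); expect_true(dn$significant)
    expect_equal(up$direction, "up"); expect_equal(dn$direction, "down")

    # GATC gate is strict: exactly 1 site fails "> 1"
    d1 <- callDifferential(.mkGeneTable(nGatcUp = 1L))
    expect_false(d1[d1$gene_id == "g041", ]$significant)
    expect_gt(d1[d1$gene_id == "g041", ]$z, 1.96)   # only the gate differs

    # FDR gate
    d2 <- callDifferential(.mkGeneTable(fdrUp = 0.5))
    expect_false(d2[d2$gene_id == "g041", ]$significant)

    # missing columns -> schema error
    broken <- .mkGeneTable()
    broken$mean_shi <- NULL
    expect_error(callDifferential(broken), "schema")
})

test_that("direction tracks the sign of z over the whole table", {
    d <- callDifferential(.mkGeneTable())
    expect_true(all(d$direction[d$z > 0] == "up"))
    expect_true(all(d$direction[d$z < 0] == "down"))
    md <- S4Vectors::metadata(d)
    expect_equal(md$counts$n_tested, 42L)
    expect_equal(md$counts$n_significant, sum(d$significant))
})

test_that("the z-score FDR flag is available as an alternative gate", {
    d <- callDifferential(.mkGeneTable(), fdrFrom = "zscore")
    expect_true(d[d$gene_id == "g041", ]$significant)
    expect_true(all(!d$significant[abs(d$z) <= 1.96]))
})
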