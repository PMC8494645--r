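# a flat-surface slice with analytically known depths
flatSlice <- function(n = 400, a = 100, b = 0.02, thickness = 1200,
                      seed = 1) {
    withSeed(seed, {
        x <- runif(n, 0, 2000)
        depth <- runif(n, 0, 1.1)
        sub <- rep("other", n)
        sub[1:40] <- "VLMC"; depth[1:40] <- 0
        sub[41:80] <- "L6b"; depth[41:80] <- 1
        # vertical offset = depth * thickness; true distance to the line
        # y = a + b x is offset / sqrt(1 + b^2)
        y <- a + b * x + depth * thickness
        list(cells = data.frame(x = x, y = y, slice_id = 1L),
             subclass = sub, depth = depth, b = b)
    })
}

test_that("depths equal analytic distances on a flat-surface slice", {
    s <- flatSlice()
    dp <- fitSurfaceAndDepth(s$cells, s$subclass)
    # VLMC cells sit on the surface; the median L6b cell is at depth 1
    expect_lt(max(dp$depth[s$subclass == "VLMC"]), 0.01)
    expect_equal(median(dp$depth[s$subclass == "L6b"]), 1)
    # vertical offsets project onto the line with factor 1/sqrt(1+b^2),
    # which cancels in the normalization
    expect_equal(dp$depth, s$depth, tolerance = 0.005)
    # translation and a mild rotation leave normalized depths unchanged
    th <- 3 * pi / 180
    xr <- s$cells$x * cos(th) - s$cells$y * sin(th) + 500
    yr <- s$cells$x * sin(th) + s$cells$y * cos(th) - 200
    dp2 <- fitSurfaceAndDepth(data.frame(x = xr, y = yr, slice_id = 1L),
                              s$subclass)
    expect_equal(dp2$depth, dp$depth, tolerance = 0.01)
})

test_that("slices without anchor populations are excluded with a warning", {
    s <- flatSlice()
    sub <- s$subclass
    sub[sub == "L6b"] <- "other"
    expect_warning(dp <- fitSurfaceAndDepth(s$cells, sub), "lacks VLMC or L6b")
    expect_true(all(is.na(dp$depth)))
})

test_that("recovered per-cluster median depths track generator truth", {
    a <- cachedAtlas(20000, seed = 5)
    tr <- atlasTruth(a)
    dp <- fitSurfaceAndDepth(a, tr$subclass)
    keep <- !is.na(dp$depth) & !tr$is_doublet & !tr$is_artifact
    med <- tapply(dp$depth[keep], tr$cluster[keep], median)
    truthMed <- tapply(tr$depth[keep], tr$cluster[keep], median)
    big <- names(which(table(tr$cluster[keep]) >= 250))
    expect_gt(length(big), 10)
    expect_true(all(abs(med[big] - truthMed[big]) <= 0.02))
})

test_that("layer boundaries reproduce planted cluster medians in order", {
    set.seed(2)
    mk <- function(cl, sc, mu, n = 101) data.frame(
        depth = mu + seq(-0.02, 0.02, length.out = n), cluster = cl,
        subclass = sc)
    d <- rbind(mk("L2/3 IT 1", "L2/3 IT", 0.12), mk("L2/3 IT 2", "L2/3 IT", 0.2),
               mk("L4/5 IT 1", "L4/5 IT", 0.35), mk("L4/5 IT 5", "L4/5 IT", 0.48),
               mk("L5 IT 1", "L5 IT", 0.55), mk("L6 IT 1", "L6 IT", 0.7),
               mk("L6 CT 1", "L6 CT", 0.85), mk("L6b 1", "L6b", 1.0))
    lb <- layerBoundaries(d$depth, d$cluster, d$subclass)
    expect_equal(lb$L23_top, 0.12)
    expect_equal(lb$L4_top, 0.35)
    expect_equal(lb$L5_top, c(0.48, 0.55))
    expect_equal(lb$L6_top, 0.7)
    expect_equal(lb$L6b_bounds,
                 unname(quantile(d$depth[d$subclass == "L6b"], c(.25, .75))))
    # generator defaults give ordered boundaries
    a <- cachedAtlas(20000, seed = 5)
    tr <- atlasTruth(a)
    lb2 <- layerBoundaries(tr$depth, tr$cluster, tr$subclass)
    expect_true(!is.unsorted(c(lb2$surface, lb2$L23_top, lb2$L4_top,
                               lb2$L5_top, lb2$L6_top)))
    # a pathological configuration raises
    d2 <- d; d2$depth[d2$cluster == "L4/5 IT 1"] <- 0.05
    expect_error(layerBoundaries(d2$depth, d2$cluster, d2$subclass),
                 "monotonically")
})

test_that("marker overlap fraction follows the half-maximum band", {
    withSeed(3, {
        n <- 5000
        depths <- runif(n)
        x <- cbind(step = ifelse(depths > 0.5, 10, 0) + runif(n, 0, 0.1),
                   const = rep(5, n))
        cl <- seq_len(n)  # the whole population as one uniform cluster
        f <- markerOverlapFraction(cl, "step", x, depths)
        expect_lt(abs(f - 0.5), 0.03)
        # cluster entirely inside the band
        inside <- which(depths > 0.7)
        expect_equal(markerOverlapFraction(inside, "step", x, depths), 1)
        # constant marker puts every bin above half max
        expect_equal(markerOverlapFraction(cl, "const", x, depths), 1)
        expect_error(markerOverlapFraction(integer(), "const", x, depths),
                     "empty")
    })
})

test_that("density overlap matches the closed-form normal overlap", {
    withSeed(4, {
        a <- rnorm(3000); b <- rnorm(3000, 2)
        # closed form for two unit normals two apart: 2 * pnorm(-1)
        expect_lt(abs(densityOverlap(a, b) - 2 * pnorm(-1)), 0.02)
        expect_equal(densityOverlap(a, b), densityOverlap(b, a))
        expect_gt(densityOverlap(a, a), 0.99)
        expect_lt(densityOverlap(a, a + 50), 0.01)
    })
})

test_that("neighbourhood complexity counts distinct labels within radius", {
    # hand-built 5-cell configuration: cells of 3 clusters within 100 um
    # of the first cell, one cell of a 4th cluster outside
    cells <- data.frame(x = c(0, 50, 80, 30, 500),
                        y = c(0, 0, 30, -40, 0), slice_id = 1L)
    cl <- c("A", "B", "C", "A", "D")
    nc <- neighborhoodComplexity(cells, cl, radius = 100)
    expect_equal(nc[1], 3)
    expect_true(all(nc <= length(unique(cl))))
    # an isolated cell counts only its own cluster
    iso <- data.frame(x = c(0, 1000), y = c(0, 0), slice_id = 1L)
    expect_equal(neighborhoodComplexity(iso, c("A", "B"), 100), c(1L, 1L))
    # cells on different slices are never neighbours
    two <- data.frame(x = c(0, 0), y = c(0, 0), slice_id = c(1L, 2L))
    expect_equal(neighborhoodComplexity(two, c("A", "B"), 100), c(1L, 1L))
})

test_that("coordinate profiles recover planted 1-D distributions", {
    withSeed(9, {
        coord <- c(runif(500, 0, 1), runif(500, 0.5, 1))
        grp <- rep(c("broad", "posterior"), each = 500)
        cp <- coordinateDistribution(coord, grp, nBins = 10)
        expect_equal(unname(rowSums(cp$fractions)), c(1, 1))
        # the restricted group has (almost) no mass in the anterior half;
        # equal-width bins span the pooled data range, so the fifth bin's
        # upper edge can sit marginally above 0.5
        expect_lt(sum(cp$fractions["posterior", 1:5]), 0.01)
        expect_gt(min(cp$fractions["broad", ]), 0.05)
    })
})
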