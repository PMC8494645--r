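test_that("tracer thresholding derives on/off and projection status", {
    # toy 6-cell table with pre-normalized intensities
    x <- rbind(c(9, 0, 0), c(0, 8, 7), c(0, 0, 0), c(6, 0, 0),
               c(9, 9, 9), c(0, 0, 6))
    colnames(x) <- c("MOs", "SSp", "TEa")
    pl <- thresholdTracer(x, thresholds = 5, normalize = FALSE)
    expect_equal(pl$status, c("single", "multi", "none", "single",
                              "multi", "single"))
    expect_equal(pl$target, c("MOs", NA, NA, "MOs", NA, "TEa"))
    expect_equal(unname(pl$n_targets), c(1, 2, 0, 1, 3, 1))
    # robust scaling separates labelled from background intensities
    withSeed(1, {
        bg <- abs(rnorm(500, 0, 0.3))
        on <- rlnorm(60, log(5), 0.3)
        v <- cbind(ch = c(bg, on))
        pl2 <- thresholdTracer(v, thresholds = 5)
        expect_gt(mean(pl2$on[501:560, 1]), 0.95)
        expect_lt(mean(pl2$on[1:500, 1]), 0.02)
    })
})

test_that("depth enrichment is 1 under uniform labelling and exact on a two-bin toy", {
    withSeed(2, {
        n <- 4000
        sub <- rep("L5 IT", n)
        depths <- runif(n)
        on <- matrix(runif(n) < 0.3, n, 1, dimnames = list(NULL, "MOs"))
        labs <- structure(list(on = on), class = "ProjectionLabels")
        e <- depthEnrichment(labs, sub, depths, "MOs", nBins = 10)
        expect_equal(e$enrichment, rep(1, 10), tolerance = 0.15)
    })
    # two bins, reference 100/100, positives 30/10 -> enrichment 1.5, 0.5
    depths <- c(seq(0, 0.49, length.out = 100),
                seq(0.51, 1, length.out = 100))
    on <- matrix(FALSE, 200, 1, dimnames = list(NULL, "SSp"))
    on[c(1:30, 101:110), 1] <- TRUE
    labs <- structure(list(on = on), class = "ProjectionLabels")
    e2 <- depthEnrichment(labs, rep("L6b", 200), depths, "SSp", nBins = 2)
    expect_equal(e2$enrichment, c(1.5, 0.5))
    expect_error(depthEnrichment(labs, rep("Astro", 200), depths, "SSp", 2),
                 "no tracer-positive")
})

test_that("composition fractions are exact on a hand-built table", {
    # 20 labelled cells across 3 clusters, targets assigned by hand
    cl <- c(rep("X 1", 8), rep("X 2", 6), rep("Y 1", 6))
    sc <- c(rep("X", 14), rep("Y", 6))
    on <- matrix(FALSE, 20, 2, dimnames = list(NULL, c("MOs", "TEa")))
    on[1:6, "MOs"] <- TRUE           # X 1: 6 MOs
    on[7:8, "TEa"] <- TRUE           # X 1: 2 TEa
    on[9:14, "TEa"] <- TRUE          # X 2: 6 TEa
    on[15:20, "MOs"] <- TRUE         # Y 1: 6 MOs
    on[15, "TEa"] <- TRUE            # one multi-projecting cell
    labs <- thresholdTracer(on * 10, thresholds = 5, normalize = FALSE)
    comp <- projectionComposition(labs, cl, sc, nBoot = 50, seed = 1)
    expect_equal(comp$per_cluster["X 1", ], c(MOs = 0.75, TEa = 0.25))
    expect_equal(comp$per_cluster["X 2", ], c(MOs = 0, TEa = 1))
    # the multi-projecting cell is excluded: Y 1 has 5 single MOs cells
    expect_equal(comp$per_cluster["Y 1", ], c(MOs = 1, TEa = 0))
    # per-target compositions sum to 1
    expect_equal(unname(colSums(comp$per_target_cluster)), c(1, 1))
    expect_equal(unname(comp$per_target_cluster["X 1", "MOs"]), 6 / 11)
    expect_equal(unname(comp$per_target_subclass["Y", "MOs"]), 5 / 11)
    # CI bounds bracket the estimates
    expect_true(all(comp$ci$lo <= comp$ci$fraction + 1e-9 &
                    comp$ci$hi >= comp$ci$fraction - 1e-9))
    # nBoot = 1 collapses the interval onto the point estimate
    c1 <- projectionComposition(labs, cl, sc, nBoot = 1, seed = 1)
    expect_equal(c1$ci$lo, c1$ci$fraction)
    expect_equal(c1$ci$hi, c1$ci$fraction)
})

test_that("compositions are invariant to cell order", {
    withSeed(3, {
        n <- 500
        cl <- sample(c("A 1", "A 2", "B 1"), n, TRUE)
        sc <- substr(cl, 1, 1)
        on <- matrix(runif(2 * n) < 0.2, n, 2,
                     dimnames = list(NULL, c("MOs", "SSp")))
        labs <- structure(list(on = on,
                               status = ifelse(rowSums(on) == 1, "single",
                                               ifelse(rowSums(on) == 0,
                                                      "none", "multi")),
                               target = ifelse(rowSums(on) == 1,
                                               colnames(on)[max.col(on)],
                                               NA)),
                          class = "ProjectionLabels")
        c1 <- projectionComposition(labs, cl, sc, nBoot = 1)
        perm <- sample(n)
        labs2 <- labs
        labs2$on <- on[perm, ]; labs2$status <- labs$status[perm]
        labs2$target <- labs$target[perm]
        c2 <- projectionComposition(labs2, cl[perm], sc[perm], nBoot = 1)
        expect_equal(c1$per_cluster, c2$per_cluster)
        expect_equal(c1$per_target_subclass, c2$per_target_subclass)
    })
})

test_that("synthetic tracer data recover the generator's composition truth", {
    a <- cachedAtlas(8000, seed = 2)
    tr <- atlasTruth(a)
    tt <- generateTracer(a, seed = 3)
    labs <- thresholdTracer(tt$intensity, thresholds = 5)
    # thresholding recovers the true labels almost perfectly
    expect_gt(mean(labs$on == tt$truth), 0.995)
    # ~90% of tracer-positive cells are IT or L6b
    pos <- labs$n_targets > 0
    itl6b <- tr$group == "IT" | tr$subclass == "L6b"
    expect_equal(mean(itl6b[pos]), 0.90, tolerance = 0.04)
    # the disjoint-target scenario: L6 IT 1 vs L6 IT 3 (truth clusters)
    comp <- projectionComposition(labs, tr$cluster, tr$subclass, nBoot = 20,
                                  seed = 4)
    expect_gt(comp$per_cluster["L6 IT 1", "MOs"], 0.6)
    expect_equal(comp$per_cluster["L6 IT 1", "TEa-ECT-PERI"], 0)
    expect_equal(comp$per_cluster["L6 IT 3", "MOs"], 0)
    expect_gt(comp$per_cluster["L6 IT 3", "TEa-ECT-PERI"], 0.6)
    # recovered per-subclass composition sits inside the bootstrap CI for
    # nearly all entries when compared to the generator truth
    labsT <- structure(list(on = tt$truth,
                            status = ifelse(rowSums(tt$truth) == 1, "single",
                                            ifelse(rowSums(tt$truth) == 0,
                                                   "none", "multi")),
                            target = ifelse(rowSums(tt$truth) == 1,
                                            colnames(tt$truth)[
                                                max.col(tt$truth)], NA)),
                       class = "ProjectionLabels")
    compT <- projectionComposition(labsT, tr$cluster, tr$subclass, nBoot = 1)
    inCI <- mapply(function(t0, s0, lo, hi) {
        tv <- compT$per_target_subclass[s0, t0]
        tv >= lo - 1e-9 & tv <= hi + 1e-9
    }, comp$ci$target, comp$ci$subclass, comp$ci$lo, comp$ci$hi)
    expect_gte(mean(inCI), 0.9)
})
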