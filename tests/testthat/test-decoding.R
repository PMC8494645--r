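test_that("preprocessing removes flat background and preserves spot centroids", {
    cb <- smallCodebook()
    # flat image goes to zero under the high-pass
    flat <- new("ImageStack",
                pixels = array(3, dim = c(nBits(cb), 32, 32)),
                pixelSize = 1, groundTruth = NULL)
    pp <- preprocessStack(flat, highpassSigma = 4, lrIterations = 0,
                          lowpassSigma = 0)
    expect_true(all(stackPixels(pp) < 1e-6))
    # identity when everything is switched off
    st <- generateSpotStack(cb, nMolecules = 5, size = 48, seed = 3)
    id <- preprocessStack(st, highpassSigma = 0, lrIterations = 0,
                          lowpassSigma = 0)
    expect_equal(stackPixels(id), stackPixels(st))
    # a single Gaussian spot keeps its centroid within 0.5 px
    px <- array(0, dim = c(1, 41, 41))
    g <- outer(dnorm(1:41, 20.3, 1.2), dnorm(1:41, 22.7, 1.2))
    px[1, , ] <- g / max(g)
    spot <- new("ImageStack", pixels = px, pixelSize = 1,
                groundTruth = NULL)
    pp2 <- preprocessStack(spot, highpassSigma = 6, lrIterations = 10,
                           lowpassSigma = 0.7)
    img <- stackPixels(pp2)[1, , ]
    cy <- sum(row(img) * img) / sum(img)
    cx <- sum(col(img) * img) / sum(img)
    expect_lt(abs(cy - 20.3), 0.5)
    expect_lt(abs(cx - 22.7), 0.5)
})

test_that("noiseless fields decode with perfect recall and precision", {
    cb <- smallCodebook()
    st <- generateSpotStack(cb, nMolecules = 60, size = 96, seed = 11)
    mol <- pixelDecode(st, cb)
    truth <- stackTruth(st)
    expect_equal(sum(mol$is_blank & FALSE), 0)
    # per-entry counts match the ground truth exactly
    expect_equal(table(factor(mol$entry, entryNames(cb))),
                 table(factor(truth$entry, entryNames(cb))))
    # every truth molecule has a decoded centroid within one pixel
    d <- sqrt(outer(truth$x, mol$x, "-")^2 + outer(truth$y, mol$y, "-")^2)
    sameEntry <- outer(truth$entry, mol$entry, "==")
    expect_true(all(apply(ifelse(sameEntry, d, Inf), 1, min) <
                    1.5 * pixelSize(st)))
    # empty stack decodes to nothing
    empty <- new("ImageStack",
                 pixels = array(0, dim = c(nBits(cb), 32, 32)),
                 pixelSize = 1, groundTruth = NULL)
    expect_equal(nrow(pixelDecode(empty, cb)), 0)
})

test_that("a dropped on-bit is recovered by single-error correction", {
    cb <- smallCodebook()
    st <- generateSpotStack(cb, nMolecules = 40, size = 96,
                            dropoutProb = 1, seed = 5)
    mol <- pixelDecode(st, cb)
    truth <- stackTruth(st)
    expect_equal(table(factor(mol$entry, entryNames(cb))),
                 table(factor(truth$entry, entryNames(cb))))
    expect_true(all(mol$n_corrected > 0.5))
    # with correction disabled the dropped molecules are lost
    mol0 <- pixelDecode(st, cb, maxErrors = 0L)
    expect_lt(nrow(mol0), nrow(mol) / 2)
})

test_that("decoding is invariant to global intensity scaling", {
    cb <- smallCodebook()
    st <- generateSpotStack(cb, nMolecules = 30, size = 64, seed = 9)
    st2 <- methods::initialize(st, pixels = stackPixels(st) * 37)
    m1 <- pixelDecode(st, cb)
    m2 <- pixelDecode(st2, cb)
    expect_equal(m1$entry, m2$entry)
    expect_equal(m1$x, m2$x)
})

test_that("misidentification rate follows the blank/coding mean ratio", {
    cb <- buildCodebook(22, 4, 4, genes = 242, nBlanks = 10, seed = 1)
    mol <- data.frame(entry = c(
        rep(codebookBlanks(cb), length.out = 20),
        rep(codebookGenes(cb), length.out = 9680)))
    expect_equal(estimateMisidRate(mol, cb), 0.05)
    expect_equal(estimateMisidRate(
        data.frame(entry = rep(codebookGenes(cb), 10)), cb), 0)
    # every entry with equal calls gives rate 1
    expect_equal(estimateMisidRate(
        data.frame(entry = rep(entryNames(cb), each = 10)), cb), 1)
    expect_error(estimateMisidRate(
        data.frame(entry = codebookBlanks(cb)), cb), "no coding")
})

test_that("adaptive filter hits the target rate and never worsens it", {
    cb <- smallCodebook()
    set.seed(21)
    n <- 4000
    isBlankCall <- runif(n) < 0.10
    entry <- ifelse(isBlankCall,
                    sample(codebookBlanks(cb), n, TRUE),
                    sample(codebookGenes(cb), n, TRUE))
    # blanks are concentrated at low quality, as in real decoding
    quality <- ifelse(isBlankCall, runif(n, 0, 0.6), runif(n))
    mol <- data.frame(entry = entry, mean_intensity = quality,
                      barcode_distance = 1 - quality,
                      stringsAsFactors = FALSE)
    kept <- adaptiveMisidFilter(mol, cb, targetRate = 0.05)
    r0 <- estimateMisidRate(mol, cb)
    r1 <- estimateMisidRate(kept, cb)
    expect_lte(r1, 0.05 + 1e-9)
    expect_lte(r1, r0)
    # oracle: sweep every quality threshold; the filter's retained rate
    # must match the best achievable prefix rate under the same ordering
    score <- rank(mol$mean_intensity) * rank(-mol$barcode_distance)
    ord <- order(-score)
    isB <- mol$entry[ord] %in% codebookBlanks(cb)
    rates <- (cumsum(isB) / sum(isBlank(cb))) /
        (cumsum(!isB) / sum(!isBlank(cb)))
    best <- max(which(rates <= 0.05))
    expect_equal(nrow(kept), best)
    # zero blank calls -> nothing filtered
    molG <- mol[!isBlankCall, ]
    expect_equal(nrow(adaptiveMisidFilter(molG, cb, 0.05)), nrow(molG))
})

test_that("watershed segmentation splits touching cells around their nuclei", {
    mkBlob <- function(img, cy, cx, r, val = 1) {
        for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
            if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j] <- val
        img
    }
    z <- matrix(0, 60, 60)
    nuc <- mkBlob(mkBlob(z, 20, 20, 4), 20, 34, 4)
    pol <- mkBlob(mkBlob(z, 20, 20, 10, 0.8), 20, 34, 10, 0.8)
    seg <- segmentCells(nuc, pol, pixelSize = 1)
    expect_equal(nrow(seg$cells), 2)
    # masks disjoint by construction; each seed inside its own mask
    expect_equal(seg$mask[20, 20] != seg$mask[20, 34], TRUE)
    expect_true(all(seg$mask[20, c(20, 34)] > 0))
    # two well-separated nuclei -> 2 cells containing their nuclei
    nuc2 <- mkBlob(mkBlob(z, 15, 15, 4), 45, 45, 4)
    pol2 <- mkBlob(mkBlob(z, 15, 15, 9, 0.8), 45, 45, 9, 0.8)
    seg2 <- segmentCells(nuc2, pol2)
    expect_equal(nrow(seg2$cells), 2)
    expect_equal(nrow(segmentCells(z, z)$cells), 0)
})

test_that("molecules map to containing masks and aggregate to counts", {
    cb <- smallCodebook()
    mask <- matrix(0L, 20, 20)
    mask[2:8, 2:8] <- 1L
    mask[12:18, 12:18] <- 2L
    seg <- list(mask = mask)
    g <- codebookGenes(cb)
    mol <- data.frame(
        entry = c(g[1], g[1], g[2], g[3], codebookBlanks(cb)[1]),
        x = c(4, 6, 15, 10, 5), y = c(4, 5, 15, 10, 3),
        stringsAsFactors = FALSE)
    mol <- assignMolecules(mol, seg, pixelSize = 1)
    expect_equal(mol$cell_id,
                 c("cell_001", "cell_001", "cell_002", NA, "cell_001"))
    cm <- moleculesToMatrix(mol, cb)
    expect_equal(cm["cell_001", g[1]], 2L)
    expect_equal(cm["cell_002", g[2]], 1L)
    expect_equal(sum(cm), 3L)  # blank and unassigned excluded
})

test_that("sequential-round signals are summed within masks and area-normalized", {
    mask <- matrix(0L, 10, 10)
    mask[2:4, 2:4] <- 1L   # 9 px
    mask[7:9, 7:8] <- 2L   # 6 px
    img <- matrix(1, 10, 10)
    img[2:4, 2:4] <- 3
    seg <- list(mask = mask)
    q <- quantifySequential(img, seg)
    expect_equal(unname(q), c(3, 1))
    expect_named(q, c("cell_001", "cell_002"))
})
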