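# toy reference with two clusters and hand-designed genes
toyRef <- function() {
    set.seed(5)
    nA <- 10; nB <- 10
    g <- cbind(
        onA  = c(rep(5, nA), rep(0, nB)),          # on in A only
        flat = rep(3, nA + nB),                    # independent of label
        mid  = c(rbinom(nA, 1, 0.8), rbinom(nB, 1, 0.2)))
    referenceExpression(g, rep(c("A", "B"), c(nA, nB)),
                        c(A = "excitatory", B = "excitatory"))
}

test_that("mutual information matches hand-computed binary-channel values", {
    ref <- toyRef()
    top <- mutualInfoRanking(ref, "excitatory", topN = 3)
    mi <- attr(top, "mi")
    # deterministic on/off gene carries exactly 1 bit; flat gene 0 bits
    expect_equal(unname(mi["onA"]), 1)
    expect_equal(unname(mi["flat"]), 0)
    expect_identical(top[1], "onA")
})

test_that("MI of a 0.8/0.2 binary channel is 0.2781 bits", {
    # exact evaluation of I(X;Y) = H(X) - H(X|Y) at equal priors
    h <- function(p) ifelse(p %in% c(0, 1), 0,
                            -p * log2(p) - (1 - p) * log2(1 - p))
    expected <- h(0.5) - 0.5 * h(0.8) - 0.5 * h(0.2)
    expect_equal(round(expected, 4), 0.2781)
    # empirical version through the ranking on a constructed table
    n <- 500
    x <- rbind(matrix(rep(c(1, 0), c(0.8 * n, 0.2 * n))),
               matrix(rep(c(1, 0), c(0.2 * n, 0.8 * n))))
    colnames(x) <- "g"
    ref <- referenceExpression(cbind(x, other = rep(c(1, 0), n)),
                               rep(c("A", "B"), each = n),
                               c(A = "excitatory", B = "excitatory"))
    mi <- attr(mutualInfoRanking(ref, "excitatory", 2), "mi")
    expect_equal(unname(mi["g"]), expected, tolerance = 1e-12)
})

test_that("MI ranking is invariant to cell order and monotone transforms", {
    ref <- toyRef()
    mi1 <- attr(mutualInfoRanking(ref, "excitatory", 3), "mi")
    perm <- sample(nrow(ref$matrix))
    ref2 <- referenceExpression(ref$matrix[perm, ], ref$labels[perm],
                                ref$classOf)
    mi2 <- attr(mutualInfoRanking(ref2, "excitatory", 3), "mi")
    expect_equal(mi1, mi2)
    ref3 <- referenceExpression(ref$matrix^2 * 10, ref$labels, ref$classOf)
    mi3 <- attr(mutualInfoRanking(ref3, "excitatory", 3), "mi")
    expect_equal(mi1, mi3)
})

test_that("DE criteria are each enforced and individually relaxable", {
    # constructed 20-cell pair in which exactly 3 of 10 genes pass all four
    # criteria (hand-evaluated)
    set.seed(1)
    nA <- 10; nB <- 10
    mk <- function(a, b) c(a, b)
    m <- cbind(
        pass1 = mk(rep(10, nA), c(20, rep(0, 9))), # passes everything
        pass2 = mk(rep(8, nA), c(rep(1, 2), rep(0, 8))),
        pass3 = mk(c(rep(6, 9), 0), rep(0, nB)),
        lowfold = mk(rep(3, nA), rep(2, nB)),      # fold 1.5 < 2
        lowfrac = mk(c(rep(20, 3), rep(0, 7)), rep(0.5, nB)),  # frac 0.3
        lowenrich = mk(rep(4, nA), rep(1, nB)) + 0,            # ratio 1
        flat = mk(rep(5, nA), rep(5, nB)),
        noisy = mk(rpois(nA, 3), rpois(nB, 3)),
        zero = mk(rep(0, nA), rep(0, nB)),
        bgonly = mk(rep(0, nA), rep(6, nB)))
    ref <- referenceExpression(m, rep(c("A", "B"), c(nA, nB)),
                               c(A = "excitatory", B = "excitatory"))
    de <- deGenesForPair(ref, "A", "B")
    expect_setequal(de$gene, c("pass1", "pass2", "pass3"))
    expect_true(all(diff(de$p) >= 0))
    # a 1.5-fold gene is excluded regardless of other criteria
    expect_false("lowfold" %in% de$gene)
    # relaxing any single criterion can only grow the list
    for (relax in list(c(fold = 1), c(pCut = 1), c(minFrac = 0),
                       c(enrich = 0))) {
        args <- c(list(ref = ref, fg = "A", bg = "B", topN = Inf),
                  as.list(relax))
        de2 <- do.call(deGenesForPair, args)
        expect_true(all(de$gene %in% de2$gene))
    }
    expect_error(deGenesForPair(
        referenceExpression(m[c(1, 11:20), ],
                            rep(c("A", "B"), c(1, 10)),
                            c(A = "excitatory", B = "excitatory")),
        "A", "B"), "2 cells")
})

test_that("greedy cover matches the exhaustive minimum on a toy instance", {
    cand <- list(
        "A|B" = c("g1", "g2"), "B|A" = c("g3"),
        "A|C" = c("g1", "g4"), "C|A" = c("g5"),
        "B|C" = c("g2", "g6"), "C|B" = c("g5", "g7"))
    sel <- greedyMarkerCover(cand, seedPanel = character(),
                             minPerDirection = 1)
    # brute-force minimum cover (1 gene per direction)
    genes <- unique(unlist(cand))
    bestSize <- Inf
    for (k in seq_along(genes)) {
        for (s in combn(genes, k, simplify = FALSE)) {
            if (all(vapply(cand, function(cc) any(cc %in% s), logical(1)))) {
                bestSize <- min(bestSize, k)
            }
        }
        if (is.finite(bestSize)) break
    }
    expect_length(sel$final_panel, bestSize)
    expect_true(all(sel$coverage$covered >= 1))
    expect_false(any(sel$coverage$uncoverable))
})

test_that("cover honours the seed panel and flags uncoverable pairs", {
    cand <- list("A|B" = c("m1", "g1"), "B|A" = character())
    sel <- greedyMarkerCover(cand, seedPanel = c("m1"), minPerDirection = 1)
    expect_true("m1" %in% sel$final_panel)
    expect_true(sel$coverage$uncoverable[sel$coverage$pair == "B|A"])
    # all pairs already covered -> no additions
    sel2 <- greedyMarkerCover(list("A|B" = "m1", "B|A" = "m1"),
                              seedPanel = "m1", minPerDirection = 1)
    expect_length(sel2$de_selected, 0)
})

test_that("sequential screening applies both the capacity and count rules", {
    m <- cbind(longLow = rpois(20, 2), shortLow = rpois(20, 2),
               longHigh = rpois(20, 250))
    ref <- referenceExpression(m, rep(c("A", "B"), each = 10),
                               c(A = "excitatory", B = "excitatory"))
    tx <- c(longLow = strrep("A", 4000), shortLow = strrep("A", 400),
            longHigh = strrep("A", 4000))
    res <- screenForSequential(ref, colnames(m), tx)
    expect_identical(res$combinatorial, "longLow")
    expect_setequal(res$sequential, c("shortLow", "longHigh"))
    expect_error(screenForSequential(ref, c(colnames(m), "absent"), tx),
                 "missing transcript")
})

test_that("probe capacity follows floor((L-30)/10)+1 and targets stay in range", {
    tx1000 <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    ps <- designEncodingProbes(tx1000, "combinatorial", nProbes = 92,
                               barcode = c(1, 1, 0, 1, 0, 1))
    expect_equal(nrow(ps$probes), 92)   # capacity 98
    tx500 <- substr(tx1000, 1, 500)
    ps2 <- designEncodingProbes(tx500, "combinatorial", nProbes = 92,
                                barcode = c(1, 1, 0, 1, 0, 1))
    expect_equal(nrow(ps2$probes), 48)  # capacity floor(470/10)+1
    # adjacent targets overlap by at most 20 nt
    expect_true(all(diff(ps2$probes$start) >= 10))
    # targets never run past the transcript end
    expect_true(all(ps2$probes$start + 30 <= 500))
    expect_true(all(nchar(ps2$probes$target_seq) == 30))
    # L = 30 gives exactly one probe; shorter errors
    expect_equal(nrow(designEncodingProbes(strrep("A", 30), "sequential",
                                           readoutId = 7)$probes), 1)
    expect_error(designEncodingProbes(strrep("A", 29), "sequential",
                                      readoutId = 7), "shorter")
})

test_that("readout assignment is balanced over the barcode's on-bits", {
    bc <- c(1, 0, 1, 0, 1, 0, 1, 0)
    ps <- designEncodingProbes(strrep("A", 4000), "combinatorial",
                               nProbes = 92, barcode = bc)
    ids <- unlist(strsplit(ps$probes$readout_ids, ","))
    expect_true(all(ids %in% as.character(which(bc == 1))))
    counts <- table(ids)
    expect_length(counts, 4)                 # all 4 on-bits used
    expect_lte(max(counts) - min(counts), 2) # near-equal usage
    # every probe carries exactly two readouts
    expect_true(all(lengths(strsplit(ps$probes$readout_ids, ",")) == 2))
    # sequential probes carry exactly one
    ps2 <- designEncodingProbes(strrep("A", 4000), "sequential",
                                nProbes = 48, readoutId = 23)
    expect_true(all(ps2$probes$readout_ids == "23"))
})
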