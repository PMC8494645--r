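#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#' @importFrom S4Vectors metadata metadata<-
NULL

# cells x genes view of an assay
.cellsByGenes <- function(sce, assayName) t(as.matrix(assay(sce, assayName)))

.qcState <- function(sce) metadata(sce)$state

`.qcState<-` <- function(sce, value) {
    metadata(sce)$state <- value
    sce
}

.qcFlagged <- function(sce) {
    f <- colData(sce)$qc_flag
    if (is.null(f)) rep(FALSE, ncol(sce)) else f != ""
}

.addFlag <- function(sce, flag, reason) {
    f <- colData(sce)$qc_flag
    if (is.null(f)) f <- rep("", ncol(sce))
    newly <- flag & f == ""
    f[newly] <- reason
    colData(sce)$qc_flag <- f
    sce
}

#' Flag cells by imaged volume
#'
#' Flags segmentation artifacts (volume below `minVolume`) and improperly
#' separated cells (volume above `maxMultiple` times the median volume).
#' The median is computed over all input cells before any removal, and both
#' cut-offs are strict inequalities.
#'
#' @param cells data.frame (or `colData`) with a `volume` column, or a
#'   `SingleCellExperiment`.
#' @param minVolume minimum volume in cubic microns.
#' @param maxMultiple multiple of the median volume defining the upper cut.
#' @return Logical vector of flagged cells.
#' @export
filterByVolume <- function(cells, minVolume = 100, maxMultiple = 3) {
    v <- if (methods::is(cells, "SummarizedExperiment"))
        colData(cells)$volume else cells$volume
    med <- stats::median(v)
    v < minVolume | v > maxMultiple * med
}

#' Normalize counts by imaged cell volume
#'
#' Divides each cell's counts by its volume, removing differences caused by
#' incomplete soma capture within the slice. Stores the result in the
#' `normcounts` assay and advances the matrix state to `volume_normalized`.
#'
#' @param sce a `SingleCellExperiment` in `raw` state with colData `volume`.
#' @return The updated object.
#' @export
normalizeByVolume <- function(sce) {
    if (!identical(.qcState(sce), "raw"))
        stop("normalizeByVolume expects a raw-state matrix")
    v <- colData(sce)$volume
    if (any(v <= 0)) stop("non-positive cell volume")
    assay(sce, "normcounts") <- sweep(as.matrix(assay(sce, "counts")), 2, v, "/")
    .qcState(sce) <- "volume_normalized"
    sce
}

#' Normalize batch mean total counts to a common target
#'
#' Scales every cell in a batch by one scalar so that the batch's mean
#' total counts per cell equals `targetMean` (250 by default), removing
#' between-experiment differences in overall detection efficiency while
#' leaving within-batch relative expression untouched. Scalars are computed
#' on unflagged cells but applied to all.
#'
#' @param sce a `SingleCellExperiment` in `volume_normalized` state with
#'   colData `batch_id`.
#' @param targetMean target mean total counts per cell.
#' @return The updated object (`batch_normalized` state).
#' @export
batchNormalize <- function(sce, targetMean = 250) {
    if (!identical(.qcState(sce), "volume_normalized"))
        stop("batchNormalize expects a volume_normalized matrix")
    m <- as.matrix(assay(sce, "normcounts"))
    batch <- colData(sce)$batch_id
    use <- !.qcFlagged(sce)
    for (b in unique(batch)) {
        inB <- batch == b
        if (!any(inB & use)) stop("batch with no usable cells: ", b)
        sc <- targetMean / mean(colSums(m[, inB & use, drop = FALSE]))
        m[, inB] <- m[, inB] * sc
    }
    assay(sce, "normcounts") <- m
    .qcState(sce) <- "batch_normalized"
    sce
}

#' Flag broad-spectrum sequential-channel artifacts
#'
#' Sequential-round channels carry mutually exclusive marker genes, so no
#' real cell should light up in most of them; a cell above the per-channel
#' `quantile` threshold in at least `minChannels` channels is flagged as
#' spurious fluorescent background.
#'
#' @param signals cells x channels numeric matrix.
#' @param quantile per-channel quantile defining "high" (default 0.90).
#' @param minChannels number of high channels required to flag.
#' @param totalChannels expected channel count (checked).
#' @return Logical vector of flagged cells.
#' @export
sequentialArtifactFilter <- function(signals, quantile = 0.90,
                                     minChannels = 12,
                                     totalChannels = ncol(signals)) {
    if (ncol(signals) != totalChannels)
        stop("channel count does not match totalChannels")
    thr <- apply(signals, 2, stats::quantile, probs = quantile)
    high <- sweep(signals, 2, thr, ">")
    rowSums(high) >= minChannels
}

#' Subtract per-cell channel-group background
#'
#' For each cell and each channel group (e.g. the 650-nm and 750-nm dye
#' channels), subtracts that cell's minimum signal across the group's
#' channels, clipping at zero.
#'
#' @param signals cells x channels numeric matrix.
#' @param channelGroups list of channel index (or name) vectors; every
#'   channel must belong to exactly one group.
#' @return The background-subtracted matrix.
#' @export
subtractChannelBackground <- function(signals, channelGroups) {
    idx <- unlist(lapply(channelGroups, function(g)
        if (is.character(g)) match(g, colnames(signals)) else g))
    if (anyNA(idx) || length(idx) != ncol(signals) || anyDuplicated(idx))
        stop("each channel must be assigned to exactly one group")
    out <- signals
    for (g in channelGroups) {
        cols <- if (is.character(g)) match(g, colnames(signals)) else g
        bg <- apply(signals[, cols, drop = FALSE], 1, min)
        out[, cols] <- pmax(sweep(signals[, cols, drop = FALSE], 1, bg), 0)
    }
    out
}

#' Flag cells with extreme total counts
#'
#' Flags cells whose total counts fall strictly below the `low` quantile or
#' strictly above the `high` quantile of the totals (linear-interpolation
#' quantiles), computed over unflagged cells.
#'
#' @param sce a `SingleCellExperiment` (uses `normcounts` if present, else
#'   `counts`) or a cells x genes matrix.
#' @param low,high quantile bounds (defaults 0.02 and 0.98).
#' @return Logical vector of flagged cells.
#' @export
quantileCountFilter <- function(sce, low = 0.02, high = 0.98) {
    stopifnot(low >= 0, high <= 1, low < high)
    if (methods::is(sce, "SummarizedExperiment")) {
        a <- if ("normcounts" %in% assayNames(sce)) "normcounts" else "counts"
        tot <- colSums(as.matrix(assay(sce, a)))
        use <- !.qcFlagged(sce)
    } else {
        tot <- rowSums(sce)
        use <- rep(TRUE, length(tot))
    }
    q <- stats::quantile(tot[use], c(low, high))
    tot < q[1] | tot > q[2]
}

#' Simulated-doublet scores
#'
#' Re-implements simulated-doublet nearest-neighbour scoring: artificial
#' doublets are synthesized as sums of random observed cell pairs, observed
#' and simulated cells are embedded together by principal components of the
#' total-normalized log counts, and each observed cell is scored from the
#' fraction of simulated doublets among its nearest neighbours, corrected
#' for the simulated/observed ratio `r` and the expected doublet prior
#' `rho`: with `q` the simulated-neighbour fraction, the score is
#' `q*rho/r / (q*rho/r + (1-q)*(1-rho))`, a posterior doublet probability
#' bounded in \[0, 1\].
#'
#' @param x cells x genes count matrix (volume/batch normalized counts are
#'   fine), or a `SingleCellExperiment` (uses `normcounts` else `counts`).
#' @param expectedRate prior doublet rate `rho`.
#' @param k neighbours per cell before ratio adjustment. The default is
#'   deliberately small: a doublet's evidence is the local excess of
#'   simulated doublets around it, and wide neighbourhoods dilute that
#'   signal with cells from the nearest singlet clusters.
#' @param simRatio simulated doublets per observed cell (the
#'   amplification factor).
#' @param nPcs principal components for the embedding.
#' @param seed integer seed (pair sampling is the only randomness).
#' @return Numeric vector of per-cell scores in \[0, 1\].
#' @export
doubletScores <- function(x, expectedRate = 0.12, k = 6, simRatio = 4,
                          nPcs = 30, seed = 1) {
    if (methods::is(x, "SummarizedExperiment")) {
        a <- if ("normcounts" %in% assayNames(x)) "normcounts" else "counts"
        x <- .cellsByGenes(x, a)
    }
    n <- nrow(x)
    if (n < 2) stop("need at least 2 cells")
    if (is.null(k)) k <- max(5L, round(0.5 * sqrt(n)))
    withSeed(seed, {
        nSim <- round(simRatio * n)
        i <- sample(n, nSim, replace = TRUE)
        j <- sample(n, nSim, replace = TRUE)
        comb <- rbind(x, x[i, , drop = FALSE] + x[j, , drop = FALSE])
        tot <- rowSums(comb)
        tot[tot == 0] <- 1
        l <- log1p(comb / tot * stats::median(tot))
        emb <- .pca(.zscore(l), npc = min(nPcs, ncol(l)))$scores
        kAdj <- round(k * (1 + simRatio))
        idx <- .knnIndex(emb, kAdj)[seq_len(n), , drop = FALSE]
        q <- rowMeans(idx > n)
        r <- nSim / n
        num <- q * expectedRate / r
        num / (num + (1 - q) * (1 - expectedRate))
    })
}

#' Flag cells above the doublet-score threshold
#'
#' @param scores per-cell scores from [doubletScores()].
#' @param threshold removal threshold on the normalized score scale
#'   (default 0.18).
#' @return Logical vector of flagged cells.
#' @export
removeDoublets <- function(scores, threshold = 0.18) {
    scores > threshold
}

#' Run the full QC cascade
#'
#' Applies, in order: (1) the volume filter, (2) volume normalization,
#' (3) batch normalization, (4) the sequential-channel artifact filter
#' (over the sequential-mode genes), (5) per-cell channel-group background
#' subtraction of the sequential signals, (6) the total-count quantile
#' filter, (7) simulated-doublet scoring and removal, and (8) removal of
#' configured low-quality genes. Flags accumulate in colData `qc_flag`
#' (first failing stage wins) and a per-stage report is stored in
#' `metadata()$qcReport`.
#'
#' @param sce a raw-state `SingleCellExperiment`.
#' @param minVolume,maxMultiple volume-filter parameters.
#' @param targetMean batch-normalization target.
#' @param sequentialGenes genes measured in sequential rounds (default
#'   from the generator config when present, else none).
#' @param artifactQuantile,artifactMinFrac sequential-artifact parameters;
#'   a cell is flagged when high in at least
#'   `round(artifactMinFrac * channels)` channels (12/16 in the reference
#'   configuration).
#' @param channelGroups list splitting the sequential channels into dye
#'   groups for background subtraction (default: alternating two groups).
#' @param lowQuantile,highQuantile total-count quantile bounds.
#' @param doubletThreshold doublet-score removal threshold.
#' @param expectedDoubletRate prior for [doubletScores()].
#' @param dropGenes genes removed from the matrix after QC.
#' @param seed integer seed for doublet simulation.
#' @return The processed object; unflagged cells are QC-passed.
#' @export
runQC <- function(sce, minVolume = 100, maxMultiple = 3, targetMean = 250,
                  sequentialGenes = NULL,
                  artifactQuantile = 0.90, artifactMinFrac = 12 / 16,
                  channelGroups = NULL,
                  lowQuantile = 0.02, highQuantile = 0.98,
                  doubletThreshold = 0.18, expectedDoubletRate = 0.12,
                  dropGenes = character(), seed = 1) {
    if (is.null(sequentialGenes)) {
        cfg <- metadata(sce)$config
        sequentialGenes <- intersect(
            if (!is.null(cfg)) cfg$sequentialGenes else character(),
            rownames(sce))
    }
    report <- list()
    note <- function(stage, flag, thr) {
        data.frame(stage = stage, n_flagged = sum(flag),
                   fraction = sum(flag) / ncol(sce), threshold = thr,
                   stringsAsFactors = FALSE)
    }

    f <- filterByVolume(sce, minVolume, maxMultiple)
    newly <- f & !.qcFlagged(sce)
    sce <- .addFlag(sce, f, "volume")
    report$volume <- note("volume", newly,
                          sprintf("<%g or >%gx median", minVolume, maxMultiple))

    sce <- normalizeByVolume(sce)
    sce <- batchNormalize(sce, targetMean)

    if (length(sequentialGenes) >= 2) {
        sig <- .cellsByGenes(sce, "normcounts")[, sequentialGenes, drop = FALSE]
        minCh <- max(1L, round(artifactMinFrac * ncol(sig)))
        f <- sequentialArtifactFilter(sig, artifactQuantile, minCh)
        newly <- f & !.qcFlagged(sce)
        sce <- .addFlag(sce, f, "sequential_artifact")
        report$seq <- note("sequential_artifact", newly,
                           sprintf(">q%.2f in >=%d/%d channels",
                                   artifactQuantile, minCh, ncol(sig)))
        if (is.null(channelGroups))
            channelGroups <- split(seq_len(ncol(sig)),
                                   rep_len(1:2, ncol(sig)))
        m <- as.matrix(assay(sce, "normcounts"))
        m[sequentialGenes, ] <- t(subtractChannelBackground(sig, channelGroups))
        assay(sce, "normcounts") <- m
    }

    f <- quantileCountFilter(sce, lowQuantile, highQuantile)
    newly <- f & !.qcFlagged(sce)
    sce <- .addFlag(sce, f, "count_quantile")
    report$quant <- note("count_quantile", newly,
                         sprintf("q%.2f-q%.2f totals", lowQuantile,
                                 highQuantile))

    use <- !.qcFlagged(sce)
    scores <- doubletScores(.cellsByGenes(sce, "normcounts")[use, , drop = FALSE],
                            expectedRate = expectedDoubletRate, seed = seed)
    full <- rep(0, ncol(sce))
    full[use] <- scores
    colData(sce)$doublet_score <- full
    f <- rep(FALSE, ncol(sce))
    f[use] <- removeDoublets(scores, doubletThreshold)
    newly <- f & !.qcFlagged(sce)
    sce <- .addFlag(sce, f, "doublet")
    report$doublet <- note("doublet", newly,
                           sprintf("score > %g", doubletThreshold))

    if (length(dropGenes))
        sce <- sce[setdiff(rownames(sce), dropGenes), ]
    metadata(sce)$qcReport <- do.call(rbind, unname(report))
    sce
}

#' Per-stage QC report
#'
#' @param sce an object processed by [runQC()].
#' @return data.frame of per-stage flagged counts and fractions.
#' @export
qcReport <- function(sce) metadata(sce)$qcReport
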