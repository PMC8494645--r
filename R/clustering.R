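#' Median-total scaling, log transform and per-gene z-scoring
#'
#' Scales each QC-passed cell's normalized counts to the global median
#' total, applies `log(1 + x)` and z-scores each gene (zero-variance genes
#' map to 0). The result is stored in the `logz` assay.
#'
#' @param sce a `SingleCellExperiment` in `batch_normalized` state.
#' @return The updated object (`log_z` state).
#' @export
logZNormalize <- function(sce) {
    if (!identical(.qcState(sce), "batch_normalized"))
        stop("logZNormalize expects a batch_normalized matrix")
    m <- .cellsByGenes(sce, "normcounts")
    tot <- rowSums(m)
    tot[tot == 0] <- 1
    m <- m / tot * stats::median(tot)
    z <- .zscore(log1p(m))
    assay(sce, "logz") <- t(z)
    .qcState(sce) <- "log_z"
    sce
}

#' Shuffle-calibrated principal-component count
#'
#' Independently permutes each gene column of the matrix, records the
#' first eigenvalue of the shuffled covariance, repeats `nShuffles` times,
#' and returns the number of real principal components whose eigenvalue
#' exceeds the mean shuffled first eigenvalue.
#'
#' @param x cells x genes matrix (log-z normalized).
#' @param nShuffles number of column shuffles (default 20).
#' @param seed integer seed.
#' @return Integer count of retained components (possibly 0).
#' @export
selectNPcsShuffle <- function(x, nShuffles = 20, seed = 1) {
    vals <- .pca(x)$values
    null1 <- withSeed(seed, vapply(seq_len(nShuffles), function(i) {
        xs <- apply(x, 2, sample)
        .topEigenvalue(xs)
    }, numeric(1)))
    sum(vals > mean(null1))
}

# Louvain communities on a kNN graph of a PC embedding
.louvain <- function(emb, k, resolution, seed) {
    g <- .knnGraph(emb, k)
    cl <- withSeed(seed, igraph::cluster_louvain(g, resolution = resolution))
    factor(igraph::membership(cl))
}

#' Graph-based clustering in principal-component space
#'
#' Builds a k-nearest-neighbour graph on the first `nPcs` principal
#' components and runs Louvain community detection at the requested
#' resolution. Deterministic given the seed.
#'
#' @param x cells x genes matrix (log-z normalized).
#' @param nPcs number of principal components (>= 1).
#' @param k neighbours per cell.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @return Factor of cluster labels (one per row of `x`).
#' @export
graphCluster <- function(x, nPcs, k = 10, resolution = 1, seed = 1) {
    stopifnot(nPcs >= 1)
    if (k >= nrow(x)) stop("k must be smaller than the number of cells")
    emb <- .pca(x, npc = nPcs)$scores
    .louvain(emb, k, resolution, seed)
}

#' Bootstrap co-clustering stability
#'
#' Reclusters random cell subsamples and, for each reference cluster,
#' measures how often pairs of its cells stay together: the mean over
#' bootstraps of \eqn{\sum_j C(n_{cj},2) / C(n_c,2)} where \eqn{n_{cj}}
#' counts the cluster's subsampled cells landing in bootstrap cluster j.
#'
#' @param x cells x genes matrix.
#' @param nPcs,k,resolution clustering parameters (see [graphCluster()]).
#' @param nBoot number of bootstrap subsamples (>= 2).
#' @param subsample fraction of cells per subsample.
#' @param seed integer seed.
#' @return Named numeric vector of per-cluster stability scores in
#'   \[0, 1\]; clusters below a chosen threshold are candidates for
#'   merging.
#' @export
bootstrapStability <- function(x, nPcs, k = 10, resolution = 1,
                               nBoot = 10, subsample = 0.8, seed = 1) {
    stopifnot(nBoot >= 2)
    ref <- graphCluster(x, nPcs, k, resolution, seed)
    boots <- withSeed(seed + 1L, lapply(seq_len(nBoot), function(b) {
        idx <- sample(nrow(x), round(subsample * nrow(x)))
        list(idx = idx,
             lab = graphCluster(x[idx, , drop = FALSE], nPcs,
                                min(k, length(idx) - 1), resolution,
                                seed + b))
    }))
    scores <- vapply(levels(ref), function(cl) {
        per <- vapply(boots, function(bt) {
            inCl <- which(ref[bt$idx] == cl)
            nc <- length(inCl)
            if (nc < 2) return(NA_real_)
            tab <- table(bt$lab[inCl])
            sum(choose(tab, 2)) / choose(nc, 2)
        }, numeric(1))
        mean(per, na.rm = TRUE)
    }, numeric(1))
    scores
}

# mean z-score of a marker set within each cluster
.clusterMarkerScore <- function(z, labels, markers) {
    markers <- intersect(markers, colnames(z))
    if (length(markers) == 0) return(rep(-Inf, nlevels(labels)))
    vapply(levels(labels), function(cl)
        mean(z[labels == cl, markers, drop = FALSE]), numeric(1))
}

# per-cluster max over single-gene marker scores
.maxMarkerScore <- function(z, labels, genes) {
    m <- vapply(genes, function(g) .clusterMarkerScore(z, labels, g),
                numeric(nlevels(labels)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nlevels(labels))
    apply(m, 1, max)
}

# route round-1 clusters to the five groups by marker rules; clusters
# co-expressing incompatible class markers are flagged as doublet clusters
.routeClusters <- function(z, labels, rules, threshold = 0.5) {
    excS <- .clusterMarkerScore(z, labels, rules$class$excitatory)
    inhS <- .maxMarkerScore(z, labels, rules$class$inhibitory)
    nnMarkers <- unlist(rules$subclass[c("Astro", "Oligo", "OPC", "Micro",
                                         "PVM", "Endo", "VLMC", "Peri",
                                         "SMC")])
    nnS <- .maxMarkerScore(z, labels, nnMarkers)
    itS <- .clusterMarkerScore(z, labels, rules$it)
    cgeS <- .maxMarkerScore(z, labels, rules$cge)
    mgeS <- .maxMarkerScore(z, labels, rules$mge)

    isExc <- excS > threshold
    isInh <- inhS > threshold
    isNN <- nnS > threshold
    doubletCl <- (isExc + isInh + isNN) >= 2
    grp <- ifelse(doubletCl, "doublet",
           ifelse(isExc, ifelse(itS > threshold, "IT", "nonIT"),
           ifelse(isInh, ifelse(cgeS >= mgeS, "CGE", "MGE"), "NN")))
    stats::setNames(grp, levels(labels))
}

# assign a subclass to each final cluster by its best marker score within
# the group's candidate subclasses
.assignSubclass <- function(z, labels, group, rules, taxByGroup) {
    cand <- taxByGroup[[group]]
    sc <- vapply(cand, function(s) {
        .clusterMarkerScore(z, labels, rules$subclass[[s]])
    }, numeric(nlevels(labels)))
    if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
    cand[max.col(sc, ties.method = "first")]
}

.groupSubclasses <- list(
    IT = c("L2/3 IT", "L4/5 IT", "L5 IT", "L6 IT", "L6 IT Car3"),
    nonIT = c("L5 ET", "L5/6 NP", "L6 CT", "L6b"),
    CGE = c("Lamp5", "Sncg", "Vip"),
    MGE = c("Sst", "Pvalb"),
    NN = c("Astro", "Oligo", "OPC", "Micro", "PVM", "Endo", "VLMC",
           "Peri", "SMC"))

.groupClass <- c(IT = "excitatory", nonIT = "excitatory",
                 CGE = "inhibitory", MGE = "inhibitory",
                 NN = "non-neuronal")

#' Two-round graph clustering with marker routing
#'
#' Round 1 clusters all QC-passed cells (k = 10, resolution 1, PCs chosen
#' by the shuffle criterion) and routes each round-1 cluster to one of five
#' groups by its marker expression: IT neurons (Slc17a7 and the pan-IT
#' marker Slc30a3), non-IT excitatory neurons (Slc17a7 without Slc30a3),
#' CGE-derived (Gad1/Gad2 with Lamp5/Sncg/Vip) and MGE-derived (Gad1/Gad2
#' with Sst/Pvalb) inhibitory neurons, and non-neuronal cells. Clusters
#' co-expressing incompatible class markers (e.g. Slc17a7 together with
#' Sox10) are flagged as doublet clusters and removed. Round 2 re-z-scores
#' and re-clusters each group separately with group-specific parameters
#' (k = 40, r = 2 for both excitatory groups; k = 15, r = 2 for both
#' inhibitory groups; k = 20, r = 1 for non-neuronal cells), applies the
#' doublet-cluster rule again at the subclass-marker level, assigns each
#' final cluster a subclass by its best marker score, and names clusters
#' "<subclass> <index>".
#'
#' @param sce a `SingleCellExperiment` in `log_z` state (see
#'   [logZNormalize()]); only QC-passed cells are clustered.
#' @param rules marker dictionary (defaults to the package's rules).
#' @param round2Params named list of `c(k, r)` per group.
#' @param routeThreshold cluster-mean z threshold for marker routing.
#' @param maxPcs cap on shuffle-selected PCs.
#' @param seed integer seed.
#' @return The object with colData columns `group`, `cluster`, `subclass`,
#'   `class` (NA for flagged/unrouted cells) and metadata
#'   `clusterTaxonomy` (cluster -> subclass -> class table).
#' @export
twoRoundCluster <- function(sce, rules = .markerRules(),
                            round2Params = list(
                                IT = c(k = 40, r = 2),
                                nonIT = c(k = 40, r = 2),
                                CGE = c(k = 15, r = 2),
                                MGE = c(k = 15, r = 2),
                                NN = c(k = 20, r = 1)),
                            routeThreshold = 0.5, maxPcs = 60, seed = 1) {
    if (!identical(.qcState(sce), "log_z"))
        stop("twoRoundCluster expects a log_z matrix; run logZNormalize()")
    use <- !.qcFlagged(sce)
    z <- .cellsByGenes(sce, "logz")[use, , drop = FALSE]

    npc1 <- min(max(2L, selectNPcsShuffle(z, seed = seed)), maxPcs)
    lab1 <- graphCluster(z, npc1, k = 10, resolution = 1, seed = seed)
    route <- .routeClusters(z, lab1, rules, routeThreshold)
    cellGroup <- unname(route[as.character(lab1)])

    cluster <- rep(NA_character_, nrow(z))
    subclass <- rep(NA_character_, nrow(z))
    for (grp in names(round2Params)) {
        inG <- which(cellGroup == grp)
        if (length(inG) == 0) next
        zg <- .zscore(z[inG, , drop = FALSE])
        p <- round2Params[[grp]]
        npc <- min(max(2L, selectNPcsShuffle(zg, seed = seed + 1L)), maxPcs)
        kg <- min(p[["k"]], length(inG) - 1)
        lab2 <- .louvain(.pca(zg, npc)$scores, kg, p[["r"]], seed)
        # doublet-cluster screen within the group, on full-data z-scores
        zIn <- z[inG, , drop = FALSE]
        excS <- .clusterMarkerScore(zIn, lab2, rules$class$excitatory)
        inhS <- .clusterMarkerScore(zIn, lab2, rules$class$inhibitory)
        nnS <- .clusterMarkerScore(zIn, lab2, unlist(
            rules$subclass[.groupSubclasses$NN]))
        bad <- switch(grp,
            IT = , nonIT = inhS > routeThreshold | nnS > routeThreshold,
            CGE = , MGE = excS > routeThreshold | nnS > routeThreshold,
            NN = excS > routeThreshold | inhS > routeThreshold)
        sub2 <- .assignSubclass(zIn, lab2, grp, rules, .groupSubclasses)
        lab2chr <- as.character(lab2)
        keep <- !(bad[lab2chr])
        cluster[inG[keep]] <- paste(grp, lab2chr[keep])
        subclass[inG[keep]] <- sub2[match(lab2chr, levels(lab2))][keep]
    }

    # name clusters "<subclass> <index>", indices ordered by cluster size
    named <- rep(NA_character_, length(cluster))
    for (s in unique(stats::na.omit(subclass))) {
        inS <- !is.na(subclass) & subclass == s
        sizes <- sort(table(cluster[inS]), decreasing = TRUE)
        idx <- stats::setNames(seq_along(sizes), names(sizes))
        named[inS] <- sprintf("%s %d", s, idx[cluster[inS]])
    }

    grpFull <- clFull <- scFull <- rep(NA_character_, ncol(sce))
    grpFull[use] <- ifelse(cellGroup == "doublet", NA, cellGroup)
    clFull[use] <- named
    scFull[use] <- subclass
    colData(sce)$group <- grpFull
    colData(sce)$cluster <- clFull
    colData(sce)$subclass <- scFull
    colData(sce)$class <- unname(.groupClass[grpFull])
    tab <- unique(data.frame(
        cluster = clFull, subclass = scFull,
        class = unname(.groupClass[grpFull]),
        stringsAsFactors = FALSE))
    metadata(sce)$clusterTaxonomy <- tab[!is.na(tab$cluster), ]
    sce
}

#' Transfer cluster labels with a multinomial classifier
#'
#' Trains a multinomial maximum-entropy classifier (on the principal
#' components of the z-scored training profiles; `method = "nnet"` fits a
#' single-hidden-layer network instead) and predicts a label plus a
#' confidence (maximum class probability) for each test cell. Train and
#' test matrices are matched on their gene intersection, and test profiles
#' are z-scored with the training statistics.
#'
#' @param trainMat cells x genes matrix (counts or normalized counts).
#' @param trainLabels per-cell labels.
#' @param testMat cells x genes matrix.
#' @param nPcs principal components used as features.
#' @param method `"multinom"` (default) or `"nnet"`.
#' @param hidden hidden units for `method = "nnet"`.
#' @param seed integer seed (weight initialization).
#' @return data.frame with `label` and `confidence` per test cell.
#' @export
labelTransfer <- function(trainMat, trainLabels, testMat, nPcs = 50,
                          method = c("multinom", "nnet"), hidden = 32,
                          seed = 1) {
    method <- match.arg(method)
    genes <- intersect(colnames(trainMat), colnames(testMat))
    if (length(genes) == 0) stop("empty gene intersection")
    tr <- as.matrix(trainMat[, genes, drop = FALSE])
    te <- as.matrix(testMat[, genes, drop = FALSE])
    if (min(tr) >= 0 && min(te) >= 0) {  # counts: log before z-scoring
        tr <- log1p(tr)
        te <- log1p(te)
    }
    mu <- colMeans(tr)
    sd <- apply(tr, 2, stats::sd)
    sd[sd == 0] <- 1
    tr <- sweep(sweep(tr, 2, mu), 2, sd, "/")
    te <- sweep(sweep(te, 2, mu), 2, sd, "/")

    ctr <- colMeans(tr)
    trc <- sweep(tr, 2, ctr)
    rot <- eigen(crossprod(trc) / (nrow(trc) - 1),
                 symmetric = TRUE)$vectors[, seq_len(min(nPcs, length(genes))),
                                           drop = FALSE]
    trP <- trc %*% rot
    teP <- sweep(te, 2, ctr) %*% rot
    y <- factor(trainLabels)
    fit <- withSeed(seed, {
        if (method == "multinom")
            nnet::multinom(y ~ ., data = data.frame(trP),
                           MaxNWts = 1e6, maxit = 300, trace = FALSE)
        else
            nnet::nnet(trP, nnet::class.ind(y), size = hidden,
                       softmax = TRUE, MaxNWts = 1e6, maxit = 300,
                       trace = FALSE)
    })
    probs <- if (method == "multinom")
        stats::predict(fit, newdata = data.frame(teP), type = "probs")
    else stats::predict(fit, teP)
    if (is.null(dim(probs)))  # two-class multinom returns a vector
        probs <- cbind(1 - probs, probs, deparse.level = 0)
    if (is.null(colnames(probs))) colnames(probs) <- levels(y)
    data.frame(
        label = colnames(probs)[max.col(probs, ties.method = "first")],
        confidence = apply(probs, 1, max),
        stringsAsFactors = FALSE)
}
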