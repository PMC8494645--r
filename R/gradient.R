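#' Genes varying along cortical depth
#'
#' Cells are split into `nBins` equal-count bins by normalized depth and
#' each gene's binned mean z-scored expression profile is computed. Genes
#' whose profile range (max - min) exceeds `minRange` are selected and
#' ordered by the depth bin at which a rolling average of the profile
#' (window `window` bins) peaks.
#'
#' @param x cells x genes matrix of z-scored expression.
#' @param depths per-cell normalized depths.
#' @param nBins number of equal-count depth bins (default 50).
#' @param minRange minimum profile range for selection (default 0.5).
#' @param window rolling-average window in bins (default 10).
#' @return data.frame (ordered by peak depth) with `gene`, `range`,
#'   `peak_bin` and `peak_depth` (mean depth of the peak window).
#' @export
depthDeGenes <- function(x, depths, nBins = 50, minRange = 0.5,
                         window = 10) {
    if (nrow(x) < nBins) stop("fewer cells than depth bins")
    bin <- ceiling(rank(depths, ties.method = "first") / length(depths) *
                   nBins)
    prof <- apply(x, 2, function(g) tapply(g, bin, mean))
    rng <- apply(prof, 2, function(p) max(p) - min(p))
    sel <- names(rng)[rng > minRange]
    if (length(sel) == 0)
        return(data.frame(gene = character(), range = numeric(),
                          peak_bin = integer(), peak_depth = numeric()))
    binDepth <- tapply(depths, bin, mean)
    roll <- function(p) {
        r <- stats::filter(p, rep(1 / window, window), sides = 2)
        which.max(as.numeric(r))
    }
    peak <- vapply(sel, function(g) roll(prof[, g]), integer(1))
    out <- data.frame(gene = sel, range = rng[sel], peak_bin = peak,
                      peak_depth = as.numeric(binDepth[as.character(peak)]),
                      stringsAsFactors = FALSE)
    out[order(out$peak_bin, out$gene), , drop = FALSE]
}

#' Chance-normalized inter-cluster kNN connectivity
#'
#' Builds a k-nearest-neighbour graph in principal-component space and
#' measures, for each cluster pair, the observed number of edges between
#' them divided by the number expected if edge endpoints were placed at
#' random in proportion to cluster sizes:
#' \eqn{E_{ab} = m \cdot 2 n_a n_b / (n(n-1))} for \eqn{a \neq b}, where m
#' is the total edge count. Values near 1 indicate chance-level mixing,
#' values near 0 well-separated clusters.
#'
#' @param x cells x genes matrix (z-scored expression).
#' @param labels per-cell cluster labels.
#' @param nPcs principal components (default 19; NULL selects by the
#'   shuffle criterion).
#' @param k neighbours per cell (default 12).
#' @param seed seed for the shuffle criterion when `nPcs` is NULL.
#' @return A list of class `ConnectivityGraph`: `weights` (symmetric
#'   cluster x cluster matrix, diagonal NA), `sizes`, and `params`. Edges
#'   below a display threshold are conventionally hidden in plots but all
#'   weights are retained here.
#' @export
clusterConnectivity <- function(x, labels, nPcs = 19, k = 12, seed = 1) {
    labels <- factor(labels)
    if (nlevels(labels) < 2) stop("need at least 2 clusters")
    if (any(table(labels) < 2)) warning("singleton-prone cluster present")
    if (is.null(nPcs)) nPcs <- max(2L, selectNPcsShuffle(x, seed = seed))
    emb <- .pca(x, npc = nPcs)$scores
    g <- .knnGraph(emb, k)
    el <- igraph::as_edgelist(g, names = FALSE)
    n <- nrow(x)
    m <- nrow(el)
    li <- as.integer(labels)
    nl <- nlevels(labels)
    obs <- matrix(0, nl, nl, dimnames = list(levels(labels), levels(labels)))
    for (e in seq_len(m)) {
        a <- li[el[e, 1]]; b <- li[el[e, 2]]
        obs[a, b] <- obs[a, b] + 1
        if (a != b) obs[b, a] <- obs[b, a] + 1
    }
    sz <- as.numeric(table(labels))
    expd <- m * 2 * outer(sz, sz) / (n * (n - 1))
    w <- obs / expd
    diag(w) <- NA
    structure(list(weights = w, sizes = stats::setNames(sz, levels(labels)),
                   params = list(nPcs = nPcs, k = k)),
              class = "ConnectivityGraph")
}

#' Diffusion pseudotime from a root cluster
#'
#' Builds a diffusion map from the kNN graph of the principal-component
#' embedding (eigendecomposition of the symmetrically normalized adjacency)
#' and assigns each cell a pseudotime equal to its diffusion distance from
#' a root cell, chosen as the member of `rootCluster` closest to that
#' cluster's PC-space centroid. The root's pseudotime is 0. When depths are
#' supplied the Spearman correlation between pseudotime and depth is
#' reported.
#'
#' @param x cells x genes matrix (z-scored expression).
#' @param labels per-cell cluster labels.
#' @param rootCluster name of the root cluster (e.g. the most superficial
#'   L2/3 IT cluster).
#' @param nPcs principal components (NULL selects by the shuffle
#'   criterion).
#' @param k neighbours per cell (default 12).
#' @param nComps diffusion components used for the distance.
#' @param excludeClusters clusters dropped before the analysis (e.g. a
#'   well-separated discrete outgroup).
#' @param depths optional per-cell normalized depths (for the
#'   correlation), aligned with `x` before exclusion.
#' @param seed integer seed (root tie-break and shuffle criterion).
#' @return A list of class `PseudotimeResult`: `pseudotime` (NA for
#'   excluded cells), `root` (index into `x`), `cor_depth` (Spearman, or
#'   NA), `included` (logical).
#' @export
diffusionPseudotime <- function(x, labels, rootCluster, nPcs = NULL, k = 12,
                                nComps = 10, excludeClusters = character(),
                                depths = NULL, seed = 1) {
    labels <- as.character(labels)
    keep <- !(labels %in% excludeClusters) & !is.na(labels)
    xi <- x[keep, , drop = FALSE]
    li <- labels[keep]
    if (!any(li == rootCluster)) stop("root cluster is empty")
    if (is.null(nPcs)) nPcs <- max(2L, selectNPcsShuffle(xi, seed = seed))
    emb <- .pca(xi, npc = nPcs)$scores
    g <- .knnGraph(emb, k)
    comp <- igraph::components(g)
    if (comp$no > 1)
        stop(sprintf("kNN graph is disconnected (%d components of sizes %s)",
                     comp$no, paste(comp$csize, collapse = ", ")))
    A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    deg <- Matrix::rowSums(A)
    Dm <- Matrix::Diagonal(x = 1 / sqrt(deg))
    N <- Dm %*% A %*% Dm
    # shift to PSD so truncated SVD returns the top of the spectrum
    M <- (N + Matrix::Diagonal(nrow(N))) / 2
    sv <- irlba::irlba(M, nv = nComps + 1, tol = 1e-7)
    lam <- 2 * sv$d - 1                      # eigenvalues of N, descending
    phi <- sv$u
    psi <- as.matrix(Dm %*% phi)             # right eigenvectors of P
    comps <- 2:(nComps + 1)                  # drop the stationary component
    scale <- lam[comps] / (1 - pmin(lam[comps], 1 - 1e-12))
    dmap <- sweep(psi[, comps, drop = FALSE], 2, scale, "*")

    ctr <- colMeans(emb[li == rootCluster, , drop = FALSE])
    dd <- rowSums(sweep(emb, 2, ctr)^2)
    dd[li != rootCluster] <- Inf
    root <- withSeed(seed, {
        cand <- which(dd == min(dd))
        if (length(cand) > 1) sample(cand, 1) else cand
    })
    pt <- sqrt(rowSums(sweep(dmap, 2, dmap[root, ])^2))

    ptFull <- rep(NA_real_, nrow(x))
    ptFull[keep] <- pt
    corDepth <- if (!is.null(depths))
        stats::cor(pt, depths[keep], method = "spearman",
                   use = "complete.obs") else NA_real_
    structure(list(pseudotime = ptFull, root = which(keep)[root],
                   cor_depth = corDepth, included = keep),
              class = "PseudotimeResult")
}
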