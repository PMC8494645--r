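#' Fit cortical surfaces and normalized soma depths
#'
#' Per slice, a quadratic surface curve is fitted through the centroids of
#' VLMC cells (the vascular leptomeningeal cells forming the outermost
#' cortical cell layer); each cell's soma depth is the shortest distance
#' from its centroid to that curve, and depths are normalized by the
#' slice's cortical thickness, defined as the median soma depth of its L6b
#' cells (surface = 0, median L6b depth = 1). Slices lacking VLMC or L6b
#' cells are excluded with a warning (their cells receive NA depth).
#'
#' @param cells data.frame with `x`, `y` (microns) and `slice_id`, or a
#'   `SingleCellExperiment` whose colData has those columns.
#' @param subclass per-cell subclass labels (`"VLMC"` and `"L6b"` are the
#'   anchors).
#' @param degree polynomial degree of the surface fit.
#' @param gridN resolution of the curve discretization used for the
#'   shortest-distance search.
#' @return A list of class `DepthProfile`: `depth` (normalized, NA where
#'   unavailable), `depth_um`, and `slices` (per-slice thickness and fit
#'   coefficients).
#' @export
fitSurfaceAndDepth <- function(cells, subclass, degree = 2, gridN = 2000) {
    if (methods::is(cells, "SummarizedExperiment"))
        cells <- as.data.frame(colData(cells))
    n <- nrow(cells)
    depthUm <- rep(NA_real_, n)
    slices <- list()
    for (s in unique(cells$slice_id)) {
        inS <- which(cells$slice_id == s)
        isV <- subclass[inS] == "VLMC" & !is.na(subclass[inS])
        isB <- subclass[inS] == "L6b" & !is.na(subclass[inS])
        if (sum(isV) < degree + 1 || sum(isB) < 1) {
            warning("slice ", s,
                    " lacks VLMC or L6b cells; excluded from depth analysis")
            next
        }
        xs <- cells$x[inS]; ys <- cells$y[inS]
        fit <- stats::lm(y ~ poly(x, degree, raw = TRUE),
                         data = data.frame(x = xs[isV], y = ys[isV]))
        xg <- seq(min(xs) - 50, max(xs) + 50, length.out = gridN)
        yg <- stats::predict(fit, newdata = data.frame(x = xg))
        # shortest distance to the discretized curve, in blocks
        d <- numeric(length(inS))
        for (blk in split(seq_along(inS),
                          ceiling(seq_along(inS) / 2000))) {
            dx <- outer(xs[blk], xg, "-")
            dy <- outer(ys[blk], yg, "-")
            d[blk] <- sqrt(apply(dx^2 + dy^2, 1, min))
        }
        thick <- stats::median(d[isB])
        depthUm[inS] <- d
        slices[[as.character(s)]] <- data.frame(
            slice_id = s, thickness = thick,
            coef = I(list(stats::coef(fit))), n_vlmc = sum(isV),
            n_l6b = sum(isB))
    }
    sliceTab <- do.call(rbind, slices)
    depth <- depthUm
    if (!is.null(sliceTab)) {
        for (i in seq_len(nrow(sliceTab))) {
            inS <- cells$slice_id == sliceTab$slice_id[i]
            depth[inS] <- depthUm[inS] / sliceTab$thickness[i]
        }
    }
    structure(list(depth = depth, depth_um = depthUm, slices = sliceTab),
              class = "DepthProfile")
}

#' Laminar layer boundaries from cluster depth medians
#'
#' Boundaries along the normalized depth axis: the surface at 0 (VLMCs);
#' the top of L2/3 at the median depth of the most superficial L2/3 IT
#' cluster; the top of L4 at the median of the most superficial L4/5 IT
#' cluster; the top of L6 at the median of the most superficial cluster
#' among L6 IT and L6 CT clusters; L6b centred at 1 with bounds from the
#' interquartile range of the L6b cells; and the top of L5 reported as an
#' uncertainty interval between the median of the deepest L4/5 IT cluster
#' and that of the most superficial L5 IT cluster. Missing designated
#' clusters yield NA boundaries; non-monotonic boundaries raise an error.
#'
#' @param depths per-cell normalized depths.
#' @param cluster,subclass per-cell cluster and subclass labels.
#' @return A list of class `LayerBoundaries` with elements `surface`,
#'   `L23_top`, `L4_top`, `L5_top` (length-2 interval), `L6_top`,
#'   `L6b_bounds`, `L6b_center`.
#' @export
layerBoundaries <- function(depths, cluster, subclass) {
    ok <- !is.na(depths) & !is.na(cluster)
    med <- tapply(depths[ok], cluster[ok], stats::median)
    scOf <- tapply(subclass[ok], cluster[ok], function(x) x[1])
    minMed <- function(subs) {
        m <- med[scOf %in% subs]
        if (length(m) == 0) NA_real_ else min(m)
    }
    maxMed <- function(subs) {
        m <- med[scOf %in% subs]
        if (length(m) == 0) NA_real_ else max(m)
    }
    l6b <- depths[ok & subclass[ok] == "L6b"]
    bounds <- list(
        surface = 0,
        L23_top = minMed("L2/3 IT"),
        L4_top = minMed("L4/5 IT"),
        L5_top = sort(c(maxMed("L4/5 IT"), minMed("L5 IT"))),
        L6_top = minMed(c("L6 IT", "L6 CT")),
        L6b_center = 1,
        L6b_bounds = if (length(l6b))
            unname(stats::quantile(l6b, c(0.25, 0.75))) else c(NA, NA))
    seqv <- c(bounds$surface, bounds$L23_top, bounds$L4_top, bounds$L5_top,
              bounds$L6_top)
    seqv <- seqv[!is.na(seqv)]
    if (is.unsorted(seqv))
        stop("layer boundaries are not monotonically increasing")
    structure(bounds, class = "LayerBoundaries")
}

#' Fraction of a cluster inside a marker's half-maximum depth band
#'
#' All cells are binned into `nBins` equal-count bins by normalized depth;
#' the marker's binned expression profile (bin mean by default) defines the
#' depth band where expression exceeds half its maximum, and the returned
#' value is the fraction of the cluster's cells falling in that band.
#'
#' @param clusterCells logical or integer index of the cluster's cells.
#' @param marker gene name.
#' @param x cells x genes expression matrix (normalized counts).
#' @param depths per-cell normalized depths.
#' @param nBins number of depth bins (default 100).
#' @param stat `"mean"` (default) or `"median"` bin summary.
#' @return Fraction in \[0, 1\].
#' @export
markerOverlapFraction <- function(clusterCells, marker, x, depths,
                                  nBins = 100, stat = c("mean", "median")) {
    stat <- match.arg(stat)
    stopifnot(nBins >= 2)
    if (is.logical(clusterCells)) clusterCells <- which(clusterCells)
    if (length(clusterCells) == 0) stop("empty cluster")
    bin <- ceiling(rank(depths, ties.method = "first") / length(depths) *
                   nBins)
    expr <- x[, marker]
    prof <- tapply(expr, bin, if (stat == "mean") mean else stats::median)
    band <- as.integer(names(prof)[prof > max(prof) / 2])
    mean(bin[clusterCells] %in% band)
}

#' Overlap of two depth density distributions
#'
#' The integral of the pointwise minimum of the two kernel density
#' estimates, a symmetric overlap measure in \[0, 1\] (1 for identical
#' distributions, ~0 for disjoint supports).
#'
#' @param a,b numeric samples (e.g. normalized depths of two clusters).
#' @param bandwidth kernel bandwidth; NULL uses Scott's rule per sample.
#' @param gridN evaluation grid size.
#' @return Overlap fraction.
#' @export
densityOverlap <- function(a, b, bandwidth = NULL, gridN = 512) {
    stopifnot(length(a) > 0, length(b) > 0)
    bwA <- if (is.null(bandwidth)) stats::bw.nrd(a) else bandwidth
    bwB <- if (is.null(bandwidth)) stats::bw.nrd(b) else bandwidth
    lo <- min(a, b) - 3 * max(bwA, bwB)
    hi <- max(a, b) + 3 * max(bwA, bwB)
    da <- stats::density(a, bw = bwA, from = lo, to = hi, n = gridN)
    db <- stats::density(b, bw = bwB, from = lo, to = hi, n = gridN)
    dx <- diff(da$x[1:2])
    sum(pmin(da$y, db$y)) * dx
}

#' Binned 1-D distribution of groups along a coordinate
#'
#' Generic profiling of cell groups along any spatial coordinate (e.g.
#' anterior-posterior slice position or medial-lateral position within a
#' slice): the coordinate range is cut into equal-width bins and each
#' group's fraction of cells per bin is returned.
#'
#' @param coord per-cell coordinate values.
#' @param group per-cell group labels (NA dropped).
#' @param nBins number of equal-width bins.
#' @return A list with `breaks` and `fractions` (groups x bins matrix,
#'   rows summing to 1).
#' @export
coordinateDistribution <- function(coord, group, nBins = 20) {
    keep <- !is.na(group) & !is.na(coord)
    coord <- coord[keep]; group <- as.character(group[keep])
    br <- seq(min(coord), max(coord), length.out = nBins + 1)
    bin <- pmin(pmax(findInterval(coord, br, all.inside = TRUE), 1), nBins)
    lv <- sort(unique(group))
    frac <- t(vapply(lv, function(g)
        tabulate(bin[group == g], nBins) / sum(group == g),
        numeric(nBins)))
    rownames(frac) <- lv
    list(breaks = br, fractions = frac)
}

#' Neighbourhood complexity
#'
#' For each cell, the number of distinct cluster labels (including its
#' own) among cells of the same slice within `radius` microns of its
#' centroid.
#'
#' @param cells data.frame with `x`, `y`, `slice_id` (or a
#'   `SingleCellExperiment`).
#' @param cluster per-cell cluster labels (NA cells are ignored as
#'   neighbours and receive NA).
#' @param radius neighbourhood radius in microns (default 100).
#' @return Integer vector of per-cell complexities.
#' @export
neighborhoodComplexity <- function(cells, cluster, radius = 100) {
    if (methods::is(cells, "SummarizedExperiment"))
        cells <- as.data.frame(colData(cells))
    stopifnot(radius > 0)
    n <- nrow(cells)
    out <- rep(NA_integer_, n)
    cl <- as.character(cluster)
    for (s in unique(cells$slice_id)) {
        inS <- which(cells$slice_id == s & !is.na(cl))
        if (length(inS) == 0) next
        xs <- cells$x[inS]; ys <- cells$y[inS]
        # bucket cells into radius-sized grid squares; neighbours can only
        # live in the 3x3 block around a cell's square
        gx <- floor(xs / radius); gy <- floor(ys / radius)
        key <- paste(gx, gy)
        buckets <- split(seq_along(inS), key)
        for (i in seq_along(inS)) {
            cand <- unlist(buckets[paste(rep(gx[i] + (-1:1), each = 3),
                                         gy[i] + (-1:1))],
                           use.names = FALSE)
            near <- cand[(xs[cand] - xs[i])^2 + (ys[cand] - ys[i])^2 <=
                         radius^2]
            out[inS[i]] <- length(unique(cl[inS[near]]))
        }
    }
    out
}
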