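#' Threshold tracer intensities into projection labels
#'
#' Each channel is robust-scaled (median/MAD over all cells, estimating
#' the unlabelled background) and a cell is called 'on' for a channel when
#' its scaled intensity exceeds the channel threshold. Thresholds default
#' to a stringent level so weakly labelled cells stay 'off'. A derived
#' status records whether a cell projects to no, one, or several targets.
#'
#' @param intensities cells x channels numeric matrix.
#' @param thresholds per-channel thresholds on the robust-scaled scale
#'   (recycled; default 5).
#' @param normalize robust-scale the channels first (default TRUE; set
#'   FALSE if `intensities` are already normalized).
#' @return A list of class `ProjectionLabels`: `on` (logical cells x
#'   channels), `status` (`"none"`, `"single"`, `"multi"`), `target`
#'   (the single target name, NA otherwise), `n_targets`.
#' @export
thresholdTracer <- function(intensities, thresholds = 5, normalize = TRUE) {
    x <- as.matrix(intensities)
    if (normalize) {
        med <- apply(x, 2, stats::median)
        md <- apply(x, 2, stats::mad)
        md[md == 0] <- 1
        x <- sweep(sweep(x, 2, med), 2, md, "/")
    }
    thr <- rep_len(thresholds, ncol(x))
    on <- sweep(x, 2, thr, ">")
    nOn <- rowSums(on)
    status <- ifelse(nOn == 0, "none", ifelse(nOn == 1, "single", "multi"))
    tgt <- rep(NA_character_, nrow(x))
    single <- nOn == 1
    tgt[single] <- colnames(on)[max.col(on[single, , drop = FALSE],
                                        ties.method = "first")]
    structure(list(on = on, status = status, target = tgt,
                   n_targets = nOn), class = "ProjectionLabels")
}

#' Depth enrichment of projecting cells
#'
#' The reference population is all cells of IT subclasses and L6b. Depth
#' bins are equal-count bins of the reference population, and the
#' enrichment in a bin is the fraction of the target's tracer-positive
#' (reference) cells in the bin divided by the fraction of all reference
#' cells in the bin. Bins with no reference cells are reported as NA.
#'
#' @param labels a `ProjectionLabels` from [thresholdTracer()].
#' @param subclass per-cell subclass labels.
#' @param depths per-cell normalized depths.
#' @param target channel name.
#' @param nBins number of equal-count depth bins (default 20).
#' @param referenceSubclasses subclasses defining the reference
#'   population.
#' @return data.frame with `bin`, `depth_lo`, `depth_hi`, `enrichment`.
#' @export
depthEnrichment <- function(labels, subclass, depths, target, nBins = 20,
                            referenceSubclasses = c(.groupSubclasses$IT,
                                                    "L6b")) {
    ref <- which(subclass %in% referenceSubclasses & !is.na(depths))
    pos <- ref[labels$on[ref, target]]
    if (length(pos) == 0) stop("no tracer-positive cells for ", target)
    br <- stats::quantile(depths[ref], probs = seq(0, 1, length.out =
                                                   nBins + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    binRef <- cut(depths[ref], br, labels = FALSE)
    binPos <- cut(depths[pos], br, labels = FALSE)
    fRef <- tabulate(binRef, nBins) / length(ref)
    fPos <- tabulate(binPos, nBins) / length(pos)
    qs <- stats::quantile(depths[ref], probs = seq(0, 1,
                                                   length.out = nBins + 1))
    data.frame(
        bin = seq_len(nBins),
        depth_lo = utils::head(qs, -1), depth_hi = utils::tail(qs, -1),
        enrichment = ifelse(fRef > 0, fPos / fRef, NA_real_),
        row.names = NULL)
}

#' Projection composition statistics
#'
#' Restricting to tracer-positive, single-projecting cells: (i) for each
#' cluster, the fractions of its single-projecting cells going to each
#' target; and (ii) for each target, the composition of its projecting
#' cells over subclasses and over clusters, with bootstrap-over-cells
#' percentile confidence intervals for the per-target subclass fractions.
#'
#' @param labels a `ProjectionLabels`.
#' @param cluster,subclass per-cell labels.
#' @param nBoot bootstrap resamples (1 collapses the CI onto the point
#'   estimate).
#' @param seed integer seed.
#' @return A list of class `CompositionTable`: `per_cluster` (cluster x
#'   target fractions; NA rows for clusters without single-projecting
#'   cells), `per_target_subclass`, `per_target_cluster` (fractions
#'   summing to 1 per target), and `ci` (long data.frame with `lo`/`hi`
#'   per target x subclass).
#' @export
projectionComposition <- function(labels, cluster, subclass, nBoot = 100,
                                  seed = 1) {
    single <- labels$status == "single" & !is.na(cluster)
    tgt <- labels$target[single]
    cl <- cluster[single]
    sc <- subclass[single]
    targets <- colnames(labels$on)

    clusters <- sort(unique(cluster[!is.na(cluster)]))
    perCluster <- matrix(NA_real_, length(clusters), length(targets),
                         dimnames = list(clusters, targets))
    for (c0 in clusters) {
        inC <- cl == c0
        if (any(inC))
            perCluster[c0, ] <- vapply(targets, function(t0)
                mean(tgt[inC] == t0), numeric(1))
    }
    compOver <- function(f) {
        lv <- sort(unique(f[!is.na(f)]))
        out <- matrix(0, length(lv), length(targets),
                      dimnames = list(lv, targets))
        for (t0 in targets) {
            ft <- f[tgt == t0]
            if (length(ft))
                out[, t0] <- as.numeric(table(factor(ft, lv)) / length(ft))
        }
        out
    }
    perTargetSub <- compOver(sc)
    perTargetClu <- compOver(cl)

    ci <- withSeed(seed, {
        rows <- list()
        for (t0 in targets) {
            idx <- which(tgt == t0)
            lv <- rownames(perTargetSub)
            bootM <- vapply(seq_len(nBoot), function(b) {
                s <- if (nBoot == 1) idx else
                    sample(idx, length(idx), replace = TRUE)
                as.numeric(table(factor(sc[s], lv)) / length(s))
            }, numeric(length(lv)))
            if (is.null(dim(bootM))) bootM <- matrix(bootM, nrow = length(lv))
            rows[[t0]] <- data.frame(
                target = t0, subclass = lv,
                fraction = perTargetSub[, t0],
                lo = apply(bootM, 1, stats::quantile, 0.025),
                hi = apply(bootM, 1, stats::quantile, 0.975),
                row.names = NULL)
        }
        do.call(rbind, rows)
    })
    structure(list(per_cluster = perCluster,
                   per_target_subclass = perTargetSub,
                   per_target_cluster = perTargetClu, ci = ci),
              class = "CompositionTable")
}
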