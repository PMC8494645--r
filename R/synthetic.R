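#' Default cortical cell-type taxonomy for the synthetic atlas
#'
#' Returns the generator's ground-truth taxonomy: 95 clusters in 23
#' subclasses across three classes (39 excitatory, 42 inhibitory and 14
#' non-neuronal clusters), mirroring the hierarchical organisation of adult
#' mouse motor-cortex cell types. Each cluster carries a laminar depth
#' distribution (mean and s.d. of normalized cortical depth, 0 = surface,
#' 1 = median L6b depth), a round-1 routing group and a sampling weight.
#'
#' Class composition defaults to 50% excitatory / 20% inhibitory / 30%
#' non-neuronal cells, with intratelencephalic (IT) clusters holding 70% of
#' the excitatory cells and clusters weighted equally within those blocks.
#'
#' @return A data.frame with columns `cluster`, `subclass`, `class`,
#'   `group` (`IT`, `nonIT`, `CGE`, `MGE`, `NN`), `depth_mean`, `depth_sd`
#'   and `weight` (sums to 1).
#' @export
defaultTaxonomy <- function() {
    seqAlong <- function(a, b, n) if (n == 1) (a + b) / 2 else seq(a, b, length.out = n)
    block <- function(subclass, n, cls, grp, dmin, dmax, dsd) {
        data.frame(
            cluster = sprintf("%s %d", subclass, seq_len(n)),
            subclass = subclass, class = cls, group = grp,
            depth_mean = seqAlong(dmin, dmax, n), depth_sd = dsd,
            stringsAsFactors = FALSE)
    }
    exc <- rbind(
        block("L2/3 IT", 5, "excitatory", "IT", 0.10, 0.32, 0.05),
        block("L4/5 IT", 6, "excitatory", "IT", 0.34, 0.48, 0.04),
        block("L5 IT",   5, "excitatory", "IT", 0.50, 0.64, 0.05),
        block("L6 IT",   5, "excitatory", "IT", 0.68, 0.86, 0.05),
        block("L6 IT Car3", 1, "excitatory", "IT", 0.80, 0.80, 0.06),
        block("L5 ET",   5, "excitatory", "nonIT", 0.52, 0.68, 0.05),
        block("L5/6 NP", 4, "excitatory", "nonIT", 0.62, 0.78, 0.05),
        block("L6 CT",   6, "excitatory", "nonIT", 0.76, 0.94, 0.04),
        block("L6b",     2, "excitatory", "nonIT", 1.00, 1.02, 0.03))
    inh <- rbind(
        block("Lamp5", 8, "inhibitory", "CGE", 0.08, 0.45, 0.08),
        block("Sncg",  6, "inhibitory", "CGE", 0.10, 0.50, 0.09),
        block("Vip",   9, "inhibitory", "CGE", 0.10, 0.55, 0.09),
        block("Sst",  12, "inhibitory", "MGE", 0.35, 0.95, 0.10),
        block("Pvalb", 7, "inhibitory", "MGE", 0.30, 0.90, 0.10))
    nn <- rbind(
        block("Astro", 3, "non-neuronal", "NN", 0.20, 1.05, 0.20),
        block("Oligo", 3, "non-neuronal", "NN", 1.00, 1.10, 0.06),
        block("OPC",   1, "non-neuronal", "NN", 0.55, 0.55, 0.30),
        block("Micro", 1, "non-neuronal", "NN", 0.55, 0.55, 0.30),
        block("PVM",   1, "non-neuronal", "NN", 0.55, 0.55, 0.30),
        block("Endo",  2, "non-neuronal", "NN", 0.45, 0.60, 0.28),
        block("VLMC",  1, "non-neuronal", "NN", 0.00, 0.00, 0.012),
        block("Peri",  1, "non-neuronal", "NN", 0.50, 0.50, 0.28),
        block("SMC",   1, "non-neuronal", "NN", 0.45, 0.45, 0.28))
    tax <- rbind(exc, inh, nn)
    itCl <- tax$group == "IT"
    nonItCl <- tax$class == "excitatory" & !itCl
    w <- numeric(nrow(tax))
    w[itCl] <- 0.50 * 0.70 / sum(itCl)
    w[nonItCl] <- 0.50 * 0.30 / sum(nonItCl)
    w[tax$class == "inhibitory"] <- 0.20 / sum(tax$class == "inhibitory")
    w[tax$class == "non-neuronal"] <- 0.30 / sum(tax$class == "non-neuronal")
    tax$weight <- w
    tax
}

# marker dictionary used by both the generator and the clustering router
.markerRules <- function() {
    list(
        class = list(
            excitatory = "Slc17a7",
            inhibitory = c("Gad1", "Gad2"),
            neuronal = "Snap25"),
        it = "Slc30a3",
        cge = c("Lamp5", "Sncg", "Vip"),
        mge = c("Sst", "Pvalb"),
        subclass = list(
            "L2/3 IT" = "Cux2",
            "L4/5 IT" = c("Rorb", "Rspo1", "Otof"),
            "L5 IT" = "Sulf2",
            "L6 IT" = "Osr1",
            "L6 IT Car3" = "Car3",
            "L5 ET" = c("Fezf2", "Fam84b"),
            "L5/6 NP" = "Tshz2",
            "L6 CT" = "Foxp2",
            "L6b" = c("Ctgf", "Cplx3"),
            "Lamp5" = "Lamp5", "Sncg" = "Sncg", "Vip" = "Vip",
            "Sst" = c("Sst", "Chodl"), "Pvalb" = "Pvalb",
            "Astro" = "Aqp4", "Oligo" = c("Sox10", "Mbp"),
            "OPC" = c("Pdgfra", "Sox10"), "Micro" = "Cx3cr1",
            "PVM" = "Mrc1", "Endo" = c("Cldn5", "Flt1"),
            "VLMC" = c("Col1a1", "Slc6a13"), "Peri" = "Kcnj8",
            "SMC" = "Acta2"))
}

.sequentialGenes <- function() {
    c("Snap25", "Mbp", "Calm2", "Nefl", "Nefm", "Actb",
      "Tuba1a", "Plp1", "Gfap", "Sncb", "Atp1a1", "Ckb")
}

#' Configuration for the synthetic atlas generator
#'
#' Assembles all generator parameters and derives the per-cluster mean
#' expression matrix (marker structure plus seeded cluster signatures).
#' Defaults encode the statistical structure the pipeline is designed for:
#' a 95-cluster taxonomy, a 254-gene panel (242 combinatorial + 12
#' sequential-mode genes), negative-binomial counts, a two-batch design
#' whose raw mean total counts differ by ~30%, 12% doublets, 2% small
#' segmentation-artifact cells, laminar depth distributions per cluster and
#' 20 depth-graded genes in IT neurons.
#'
#' @param nCells number of cells to generate.
#' @param taxonomy taxonomy data.frame, see [defaultTaxonomy()].
#' @param nGenes panel size (>= 60; named markers are always included).
#' @param doubletRate fraction of cells that are doublets.
#' @param artifactRate fraction of small segmentation-artifact cells.
#' @param batchFactors per-batch multiplicative factors on mean counts.
#' @param nSlices number of coronal slices.
#' @param totalBase target raw mean total counts per cell at batch factor 1.
#' @param dispersion negative-binomial size parameter.
#' @param nGradientGenes number of IT depth-graded genes.
#' @param clusterSigma s.d. of the per-cluster log-normal expression jitter.
#' @param nSignature signature genes boosted per cluster.
#' @param signatureFold fold boost of signature genes.
#' @param seed integer seed; fixes the panel, cluster means and all
#'   downstream sampling.
#' @return A list of class `AtlasConfig`.
#' @export
atlasConfig <- function(nCells = 30000, taxonomy = defaultTaxonomy(),
                        nGenes = 254, doubletRate = 0.12,
                        artifactRate = 0.02, batchFactors = c(1, 1.3),
                        nSlices = 3, totalBase = 215, dispersion = 8,
                        nGradientGenes = 20, clusterSigma = 0.35,
                        nSignature = 6, signatureFold = 10, seed = 1) {
    mk <- .markerRules()
    markerGenes <- unique(c(unlist(mk$class), mk$it, unlist(mk$subclass)))
    named <- unique(c(markerGenes, .sequentialGenes()))
    nFill <- nGenes - length(named)
    if (nFill < nGradientGenes + 10)
        stop("nGenes too small for the named markers and gradient genes")
    fillers <- sprintf("Gene%03d", seq_len(nFill))
    genes <- c(named, fillers)
    gradientGenes <- fillers[seq_len(nGradientGenes)]
    signaturePool <- setdiff(fillers, gradientGenes)

    nClu <- nrow(taxonomy)
    means <- withSeed(seed * 7L + 3L, {
        base <- stats::rlnorm(length(genes), log(0.15), 0.6)
        names(base) <- genes
        base[.sequentialGenes()] <- stats::rlnorm(12, log(4), 0.3)
        M <- matrix(rep(base, each = nClu), nClu, length(genes),
                    dimnames = list(taxonomy$cluster, genes))
        # class / group / subclass marker structure
        neuron <- taxonomy$class %in% c("excitatory", "inhibitory")
        M[taxonomy$class == "excitatory", "Slc17a7"] <- 6
        M[taxonomy$class != "excitatory", "Slc17a7"] <- 0.05
        for (g in c("Gad1", "Gad2")) {
            M[taxonomy$class == "inhibitory", g] <- 6
            M[taxonomy$class != "inhibitory", g] <- 0.05
        }
        M[neuron, "Snap25"] <- 8
        M[!neuron, "Snap25"] <- 0.4
        M[, "Slc30a3"] <- 0.05
        M[taxonomy$group == "IT", "Slc30a3"] <- 4
        for (sc in names(mk$subclass)) {
            rows <- taxonomy$subclass == sc
            if (!any(rows)) next
            for (g in mk$subclass[[sc]]) {
                M[!taxonomy$subclass %in% names(mk$subclass)[
                    vapply(mk$subclass, function(v) g %in% v, TRUE)], g] <- 0.05
                M[rows, g] <- 5
            }
        }
        # per-cluster signatures and log-normal jitter over the filler genes
        sigs <- lapply(seq_len(nClu), function(i)
            sample(signaturePool, nSignature))
        for (i in seq_len(nClu))
            M[i, sigs[[i]]] <- M[i, sigs[[i]]] * signatureFold
        jit <- matrix(stats::rlnorm(nClu * length(fillers), 0, clusterSigma),
                      nClu, length(fillers))
        M[, fillers] <- M[, fillers] * jit
        attr(M, "signatures") <- sigs
        M
    })
    # one global scale so the weighted mean total lands at totalBase
    sc <- totalBase / sum(taxonomy$weight * rowSums(means))
    sig <- attr(means, "signatures")
    means <- means * sc
    attr(means, "signatures") <- sig

    gradientSlope <- withSeed(seed * 7L + 4L,
        stats::runif(nGradientGenes, 1.5, 3) *
            rep_len(c(1, -1), nGradientGenes))
    names(gradientSlope) <- gradientGenes

    structure(list(
        nCells = nCells, taxonomy = taxonomy, genes = genes,
        sequentialGenes = .sequentialGenes(), gradientGenes = gradientGenes,
        gradientSlope = gradientSlope, means = means,
        doubletRate = doubletRate, artifactRate = artifactRate,
        batchFactors = batchFactors, nSlices = nSlices,
        dispersion = dispersion, markerRules = mk, seed = seed
    ), class = "AtlasConfig")
}

# truncated-normal depth sample, clamped to [0, 1.15]
.sampleDepth <- function(mu, sd) {
    d <- stats::rnorm(length(mu), mu, sd)
    bad <- d < 0 | d > 1.15
    d[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
    pmin(pmax(d, 0), 1.15)
}

# expected count matrix for cells given cluster index and depth
.cellMeans <- function(config, cluIdx, depth) {
    M <- config$means[cluIdx, , drop = FALSE]
    isIT <- config$taxonomy$group[cluIdx] == "IT"
    if (any(isIT) && length(config$gradientGenes)) {
        for (g in config$gradientGenes) {
            M[isIT, g] <- M[isIT, g] *
                exp(config$gradientSlope[g] * (depth[isIT] - 0.5))
        }
    }
    M
}

#' Generate a ground-truthed synthetic cell atlas
#'
#' Samples cells from the configured taxonomy: negative-binomial counts
#' around cluster-specific (and, for IT neurons, depth-graded) means; a
#' per-slice quadratic cortical surface with cells placed at their true
#' normalized depths; log-normal cell volumes with counts scaling with
#' volume; batch scaling of mean counts; doublets as summed profiles of two
#' parent cells; and small low-count artifact cells. Fully reproducible
#' from `config$seed`.
#'
#' @param config an `AtlasConfig`, see [atlasConfig()]. The config fixes
#'   the biology (taxonomy, panel, cluster means); generating with a
#'   different `seed` draws an independent experiment — a replicate
#'   animal — from the same biology.
#' @param nCells,seed overrides of the config values, for generating
#'   replicate experiments of a different size.
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts` (genes x cells), colData columns `x`, `y`, `volume`,
#'   `slice_id`, `batch_id`, and ground truth in `metadata()$truth`
#'   (per-cell `cluster`, `subclass`, `class`, `group`, `depth`,
#'   `is_doublet`, `is_artifact`), `metadata()$geometry` (per-slice surface
#'   coefficients and thickness) and `metadata()$config`.
#' @export
generateAtlas <- function(config = atlasConfig(), nCells = NULL,
                          seed = NULL) {
    tax <- config$taxonomy
    n <- if (is.null(nCells)) config$nCells else nCells
    if (is.null(seed)) seed <- config$seed
    withSeed(seed, {
        cluIdx <- sample(nrow(tax), n, replace = TRUE, prob = tax$weight)
        depth <- .sampleDepth(tax$depth_mean[cluIdx], tax$depth_sd[cluIdx])
        batch <- sample(length(config$batchFactors), n, replace = TRUE)
        slice <- sample(config$nSlices, n, replace = TRUE)
        volume <- stats::rlnorm(n, log(300), 0.25)
        libNoise <- stats::rlnorm(n, 0, 0.15)

        isArt <- stats::runif(n) < config$artifactRate
        volume[isArt] <- stats::runif(sum(isArt), 20, 95)
        nDbl <- round(config$doubletRate * n)
        isDbl <- rep(FALSE, n)
        isDbl[sample(which(!isArt), nDbl)] <- TRUE

        lib <- (volume / 300) * config$batchFactors[batch] * libNoise
        lib[isArt] <- lib[isArt] * 0.3
        mu <- .cellMeans(config, cluIdx, depth) * lib
        counts <- matrix(
            stats::rnbinom(length(mu), mu = mu, size = config$dispersion),
            nrow = n)

        # doublets: add a second, independently sampled parent profile
        if (nDbl > 0) {
            pIdx <- sample(nrow(tax), nDbl, replace = TRUE, prob = tax$weight)
            pDepth <- .sampleDepth(tax$depth_mean[pIdx], tax$depth_sd[pIdx])
            pVol <- stats::rlnorm(nDbl, log(300), 0.25)
            pLib <- (pVol / 300) * config$batchFactors[batch[isDbl]] *
                stats::rlnorm(nDbl, 0, 0.15)
            pMu <- .cellMeans(config, pIdx, pDepth) * pLib
            counts[isDbl, ] <- counts[isDbl, ] + matrix(
                stats::rnbinom(length(pMu), mu = pMu,
                               size = config$dispersion), nrow = nDbl)
            volume[isDbl] <- volume[isDbl] + pVol
        }

        # geometry: per-slice gently curved surface, varying thickness
        geom <- data.frame(
            slice_id = seq_len(config$nSlices),
            a = stats::runif(config$nSlices, 50, 150),
            b = stats::runif(config$nSlices, -0.05, 0.05),
            c = stats::runif(config$nSlices, -2e-5, 2e-5),
            thickness = stats::runif(config$nSlices, 1100, 1300))
        x <- stats::runif(n, 0, 2000)
        ySurf <- geom$a[slice] + geom$b[slice] * x + geom$c[slice] * x^2
        y <- ySurf + depth * geom$thickness[slice]

        ids <- sprintf("cell_%05d", seq_len(n))
        colnames(counts) <- config$genes
        truth <- data.frame(
            cell_id = ids, cluster = tax$cluster[cluIdx],
            subclass = tax$subclass[cluIdx], class = tax$class[cluIdx],
            group = tax$group[cluIdx], depth = depth,
            is_doublet = isDbl, is_artifact = isArt,
            batch = batch, stringsAsFactors = FALSE)
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = t(counts)),
            colData = S4Vectors::DataFrame(
                cell_id = ids, x = x, y = y, volume = volume,
                slice_id = slice, batch_id = batch, row.names = ids))
        S4Vectors::metadata(sce) <- list(
            truth = truth, geometry = geom, config = config,
            state = "raw")
        sce
    })
}

#' Default projection-target composition for the tracer generator
#'
#' Per-cluster probabilities of retrograde labelling from three injection
#' targets (MOs, SSp, TEa-ECT-PERI). IT clusters are labelled at high,
#' depth-dependent rates, L6b at moderate rates, and all other clusters at
#' a small leak rate, so that IT and L6b cells jointly account for about
#' 90% of labelled cells. The deepest two L6 IT clusters are configured
#' with disjoint targets (cluster "L6 IT 1" projects to MOs but never
#' TEa-ECT-PERI; "L6 IT 3" the reverse), a projection-specificity scenario
#' among molecularly similar clusters.
#'
#' @param taxonomy taxonomy data.frame.
#' @param leak labelling probability per channel for non-IT, non-L6b
#'   clusters.
#' @return matrix clusters x targets of labelling probabilities.
#' @export
defaultProjectionComposition <- function(taxonomy = defaultTaxonomy(),
                                         leak = 0.009) {
    P <- matrix(leak, nrow(taxonomy), 3,
                dimnames = list(taxonomy$cluster,
                                c("MOs", "SSp", "TEa-ECT-PERI")))
    sc <- taxonomy$subclass
    P[sc == "L2/3 IT", ] <- rep(c(0.25, 0.20, 0.15), each = sum(sc == "L2/3 IT"))
    P[sc == "L4/5 IT", ] <- rep(c(0.20, 0.25, 0.05), each = sum(sc == "L4/5 IT"))
    P[sc == "L5 IT", ]  <- rep(c(0.25, 0.20, 0.15), each = sum(sc == "L5 IT"))
    P[sc == "L6 IT", ]  <- rep(c(0.15, 0.10, 0.15), each = sum(sc == "L6 IT"))
    P["L6 IT 1", ] <- c(0.35, 0.10, 0.00)
    P["L6 IT 3", ] <- c(0.00, 0.02, 0.35)
    P[sc == "L6 IT Car3", ] <- rep(c(0.05, 0.05, 0.10), each = sum(sc == "L6 IT Car3"))
    P[sc == "L6b", ] <- 0.08
    P
}

#' Generate synthetic retrograde-tracer intensities
#'
#' For each cell, each tracer channel is switched on independently with the
#' cluster's configured labelling probability; labelled channels receive
#' high log-normal intensities and unlabelled channels a weak background.
#'
#' @param sce a synthetic atlas from [generateAtlas()].
#' @param composition clusters x targets probability matrix, see
#'   [defaultProjectionComposition()].
#' @param onMean,onSd log-scale mean/s.d. of labelled intensities.
#' @param bgSd s.d. of the background intensity.
#' @param seed integer seed.
#' @return A list with `intensity` (cells x channels matrix) and `truth`
#'   (logical cells x channels matrix of true labels).
#' @export
generateTracer <- function(sce, composition = NULL, onMean = log(5),
                           onSd = 0.3, bgSd = 0.3, seed = 1) {
    truth <- S4Vectors::metadata(sce)$truth
    if (is.null(composition))
        composition <- defaultProjectionComposition(
            S4Vectors::metadata(sce)$config$taxonomy)
    if (any(rowSums(composition) > 1 + 1e-9))
        stop("per-cluster labelling probabilities must sum to <= 1 per channel set")
    P <- composition[truth$cluster, , drop = FALSE]
    withSeed(seed, {
        on <- matrix(stats::runif(length(P)) < P, nrow(P),
                     dimnames = dimnames(P))
        intensity <- abs(matrix(stats::rnorm(length(P), 0, bgSd), nrow(P)))
        intensity[on] <- stats::rlnorm(sum(on), onMean, onSd)
        dimnames(intensity) <- list(truth$cell_id, colnames(composition))
        rownames(on) <- truth$cell_id
        list(intensity = intensity, truth = on)
    })
}

#' Multi-round image stack with ground truth
#'
#' An S4 container for a rounds x height x width intensity stack, the pixel
#' size, and (optionally) the ground-truth molecule positions used to
#' validate decoding.
#'
#' @slot pixels numeric array, rounds x height x width, non-negative.
#' @slot pixelSize microns per pixel.
#' @slot groundTruth data.frame with columns `x`, `y` (microns) and
#'   `entry`, or NULL.
#' @export
setClass("ImageStack",
    representation(pixels = "array", pixelSize = "numeric",
                   groundTruth = "ANY"))

setValidity("ImageStack", function(object) {
    if (length(dim(object@pixels)) != 3)
        return("pixels must be a rounds x height x width array")
    if (min(object@pixels) < 0) return("intensities must be >= 0")
    TRUE
})

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("ImageStack: %d rounds, %d x %d px (%.3f um/px)%s\n",
                d[1], d[2], d[3], object@pixelSize,
                if (!is.null(object@groundTruth))
                    sprintf(", %d ground-truth molecules",
                            nrow(object@groundTruth)) else ""))
})

#' @describeIn ImageStack number of imaging rounds
#' @param x an `ImageStack`
#' @export
stackRounds <- function(x) dim(x@pixels)[1]

#' @describeIn ImageStack the pixel array (rounds x height x width)
#' @export
stackPixels <- function(x) x@pixels

#' @describeIn ImageStack microns per pixel
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn ImageStack ground-truth molecule table (or NULL)
#' @export
stackTruth <- function(x) x@groundTruth

#' Render a synthetic multi-round spot image stack
#'
#' Places molecules uniformly at random in the field; each molecule's
#' barcode on-bits are rendered as 2-D Gaussian spots in the corresponding
#' rounds, with per-spot amplitude jitter, optional single-bit dropout, and
#' additive Gaussian background noise (clipped at zero). The true molecule
#' positions and identities are recorded for decoding validation.
#'
#' @param codebook a [Codebook-class]; rounds = `nBits(codebook)`.
#' @param nMolecules number of molecules to place.
#' @param size image side length in pixels.
#' @param psfSigma Gaussian spot s.d. in pixels.
#' @param amplitude mean on-bit peak intensity.
#' @param ampJitterSd log-scale s.d. of per-spot amplitude jitter.
#' @param dropoutProb probability that one on-bit of a molecule is dropped.
#' @param falseSpotRate number of dim spurious spots (autofluorescent
#'   debris rendering a random weight-4 bit pattern) relative to
#'   `nMolecules`; these are the false-positive population the blank-based
#'   misidentification filter is designed to remove, and they are not part
#'   of the ground truth.
#' @param falseSpotAmp peak intensity of false spots relative to
#'   `amplitude`.
#' @param noiseSd s.d. of additive background noise.
#' @param pixelSize microns per pixel.
#' @param minSep minimum molecule separation in pixels (placements are
#'   rejection-sampled), keeping the ground truth resolvable.
#' @param seed integer seed.
#' @return An [ImageStack-class] with ground truth.
#' @export
generateSpotStack <- function(codebook, nMolecules = 100, size = 96,
                              psfSigma = 1.1, amplitude = 1,
                              ampJitterSd = 0.1, dropoutProb = 0,
                              falseSpotRate = 0, falseSpotAmp = 0.35,
                              noiseSd = 0, pixelSize = 0.167, minSep = 5,
                              seed = 1) {
    B <- barcodeMatrix(codebook)
    nb <- nBits(codebook)
    if (nMolecules / size^2 > 0.01)
        warning("molecule density high; ground-truth evaluation may be unreliable")
    withSeed(seed, {
        px <- array(0, dim = c(nb, size, size))
        cx <- stats::runif(nMolecules, 4, size - 3)
        cy <- stats::runif(nMolecules, 4, size - 3)
        for (tries in seq_len(200)) {
            d2 <- as.matrix(stats::dist(cbind(cx, cy)))
            diag(d2) <- Inf
            bad <- unique(apply(which(d2 < minSep, arr.ind = TRUE), 1, max))
            if (length(bad) == 0) break
            cx[bad] <- stats::runif(length(bad), 4, size - 3)
            cy[bad] <- stats::runif(length(bad), 4, size - 3)
        }
        geneRows <- which(!isBlank(codebook))  # no RNA carries a blank code
        ent <- sample(geneRows, nMolecules, replace = TRUE)
        drop <- stats::runif(nMolecules) < dropoutProb
        xg <- seq_len(size)
        for (m in seq_len(nMolecules)) {
            onBits <- which(B[ent[m], ] == 1)
            if (drop[m]) onBits <- onBits[-sample(length(onBits), 1)]
            gy <- exp(-(xg - cy[m])^2 / (2 * psfSigma^2))
            gx <- exp(-(xg - cx[m])^2 / (2 * psfSigma^2))
            spot <- outer(gy, gx)
            for (b in onBits) {
                amp <- amplitude * stats::rlnorm(1, 0, ampJitterSd)
                px[b, , ] <- px[b, , ] + amp * spot
            }
        }
        nFalse <- round(falseSpotRate * nMolecules)
        if (nFalse > 0) {
            fx <- stats::runif(nFalse, 4, size - 3)
            fy <- stats::runif(nFalse, 4, size - 3)
            # debris lights one round fewer than a real barcode: such
            # patterns sit within the single-error radius of at most one
            # codeword, so a fraction of them decode -- uniformly over
            # genes and blanks alike
            w <- codeWeight(codebook)
            for (m in seq_len(nFalse)) {
                bitsOn <- sample(nb, w - 1L)
                gy <- exp(-(xg - fy[m])^2 / (2 * psfSigma^2))
                gx <- exp(-(xg - fx[m])^2 / (2 * psfSigma^2))
                spot <- outer(gy, gx)
                for (b in bitsOn) {
                    amp <- falseSpotAmp * amplitude *
                        stats::rlnorm(1, 0, ampJitterSd)
                    px[b, , ] <- px[b, , ] + amp * spot
                }
            }
        }
        if (noiseSd > 0)
            px <- pmax(px + array(stats::rnorm(length(px), 0, noiseSd),
                                  dim = dim(px)), 0)
        new("ImageStack", pixels = px, pixelSize = pixelSize,
            groundTruth = data.frame(
                x = cx * pixelSize, y = cy * pixelSize,
                entry = rownames(B)[ent], stringsAsFactors = FALSE))
    })
}
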