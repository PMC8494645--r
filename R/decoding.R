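#' @importFrom EBImage bwlabel otsu propagate Image imageData
NULL

# 2-D Gaussian convolution via EBImage's FFT filter; sigma <= 0 is identity
.gsmooth <- function(img, sigma) {
    if (sigma <= 0) return(img)
    sz <- 2 * ceiling(3 * sigma) + 1
    sz <- min(sz, 2 * floor((min(dim(img)) - 1) / 2) - 1)
    k <- EBImage::makeBrush(sz, shape = "gaussian", sigma = sigma)
    as.matrix(EBImage::filter2(EBImage::Image(img), k))
}

# Lucy-Richardson deconvolution with a Gaussian PSF (symmetric kernel)
.lucyRichardson <- function(img, psfSigma, iterations) {
    if (iterations <= 0 || psfSigma <= 0) return(img)
    u <- pmax(img, 1e-6)
    eps <- 1e-9
    for (i in seq_len(iterations)) {
        est <- .gsmooth(u, psfSigma)
        ratio <- img / (est + eps)
        u <- u * .gsmooth(ratio, psfSigma)
    }
    u
}

#' Preprocess a multi-round image stack
#'
#' Per round: high-pass filtering (subtraction of a heavily smoothed copy)
#' to remove background, Lucy-Richardson deconvolution with a Gaussian
#' point-spread function to tighten spots, then mild low-pass smoothing to
#' absorb sub-pixel centroid movement between rounds. Intensities remain
#' non-negative. Sigmas of zero and zero iterations give the identity
#' transform.
#'
#' @param stack an [ImageStack-class].
#' @param highpassSigma s.d. (px) of the background estimate.
#' @param lrIterations Lucy-Richardson iteration count.
#' @param lowpassSigma s.d. (px) of the final smoothing.
#' @param psfSigma s.d. (px) of the Gaussian PSF used for deconvolution.
#' @return The preprocessed [ImageStack-class].
#' @export
preprocessStack <- function(stack, highpassSigma = 5, lrIterations = 20,
                            lowpassSigma = 0.8, psfSigma = 1.1) {
    stopifnot(highpassSigma >= 0, lowpassSigma >= 0, lrIterations >= 0)
    px <- stack@pixels
    for (r in seq_len(dim(px)[1])) {
        img <- px[r, , ]
        if (highpassSigma > 0)
            img <- pmax(img - .gsmooth(img, highpassSigma), 0)
        img <- .lucyRichardson(img, psfSigma, lrIterations)
        img <- .gsmooth(img, lowpassSigma)
        px[r, , ] <- pmax(img, 0)
    }
    methods::initialize(stack, pixels = px)
}

# call bits for one pixel's round-intensity vector: threshold at the
# midpoint of the largest gap between consecutive sorted intensities
.callBits <- function(v) {
    s <- sort(v)
    gaps <- diff(s)
    i <- which.max(gaps)
    thr <- (s[i] + s[i + 1]) / 2
    as.integer(v > thr)
}

#' Pixel-based decoding of an image stack
#'
#' Each sufficiently bright pixel's round-intensity vector is unit
#' normalized and converted to a bit vector (threshold at the midpoint of
#' the largest intensity gap), then decoded against the codebook with
#' single-error correction. Four-connected pixels decoding to the same
#' entry are aggregated into candidate molecules; single-pixel candidates
#' are discarded as they are dominated by spurious background calls.
#'
#' @param stack a preprocessed [ImageStack-class].
#' @param codebook a [Codebook-class] with `nBits` = rounds.
#' @param minNormFrac pixels with round-vector magnitude below this
#'   fraction of the maximum magnitude are not decoded.
#' @param maxErrors bit errors correctable per pixel (0 or 1).
#' @return A data.frame of candidate molecules: `entry`, `x`, `y`
#'   (microns), `n_pixels`, `mean_intensity`, `barcode_distance` (mean
#'   cosine distance to the unit barcode), `n_corrected`, `is_blank`,
#'   `cell_id` (NA until assignment).
#' @export
pixelDecode <- function(stack, codebook, minNormFrac = 0.2, maxErrors = 1L) {
    if (dim(stack@pixels)[1] != nBits(codebook))
        stop("stack rounds do not match codebook nBits")
    d <- dim(stack@pixels)
    nb <- d[1]
    V <- matrix(stack@pixels, nrow = nb)  # bits x pixels
    nrm <- sqrt(colSums(V^2))
    cand <- which(nrm > minNormFrac * max(nrm, 1e-12) & nrm > 0)
    empty <- data.frame(
        entry = character(), x = numeric(), y = numeric(),
        n_pixels = integer(), mean_intensity = numeric(),
        barcode_distance = numeric(), n_corrected = numeric(),
        is_blank = logical(), cell_id = character(),
        stringsAsFactors = FALSE)
    if (length(cand) == 0) return(empty)

    bits <- t(vapply(cand, function(j) .callBits(V[, j]), integer(nb)))
    dec <- decodeWords(bits, codebook, maxErrors)
    ok <- !is.na(dec$entry)
    cand <- cand[ok]; dec <- dec[ok, , drop = FALSE]
    if (length(cand) == 0) return(empty)

    B <- barcodeMatrix(codebook)
    Bu <- B / sqrt(rowSums(B^2))
    U <- V[, cand, drop = FALSE]
    U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
    cosDist <- 1 - colSums(U * t(Bu[dec$entry, , drop = FALSE]))
    onMean <- colSums(V[, cand, drop = FALSE] *
                      t(B[dec$entry, , drop = FALSE])) / codeWeight(codebook)

    # aggregate 4-connected pixels with identical entry calls
    row <- (cand - 1) %% d[2] + 1
    col <- (cand - 1) %/% d[2] + 1
    entryImg <- matrix(0L, d[2], d[3])
    eIdx <- match(dec$entry, entryNames(codebook))
    entryImg[cbind(row, col)] <- eIdx
    out <- vector("list", length(unique(eIdx)))
    ui <- 0
    ps <- stack@pixelSize
    for (e in unique(eIdx)) {
        lab <- EBImage::bwlabel(EBImage::Image(entryImg == e))
        lab <- matrix(EBImage::imageData(lab), nrow(entryImg))
        sel <- eIdx == e
        comp <- lab[cbind(row[sel], col[sel])]
        ui <- ui + 1
        out[[ui]] <- data.frame(
            entry = entryNames(codebook)[e],
            comp = comp,
            x = (col[sel] - 0.5) * ps, y = (row[sel] - 0.5) * ps,
            mi = onMean[sel], bd = cosDist[sel], nc = dec$nCorrected[sel],
            stringsAsFactors = FALSE)
    }
    pix <- do.call(rbind, out)
    agg <- do.call(rbind, lapply(
        split(pix, paste(pix$entry, pix$comp)), function(p) data.frame(
            entry = p$entry[1],
            x = mean(p$x), y = mean(p$y), n_pixels = nrow(p),
            mean_intensity = mean(p$mi), barcode_distance = mean(p$bd),
            n_corrected = mean(p$nc), stringsAsFactors = FALSE)))
    agg <- agg[agg$n_pixels >= 2, , drop = FALSE]
    if (nrow(agg) == 0) return(empty)
    agg$is_blank <- isBlank(codebook)[agg$entry]
    agg$cell_id <- NA_character_
    rownames(agg) <- NULL
    agg[order(-agg$n_pixels), , drop = FALSE]
}

#' Blank-barcode misidentification rate
#'
#' The mean molecule count per blank entry divided by the mean count per
#' coding (gene) entry. Blank barcodes are valid codewords assigned to no
#' gene, so their call rate estimates the per-barcode false-positive rate.
#'
#' @param molecules a molecule data.frame with an `entry` column.
#' @param codebook a [Codebook-class] with at least one blank.
#' @return The misidentification rate (0 when there are no blank calls).
#' @export
estimateMisidRate <- function(molecules, codebook) {
    blanks <- codebookBlanks(codebook)
    genes <- codebookGenes(codebook)
    if (length(blanks) == 0) stop("codebook has no blank entries")
    nBlank <- sum(molecules$entry %in% blanks)
    nGene <- sum(molecules$entry %in% genes)
    if (nGene == 0) stop("no coding calls; rate undefined")
    (nBlank / length(blanks)) / (nGene / length(genes))
}

#' Adaptive misidentification filtering
#'
#' Ranks candidate molecules by a combined quality score (the rank product
#' of mean on-bit intensity and one minus the normalized barcode distance,
#' both monotone in quality) and retains the largest top-quality prefix
#' whose blank-derived misidentification rate does not exceed
#' `targetRate`. If no prefix satisfies the bound, the prefix whose rate is
#' closest to the target is retained.
#'
#' @param molecules candidate molecules from [pixelDecode()].
#' @param codebook a [Codebook-class] with blanks.
#' @param targetRate target misidentification rate (default 0.05).
#' @return The retained subset of `molecules`.
#' @export
adaptiveMisidFilter <- function(molecules, codebook, targetRate = 0.05) {
    if (sum(isBlank(codebook)) == 0)
        stop("codebook has no blank entries; rate inestimable")
    n <- nrow(molecules)
    if (n == 0) return(molecules)
    score <- rank(molecules$mean_intensity, ties.method = "average") *
        rank(-molecules$barcode_distance, ties.method = "average")
    ord <- order(-score)
    m <- molecules[ord, , drop = FALSE]
    isB <- m$entry %in% codebookBlanks(codebook)
    isG <- m$entry %in% codebookGenes(codebook)
    cumB <- cumsum(isB) / sum(isBlank(codebook))
    cumG <- cumsum(isG) / sum(!isBlank(codebook))
    rate <- ifelse(cumG > 0, cumB / cumG, Inf)
    okPrefix <- which(rate <= targetRate)
    keep <- if (length(okPrefix)) max(okPrefix) else
        which.min(abs(rate - targetRate))
    molecules[sort(ord[seq_len(keep)]), , drop = FALSE]
}

#' Seeded-watershed cell segmentation
#'
#' Nuclei are thresholded (Otsu by default) and labelled as seeds; seed
#' labels are then propagated over the polyA intensity landscape within
#' the polyA foreground mask, yielding disjoint cell masks each containing
#' its seed nucleus.
#'
#' @param nucleiImage numeric matrix (e.g. DAPI).
#' @param polyaImage numeric matrix, same shape.
#' @param pixelSize microns per pixel.
#' @param sliceThickness nominal slice thickness (microns) used to convert
#'   the 2-D area to a volume.
#' @param nucleusThreshold,polyaThreshold absolute thresholds; NULL uses
#'   Otsu on the rescaled image.
#' @param minSeedArea minimum seed size in pixels.
#' @return A list with `cells` (data.frame: `cell_id`, `x`, `y` centroids
#'   in microns, `area_px`, `volume`, `on_border`) and `mask` (integer
#'   label matrix, 0 = background).
#' @export
segmentCells <- function(nucleiImage, polyaImage, pixelSize = 1,
                         sliceThickness = 10, nucleusThreshold = NULL,
                         polyaThreshold = NULL, minSeedArea = 4) {
    stopifnot(all(dim(nucleiImage) == dim(polyaImage)))
    rescale <- function(img) {
        rg <- range(img)
        if (diff(rg) == 0) return(img * 0)
        (img - rg[1]) / diff(rg)
    }
    nuc <- rescale(nucleiImage)
    if (is.null(nucleusThreshold)) nucleusThreshold <- EBImage::otsu(
        EBImage::Image(nuc))
    seeds <- EBImage::bwlabel(EBImage::Image(nuc > nucleusThreshold))
    seedM <- matrix(as.integer(EBImage::imageData(seeds)), nrow(nucleiImage))
    tab <- table(as.vector(seedM))
    small <- as.integer(names(tab)[tab < minSeedArea])
    seedM[seedM %in% setdiff(small, 0L)] <- 0L
    emptyRes <- list(cells = data.frame(
        cell_id = character(), x = numeric(), y = numeric(),
        area_px = integer(), volume = numeric(), on_border = logical(),
        stringsAsFactors = FALSE), mask = matrix(0L, nrow(nucleiImage),
                                                 ncol(nucleiImage)))
    if (max(seedM) == 0) return(emptyRes)

    pol <- rescale(polyaImage)
    if (is.null(polyaThreshold)) polyaThreshold <- EBImage::otsu(
        EBImage::Image(pol))
    mask <- pol > polyaThreshold | seedM > 0
    lab <- EBImage::propagate(EBImage::Image(pol), EBImage::Image(seedM),
                              mask = EBImage::Image(mask))
    lab <- matrix(EBImage::imageData(lab), nrow(nucleiImage))
    ids <- sort(setdiff(unique(as.vector(lab)), 0))
    cells <- do.call(rbind, lapply(ids, function(i) {
        w <- which(lab == i, arr.ind = TRUE)
        data.frame(
            cell_id = sprintf("cell_%03d", i),
            x = (mean(w[, 2]) - 0.5) * pixelSize,
            y = (mean(w[, 1]) - 0.5) * pixelSize,
            area_px = nrow(w),
            volume = nrow(w) * pixelSize^2 * sliceThickness,
            on_border = any(w == 1) || any(w[, 1] == nrow(lab)) ||
                any(w[, 2] == ncol(lab)),
            stringsAsFactors = FALSE)
    }))
    labNamed <- lab
    list(cells = cells, mask = labNamed)
}

#' Assign decoded molecules to segmented cells
#'
#' A molecule receives the id of the cell mask containing its centroid;
#' molecules outside all masks stay unassigned.
#'
#' @param molecules molecule data.frame with `x`, `y` in microns.
#' @param segmentation result of [segmentCells()].
#' @param pixelSize microns per pixel of the segmentation mask.
#' @return `molecules` with `cell_id` filled in (NA = unassigned).
#' @export
assignMolecules <- function(molecules, segmentation, pixelSize = 1) {
    if (nrow(molecules) == 0) return(molecules)
    mask <- segmentation$mask
    r <- pmin(pmax(ceiling(molecules$y / pixelSize), 1), nrow(mask))
    c <- pmin(pmax(ceiling(molecules$x / pixelSize), 1), ncol(mask))
    lab <- mask[cbind(r, c)]
    molecules$cell_id <- ifelse(lab > 0, sprintf("cell_%03d", lab),
                                NA_character_)
    molecules
}

#' Quantify a sequential-round image per cell
#'
#' Sequential-round genes carry no combinatorial barcode; their per-cell
#' signal is the summed fluorescence intensity of all pixels within the
#' cell mask, normalized by the cell's pixel area.
#'
#' @param image numeric matrix for one sequential round/channel.
#' @param segmentation result of [segmentCells()].
#' @return Named numeric vector of area-normalized intensities per cell.
#' @export
quantifySequential <- function(image, segmentation) {
    mask <- segmentation$mask
    stopifnot(all(dim(image) == dim(mask)))
    ids <- sort(setdiff(unique(as.vector(mask)), 0))
    out <- vapply(ids, function(i) {
        px <- mask == i
        sum(image[px]) / sum(px)
    }, numeric(1))
    stats::setNames(out, sprintf("cell_%03d", ids))
}

#' Aggregate assigned molecules into a cell-by-gene count matrix
#'
#' @param molecules molecule data.frame with `entry` and `cell_id`.
#' @param codebook a [Codebook-class]; columns are its gene entries.
#' @return integer matrix cells x genes (unassigned molecules and blank
#'   calls are excluded).
#' @export
moleculesToMatrix <- function(molecules, codebook) {
    genes <- codebookGenes(codebook)
    m <- molecules[!is.na(molecules$cell_id) &
                   molecules$entry %in% genes, , drop = FALSE]
    cells <- sort(unique(m$cell_id))
    out <- matrix(0L, length(cells), length(genes),
                  dimnames = list(cells, genes))
    if (nrow(m))
        for (i in seq_len(nrow(m)))
            out[m$cell_id[i], m$entry[i]] <- out[m$cell_id[i], m$entry[i]] + 1L
    out
}
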