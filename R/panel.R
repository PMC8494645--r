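#' Reference expression container for panel selection
#'
#' Bundles a cells x genes count matrix with per-cell cluster labels and a
#' cluster-to-class map, the inputs to marker-panel selection.
#'
#' @param matrix cells x genes non-negative count matrix with gene column
#'   names.
#' @param labels per-cell cluster names.
#' @param classOf named vector mapping each cluster to
#'   `"excitatory"`, `"inhibitory"` or `"other"`.
#' @return A list of class `ReferenceExpression`.
#' @export
referenceExpression <- function(matrix, labels, classOf) {
    stopifnot(nrow(matrix) == length(labels), min(matrix) >= 0,
              all(unique(labels) %in% names(classOf)))
    structure(list(matrix = matrix, labels = as.character(labels),
                   classOf = classOf), class = "ReferenceExpression")
}

# I(X; Y) in bits for binary X and categorical Y
.binaryMI <- function(x, y) {
    h <- function(p) {
        p <- p[p > 0]
        -sum(p * log2(p))
    }
    px <- mean(x)
    hx <- h(c(px, 1 - px))
    hxy <- 0
    for (lv in unique(y)) {
        sel <- y == lv
        p1 <- mean(x[sel])
        hxy <- hxy + mean(sel) * h(c(p1, 1 - p1))
    }
    hx - hxy
}

#' Rank genes by mutual information with cluster labels
#'
#' Expression is binarized at a count cut-off of zero and each gene is
#' scored by the mutual information (in bits) between its on/off state and
#' the cluster label, within the clusters of the requested class. Ties are
#' broken by gene-name order.
#'
#' @param ref a [referenceExpression()] object.
#' @param group `"excitatory"` or `"inhibitory"`.
#' @param topN number of genes to return.
#' @return Character vector of the top genes (with MI values as the
#'   `mi` attribute).
#' @export
mutualInfoRanking <- function(ref, group = c("excitatory", "inhibitory"),
                              topN = 50) {
    group <- match.arg(group)
    clus <- names(ref$classOf)[ref$classOf == group]
    sel <- ref$labels %in% clus
    if (!any(sel) || length(unique(ref$labels[sel])) < 2)
        stop("need at least 2 clusters in group ", group)
    xb <- ref$matrix[sel, , drop = FALSE] > 0
    y <- ref$labels[sel]
    mi <- vapply(colnames(xb), function(g) .binaryMI(xb[, g], y), numeric(1))
    ord <- order(-mi, names(mi))
    top <- names(mi)[ord][seq_len(min(topN, length(mi)))]
    attr(top, "mi") <- mi[top]
    top
}

#' Differentially expressed genes for a cluster pair
#'
#' Genes up in the foreground cluster relative to the background cluster,
#' passing all of: fold change of the means at least `fold`; p below
#' `pCut` from a two-group one-way test on log-transformed values
#' (equivalent to a two-group ANOVA, computed as an equal-variance t
#' test on `log(x + 1)`); expressing fraction (count > 0) at least
#' `minFrac` in the foreground; and an expressing-fraction ratio
#' (foreground over background) above `enrich`, with a background fraction
#' of zero counting as infinite enrichment. Genes are ranked by ascending
#' p and at most `topN` returned. Relax a criterion (e.g. `pCut = 1`) to
#' switch it off.
#'
#' @param ref a [referenceExpression()] object.
#' @param fg,bg foreground and background cluster names.
#' @param topN maximum genes returned.
#' @param fold,pCut,minFrac,enrich the four criteria thresholds.
#' @return data.frame with `gene`, `fold`, `p`, `frac_fg`, `frac_bg`,
#'   ranked by p.
#' @export
deGenesForPair <- function(ref, fg, bg, topN = 50, fold = 2, pCut = 0.05,
                           minFrac = 0.40, enrich = 3) {
    xf <- ref$matrix[ref$labels == fg, , drop = FALSE]
    xb <- ref$matrix[ref$labels == bg, , drop = FALSE]
    if (nrow(xf) < 2 || nrow(xb) < 2)
        stop("clusters need at least 2 cells for the p-value")
    mf <- colMeans(xf); mb <- colMeans(xb)
    fc <- mf / pmax(mb, .Machine$double.eps)
    lf <- log(xf + 1); lb <- log(xb + 1)
    vf <- apply(lf, 2, stats::var); vb <- apply(lb, 2, stats::var)
    nf <- nrow(xf); nb <- nrow(xb)
    sp <- ((nf - 1) * vf + (nb - 1) * vb) / (nf + nb - 2)
    tt <- (colMeans(lf) - colMeans(lb)) / sqrt(sp * (1 / nf + 1 / nb))
    p <- 2 * stats::pt(-abs(tt), df = nf + nb - 2)
    p[is.na(p)] <- 1
    ff <- colMeans(xf > 0); fb <- colMeans(xb > 0)
    ratio <- ifelse(fb == 0, Inf, ff / fb)
    pass <- fc >= fold & p < pCut & ff >= minFrac & ratio > enrich
    out <- data.frame(gene = colnames(ref$matrix), fold = fc, p = p,
                      frac_fg = ff, frac_bg = fb,
                      stringsAsFactors = FALSE)[pass, , drop = FALSE]
    out <- out[order(out$p, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, topN)
}

#' Greedy marker cover over cluster-pair DE candidates
#'
#' Starting from a seed panel, repeatedly adds the candidate gene covering
#' the largest number of still-uncovered (pair, direction) slots until
#' every ordered pair has at least `minPerDirection` of its DE candidates
#' in the panel, or no candidate helps. Pairs that cannot reach the target
#' even with all their candidates are flagged as uncoverable, never
#' silently dropped.
#'
#' @param candidates named list, one element per ordered pair
#'   (`"fg|bg"`), each a character vector of DE candidate genes (ranked).
#' @param seedPanel genes always included.
#' @param minPerDirection required covered genes per ordered pair.
#' @return A list of class `PanelSelection`: `manual`, `de_selected`
#'   (greedy additions in order), `final_panel`, `coverage` (data.frame
#'   per pair: `pair`, `covered`, `required`, `uncoverable`).
#' @export
greedyMarkerCover <- function(candidates, seedPanel = character(),
                              minPerDirection = 2) {
    panel <- unique(seedPanel)
    covered <- vapply(candidates, function(g) sum(g %in% panel), integer(1))
    maxPossible <- vapply(candidates, length, integer(1))
    uncoverable <- maxPossible < minPerDirection
    added <- character()
    repeat {
        need <- names(candidates)[covered < minPerDirection & !uncoverable]
        if (length(need) == 0) break
        pool <- setdiff(unique(unlist(candidates[need])), panel)
        if (length(pool) == 0) break
        gain <- vapply(pool, function(g)
            sum(vapply(candidates[need], function(cc) g %in% cc, logical(1))),
            integer(1))
        best <- sort(pool[gain == max(gain)])[1]
        if (max(gain) == 0) break
        panel <- c(panel, best)
        added <- c(added, best)
        covered <- covered + vapply(candidates, function(g) best %in% g,
                                    logical(1))
    }
    coverage <- data.frame(
        pair = names(candidates), covered = unname(covered),
        required = minPerDirection, uncoverable = unname(uncoverable),
        row.names = NULL, stringsAsFactors = FALSE)
    structure(list(manual = seedPanel, de_selected = added,
                   final_panel = unique(c(seedPanel, added)),
                   coverage = coverage), class = "PanelSelection")
}

#' Route panel genes to combinatorial or sequential imaging
#'
#' A gene is imaged in sequential rounds (rather than combinatorially)
#' when its transcript cannot accommodate `minProbes` 30-nt targeting
#' sequences even with the maximum allowed overlap, or when its mean count
#' per cell reaches `maxMeanCount` in any cluster — short or very highly
#' expressed genes are problematic for combinatorial imaging.
#'
#' @param ref a [referenceExpression()] object.
#' @param panel gene names to screen.
#' @param transcripts named [Biostrings::DNAStringSet] (or named character
#'   vector) of transcript sequences covering the panel.
#' @param maxMeanCount per-cluster mean count threshold (default 200).
#' @param minProbes probe-capacity threshold (default 48).
#' @param targetLen,maxOverlap probe geometry (defaults 30 and 20 nt).
#' @return A list with `combinatorial` and `sequential` gene vectors.
#' @export
screenForSequential <- function(ref, panel, transcripts, maxMeanCount = 200,
                                minProbes = 48, targetLen = 30,
                                maxOverlap = 20) {
    lens <- if (methods::is(transcripts, "XStringSet"))
        stats::setNames(Biostrings::width(transcripts), names(transcripts))
    else stats::setNames(nchar(transcripts), names(transcripts))
    missing <- setdiff(panel, names(lens))
    if (length(missing))
        stop("missing transcript for: ", paste(missing, collapse = ", "))
    caps <- floor((lens[panel] - targetLen) / (targetLen - maxOverlap)) + 1
    cluMeans <- vapply(unique(ref$labels), function(cl)
        colMeans(ref$matrix[ref$labels == cl, panel, drop = FALSE]),
        numeric(length(panel)))
    if (is.null(dim(cluMeans))) cluMeans <- matrix(cluMeans, nrow = 1)
    maxMean <- apply(cluMeans, 1, max)
    seqGenes <- panel[caps < minProbes | maxMean >= maxMeanCount]
    list(combinatorial = setdiff(panel, seqGenes), sequential = seqGenes)
}

#' Design encoding probes for one transcript
#'
#' Selects up to `nProbes` 30-nt targeting sequences along the transcript.
#' When the transcript fits that many non-overlapping targets, start
#' positions are sampled (seeded) from the non-overlapping grid; otherwise
#' targets are placed on a deterministic evenly spaced grid in which
#' adjacent targets overlap by at most `maxOverlap` nt. Combinatorial
#' probes carry two readout ids drawn from the gene barcode's four
#' on-bits, cycled so every on-bit appears on a near-equal number of
#' probes; sequential probes carry the single gene-specific readout.
#'
#' @param transcript a [Biostrings::DNAString] or character sequence.
#' @param mode `"combinatorial"` or `"sequential"`.
#' @param nProbes probes requested (92 combinatorial / 48 sequential by
#'   convention).
#' @param targetLen targeting-sequence length (default 30).
#' @param maxOverlap maximum overlap of adjacent targets (default 20).
#' @param barcode 0/1 bit vector of the gene's barcode (combinatorial
#'   mode).
#' @param readoutId single readout id (sequential mode).
#' @param seed integer seed for start sampling and pair shuffling.
#' @return A list of class `ProbeSet` with `mode` and `probes`
#'   (data.frame: `start` 0-based, `target_seq`, `readout_ids`
#'   comma-joined).
#' @export
designEncodingProbes <- function(transcript, mode = c("combinatorial",
                                                      "sequential"),
                                 nProbes = 92, targetLen = 30,
                                 maxOverlap = 20, barcode = NULL,
                                 readoutId = NULL, seed = 1) {
    mode <- match.arg(mode)
    seqc <- as.character(transcript)
    L <- nchar(seqc)
    if (L < targetLen) stop("transcript shorter than the target length")
    capacity <- floor((L - targetLen) / (targetLen - maxOverlap)) + 1
    n <- min(nProbes, capacity)
    gridSlots <- floor(L / targetLen)
    starts <- withSeed(seed, {
        if (gridSlots >= n) {
            sort(sample(0:(gridSlots - 1), n)) * targetLen
        } else {
            floor(seq(0, L - targetLen, length.out = n))
        }
    })
    targets <- substring(seqc, starts + 1, starts + targetLen)

    readouts <- if (mode == "combinatorial") {
        if (is.null(barcode)) stop("combinatorial mode needs a barcode")
        onBits <- which(barcode == 1)
        pairs <- utils::combn(onBits, 2, simplify = FALSE)
        pairs <- withSeed(seed + 1L, sample(pairs))
        vapply(seq_len(n), function(i)
            paste(pairs[[(i - 1) %% length(pairs) + 1]], collapse = ","),
            character(1))
    } else {
        if (is.null(readoutId)) stop("sequential mode needs a readoutId")
        rep(as.character(readoutId), n)
    }
    structure(list(
        mode = mode,
        probes = data.frame(start = starts, target_seq = targets,
                            readout_ids = readouts,
                            stringsAsFactors = FALSE)),
        class = "ProbeSet")
}
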