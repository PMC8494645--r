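#' @import methods
NULL

#' Constant-weight error-robust codebook
#'
#' An S4 container mapping genes (and unassigned "blank" barcodes) to binary
#' barcodes of fixed length, fixed Hamming weight and guaranteed minimum
#' pairwise Hamming distance. A minimum distance of 4 permits correction of
#' any single-bit error; blank barcodes, which are valid codewords assigned
#' to no gene, provide an internal estimate of the false-positive call rate.
#'
#' @slot nBits integer, barcode length (number of imaging rounds).
#' @slot weight integer, number of on-bits per barcode.
#' @slot minDistance integer, guaranteed minimum pairwise Hamming distance.
#' @slot barcodes 0/1 integer matrix, one row per entry (rownames are entry
#'   names), one column per bit; column j corresponds to imaging round j.
#' @slot isBlank named logical vector, TRUE for blank entries.
#'
#' @seealso [buildCodebook()], [decodeWord()]
#' @export
setClass("Codebook",
    representation(
        nBits = "integer",
        weight = "integer",
        minDistance = "integer",
        barcodes = "matrix",
        isBlank = "logical"
    )
)

setValidity("Codebook", function(object) {
    msg <- character()
    B <- object@barcodes
    if (ncol(B) != object@nBits)
        msg <- c(msg, "barcode matrix must have nBits columns")
    if (!all(B %in% c(0L, 1L)))
        msg <- c(msg, "barcodes must be 0/1")
    if (!all(rowSums(B) == object@weight))
        msg <- c(msg, "every barcode must have exactly 'weight' on-bits")
    if (is.null(rownames(B)) || anyDuplicated(rownames(B)))
        msg <- c(msg, "entries must have unique names")
    if (length(object@isBlank) != nrow(B))
        msg <- c(msg, "isBlank must have one flag per entry")
    if (nrow(B) > 1) {
        d <- .pairwiseHamming(B)
        if (min(d[upper.tri(d)]) < object@minDistance)
            msg <- c(msg, "pairwise Hamming distance below minDistance")
    }
    if (length(msg)) msg else TRUE
})

# all-pairs Hamming distances for a 0/1 matrix (rows are words)
.pairwiseHamming <- function(B) {
    ov <- tcrossprod(B)
    w <- rowSums(B)
    outer(w, w, "+") - 2 * ov
}

#' @describeIn Codebook number of bits (imaging rounds) per barcode
#' @param x,object a `Codebook`
#' @export
nBits <- function(x) x@nBits

#' @describeIn Codebook Hamming weight of every barcode
#' @export
codeWeight <- function(x) x@weight

#' @describeIn Codebook guaranteed minimum pairwise Hamming distance
#' @export
minDistance <- function(x) x@minDistance

#' @describeIn Codebook 0/1 barcode matrix (entries x bits)
#' @export
barcodeMatrix <- function(x) x@barcodes

#' @describeIn Codebook names of all entries (genes then blanks)
#' @export
entryNames <- function(x) rownames(x@barcodes)

#' @describeIn Codebook logical, which entries are blanks
#' @export
isBlank <- function(x) x@isBlank

#' @describeIn Codebook names of gene (non-blank) entries
#' @export
codebookGenes <- function(x) rownames(x@barcodes)[!x@isBlank]

#' @describeIn Codebook names of blank entries
#' @export
codebookBlanks <- function(x) rownames(x@barcodes)[x@isBlank]

setMethod("show", "Codebook", function(object) {
    cat(sprintf(
        "Codebook: %d-bit, weight-%d, min Hamming distance %d\n%d entries: %d genes + %d blanks\n",
        object@nBits, object@weight, object@minDistance,
        nrow(object@barcodes), sum(!object@isBlank), sum(object@isBlank)
    ))
})

# All weight-w words over nBits bits whose on-bit positions (0-based) sum to
# 0 modulo nBits.  Two distinct such words share at most w-2 on-bits (if they
# shared w-1, the remaining positions would be congruent mod nBits and hence
# equal), forcing pairwise distance >= 4.
.residueCodewords <- function(nBits, weight) {
    combs <- utils::combn(0:(nBits - 1), weight)
    keep <- colSums(combs) %% nBits == 0
    combs <- combs[, keep, drop = FALSE]
    B <- matrix(0L, ncol(combs), nBits)
    for (i in seq_len(ncol(combs))) B[i, combs[, i] + 1L] <- 1L
    B
}

# Greedy lexicographic fallback: scan all weight-w words in lexicographic
# order of their bit strings, keeping each word at distance >= minDistance
# from all kept words.
.greedyCodewords <- function(nBits, weight, minDistance, needed) {
    combs <- utils::combn(seq_len(nBits), weight)
    B <- matrix(0L, ncol(combs), nBits)
    for (i in seq_len(ncol(combs))) B[i, combs[, i]] <- 1L
    B <- B[order(apply(B, 1, paste, collapse = "")), , drop = FALSE]
    kept <- matrix(0L, 0, nBits)
    for (i in seq_len(nrow(B))) {
        w <- B[i, ]
        if (nrow(kept) == 0 ||
            min(weight + rowSums(kept) - 2 * drop(kept %*% w)) >= minDistance)
            kept <- rbind(kept, w)
        if (nrow(kept) >= needed) break
    }
    rownames(kept) <- NULL
    kept
}

#' Build a constant-weight error-robust codebook
#'
#' Generates binary barcodes of length `nBits` with exactly `weight` on-bits
#' and pairwise Hamming distance at least `minDistance`, then assigns genes
#' and blank barcodes. The primary generator is the sum-residue
#' construction: all weight-`weight` words whose (0-based) on-bit positions
#' sum to 0 modulo `nBits`. Any two such words share at most `weight - 2`
#' on-bits, so the pairwise distance is at least 4 by construction; the
#' distance is re-verified exhaustively by the class validity check. When
#' the residue pool is too small for the requested number of entries (or
#' `minDistance > 4`), a greedy lexicographic construction is used instead.
#'
#' Codewords are ordered lexicographically by bit string; blanks are sampled
#' uniformly at random from the pool using `seed`, and the remaining
#' codewords are assigned to genes in input order.
#'
#' @param nBits barcode length (imaging rounds).
#' @param weight on-bits per barcode.
#' @param minDistance required minimum pairwise Hamming distance (even,
#'   >= 2).
#' @param genes character vector of gene names, or a single integer count
#'   (genes are then named `Gene001`, ...).
#' @param nBlanks number of blank barcodes to reserve.
#' @param seed integer seed controlling blank selection.
#' @return A [Codebook-class] object with `length(genes) + nBlanks` entries.
#' @examples
#' cb <- buildCodebook(8, 4, 4, genes = 5, nBlanks = 2, seed = 1)
#' cb
#' @export
buildCodebook <- function(nBits, weight, minDistance, genes, nBlanks = 0L,
                          seed = 1L) {
    nBits <- as.integer(nBits); weight <- as.integer(weight)
    minDistance <- as.integer(minDistance)
    if (weight > nBits)
        stop("weight must not exceed nBits")
    if (minDistance %% 2L != 0L || minDistance < 2L)
        stop("minDistance must be even and >= 2")
    if (length(genes) == 1L && is.numeric(genes))
        genes <- sprintf("Gene%03d", seq_len(genes))
    nGenes <- length(genes)
    if (nGenes + nBlanks < 1L) stop("need at least one entry")
    if (choose(nBits, weight) > 5e6)
        stop("parameter space too large to enumerate")

    needed <- nGenes + as.integer(nBlanks)
    B <- if (minDistance <= 4L) .residueCodewords(nBits, weight) else
        matrix(0L, 0, nBits)
    if (nrow(B) < needed)
        B <- .greedyCodewords(nBits, weight, minDistance, needed)
    if (nrow(B) < needed)
        stop(sprintf(
            "capacity error: construction yields %d codewords, %d required",
            nrow(B), needed))
    B <- B[order(apply(B, 1, paste, collapse = "")), , drop = FALSE]

    blankIdx <- integer(0)
    if (nBlanks > 0) {
        blankIdx <- withSeed(seed, sample(nrow(B), nBlanks))
    }
    geneIdx <- setdiff(seq_len(nrow(B)), blankIdx)[seq_len(nGenes)]
    keep <- c(geneIdx, blankIdx)
    B <- B[keep, , drop = FALSE]
    rownames(B) <- c(genes, if (nBlanks > 0) sprintf("Blank-%d", seq_len(nBlanks)))
    new("Codebook",
        nBits = nBits, weight = weight, minDistance = minDistance,
        barcodes = B,
        isBlank = stats::setNames(
            c(rep(FALSE, nGenes), rep(TRUE, nBlanks)), rownames(B)))
}

#' Capacity of the codeword constructions
#'
#' Number of codewords available at the given parameters (sum-residue
#' construction when `minDistance <= 4`, greedy lexicographic otherwise),
#' with the pairwise minimum distance re-verified by brute force.
#'
#' @inheritParams buildCodebook
#' @return Integer count of available codewords.
#' @export
codebookCapacity <- function(nBits, weight, minDistance = 4) {
    B <- if (minDistance <= 4) .residueCodewords(nBits, weight) else
        .greedyCodewords(nBits, weight, minDistance, choose(nBits, weight))
    if (nrow(B) > 1) {
        d <- .pairwiseHamming(B)
        stopifnot(min(d[upper.tri(d)]) >= minDistance)
    }
    nrow(B)
}

#' Decode a single bit vector against a codebook
#'
#' Finds the unique codebook entry within Hamming distance `maxErrors` of
#' `bits`. Ties or out-of-range words yield a no-call (the decoder never
#' guesses); with `minDistance` 4 and `maxErrors` 1 decoding is unambiguous
#' for any single-bit error.
#'
#' @param bits 0/1 vector of length `nBits(codebook)`.
#' @param codebook a [Codebook-class].
#' @param maxErrors 0 or 1, maximum number of correctable bit errors.
#' @return A list with elements `entry` (entry name, or `NA` for a no-call),
#'   `nCorrected` (bits corrected, `NA` for a no-call) and `isBlank`.
#' @export
decodeWord <- function(bits, codebook, maxErrors = 1L) {
    if (length(bits) != codebook@nBits)
        stop("length mismatch: expected ", codebook@nBits, " bits")
    stopifnot(maxErrors %in% c(0L, 1L))
    res <- decodeWords(matrix(as.integer(bits), 1), codebook, maxErrors)
    list(entry = res$entry[1], nCorrected = res$nCorrected[1],
         isBlank = res$isBlank[1])
}

#' Decode many bit vectors at once
#'
#' Vectorised form of [decodeWord()]: each row of `bits` is decoded
#' independently.
#'
#' @param bits 0/1 matrix, one word per row, `nBits(codebook)` columns.
#' @param codebook a [Codebook-class].
#' @param maxErrors 0 or 1.
#' @return A data.frame with columns `entry`, `nCorrected`, `isBlank`
#'   (`NA`s mark no-calls).
#' @export
decodeWords <- function(bits, codebook, maxErrors = 1L) {
    if (ncol(bits) != codebook@nBits)
        stop("length mismatch: expected ", codebook@nBits, " bits")
    B <- codebook@barcodes
    storage.mode(bits) <- "integer"
    # Hamming distance between binary words x, y: |x| + |y| - 2 x.y
    d <- outer(rowSums(bits), rowSums(B), "+") - 2 * tcrossprod(bits, B)
    dmin <- apply(d, 1, min)
    nmin <- rowSums(d == dmin)
    hit <- dmin <= maxErrors & nmin == 1L
    idx <- max.col(-d, ties.method = "first")
    data.frame(
        entry = ifelse(hit, rownames(B)[idx], NA_character_),
        nCorrected = ifelse(hit, as.integer(round(dmin)), NA_integer_),
        isBlank = ifelse(hit, unname(codebook@isBlank[idx]), NA),
        stringsAsFactors = FALSE)
}

#' Write a codebook to CSV
#'
#' Serialises to `name,is_blank,barcode` with the barcode as a bit string;
#' string position 1 is imaging round 1.
#'
#' @param codebook a [Codebook-class].
#' @param file output path.
#' @export
writeCodebook <- function(codebook, file) {
    df <- data.frame(
        name = rownames(codebook@barcodes),
        is_blank = as.integer(codebook@isBlank),
        barcode = apply(codebook@barcodes, 1, paste, collapse = ""))
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' Read a codebook from CSV
#'
#' Inverse of [writeCodebook()]; code parameters are recovered from the
#' barcodes themselves (the minimum pairwise distance is recomputed).
#'
#' @param file path to a codebook CSV.
#' @return A [Codebook-class].
#' @export
readCodebook <- function(file) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE,
                          colClasses = c(barcode = "character"))
    B <- t(vapply(strsplit(df$barcode, ""),
                  function(x) as.integer(x), integer(nchar(df$barcode[1]))))
    rownames(B) <- df$name
    d <- .pairwiseHamming(B)
    new("Codebook",
        nBits = ncol(B), weight = as.integer(rowSums(B)[1]),
        minDistance = as.integer(min(d[upper.tri(d)])),
        barcodes = B,
        isBlank = stats::setNames(df$is_blank == 1, df$name))
}
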