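#' Write a cell-by-gene count matrix to Matrix-Market files
#'
#' Writes `<prefix>.mtx` plus `<prefix>.genes.txt` and
#' `<prefix>.cells.txt` sidecars holding the axis names.
#'
#' @param sce a `SingleCellExperiment` (the `counts` assay is written) or
#'   a genes x cells matrix.
#' @param prefix output path prefix.
#' @export
writeCountsMTX <- function(sce, prefix) {
    m <- if (methods::is(sce, "SummarizedExperiment"))
        as.matrix(assay(sce, "counts")) else as.matrix(sce)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"),
                    paste0(prefix, ".mtx"))
    writeLines(rownames(m), paste0(prefix, ".genes.txt"))
    writeLines(colnames(m), paste0(prefix, ".cells.txt"))
    invisible(prefix)
}

#' Read a cell-by-gene count matrix written by [writeCountsMTX()]
#'
#' @param prefix path prefix.
#' @return A genes x cells dense matrix with dimnames.
#' @export
readCountsMTX <- function(prefix) {
    m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
    dimnames(m) <- list(readLines(paste0(prefix, ".genes.txt")),
                        readLines(paste0(prefix, ".cells.txt")))
    m
}

#' Write decoded molecules to CSV
#'
#' @param molecules molecule data.frame from [pixelDecode()].
#' @param file output path.
#' @export
writeMolecules <- function(molecules, file) {
    utils::write.csv(molecules, file, row.names = FALSE)
    invisible(file)
}
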