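#' Read a 10x-style MatrixMarket count directory
#'
#' Loads \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv}
#' (or \code{genes.tsv}) from a directory into a
#' \linkS4class{SingleCellExperiment} with a \code{counts} assay. Row names
#' are gene symbols (second column of the features file when present,
#' otherwise the first), column names are cell barcodes.
#'
#' @param dir directory containing the three files (uncompressed).
#' @return a \linkS4class{SingleCellExperiment}.
#' @export
readTenxCounts <- function(dir) {
    mtx <- file.path(dir, "matrix.mtx")
    bc <- file.path(dir, "barcodes.tsv")
    ft <- file.path(dir, "features.tsv")
    if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
    for (f in c(mtx, bc, ft))
        if (!file.exists(f)) stop("missing 10x file: ", f)
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    barcodes <- readLines(bc)
    feat <- utils::read.table(ft, sep = "\t", stringsAsFactors = FALSE)
    symbols <- if (ncol(feat) >= 2L) feat[[2L]] else feat[[1L]]
    if (nrow(feat) != nrow(m) || length(barcodes) != ncol(m))
        stop("matrix dimensions do not match barcodes/features files")
    dimnames(m) <- list(symbols, barcodes)
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a count matrix as a 10x-style MatrixMarket directory
#'
#' @param sce a \linkS4class{SingleCellExperiment} (or any object with a
#'   \code{counts} assay) with gene symbols as row names and barcodes as
#'   column names.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeTenxCounts <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- SummarizedExperiment::assay(sce, "counts")
    Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
    utils::write.table(data.frame(id = rownames(m), symbol = rownames(m)),
                       file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(dir)
}
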