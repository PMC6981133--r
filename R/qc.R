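getCounts <- function(x) {
    m <- SummarizedExperiment::assay(x, "counts")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("counts matrix needs gene symbols as rownames and barcodes as ",
             "colnames")
    m
}

#' Per-cell QC summaries
#'
#' Total UMI count, number of detected genes, and mitochondrial fraction
#' (counts on genes whose symbol starts with \code{mitoPrefix}, divided by
#' the total) for every cell.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts}
#'   assay.
#' @param mitoPrefix prefix identifying mitochondrial genes; the standard
#'   human convention is \code{"MT-"}.
#' @return data.frame with rownames = barcodes and columns \code{umi},
#'   \code{genes}, \code{mito}.
#' @export
perCellQC <- function(sce, mitoPrefix = "MT-") {
    m <- getCounts(sce)
    umi <- Matrix::colSums(m)
    genes <- Matrix::colSums(m > 0)
    mitoGenes <- startsWith(rownames(m), mitoPrefix)
    mitoCounts <- if (any(mitoGenes))
        Matrix::colSums(m[mitoGenes, , drop = FALSE]) else rep(0, ncol(m))
    mito <- ifelse(umi > 0, mitoCounts / umi, 0)
    data.frame(umi = umi, genes = genes, mito = mito,
               row.names = colnames(m))
}

#' Cell-level quality-control filter
#'
#' Retains cells with strictly more than \code{minUMI} UMIs, between
#' \code{minGenes} and \code{maxGenes} detected genes (bounds inclusive),
#' and mitochondrial content strictly below \code{maxMito}. Defaults are
#' the standard thresholds for this workflow: UMI > 400, 100-8000 genes
#' inclusive, mitochondrial fraction < 10%.
#'
#' @inheritParams perCellQC
#' @param minUMI retain only cells with UMI strictly greater than this.
#' @param minGenes,maxGenes inclusive bounds on detected genes.
#' @param maxMito retain only cells with mitochondrial fraction strictly
#'   below this.
#' @return character vector of retained barcodes.
#' @examples
#' sce <- simulateExpressionMatrix(20, 5, seed = 1)
#' length(qcFilterCells(sce))
#' @export
qcFilterCells <- function(sce, minUMI = 400, minGenes = 100,
                          maxGenes = 8000, maxMito = 0.10,
                          mitoPrefix = "MT-") {
    qc <- perCellQC(sce, mitoPrefix)
    keep <- qc$umi > minUMI & qc$genes >= minGenes & qc$genes <= maxGenes &
        qc$mito < maxMito
    rownames(qc)[keep]
}

#' Select normal reference cells by marker expression
#'
#' Reference (normal) cells are selected as those whose log-normalized
#' marker expression (counts scaled to 10,000 per cell, then log1p) exceeds
#' the mean by more than \code{zThreshold} standard deviations, and that
#' have zero raw counts for every excluded tumor-marker gene. Mean and SD
#' are taken over the QC-passing cells supplied in \code{cells}. The
#' defaults select T cells by CD3E with no expression of the melanoma
#' markers PRAME and HTR2B.
#'
#' @inheritParams perCellQC
#' @param marker gene symbol used for positive selection.
#' @param zThreshold number of standard deviations above the mean.
#' @param excluded gene symbols that must have zero counts.
#' @param cells barcodes over which selection (and the mean/SD) is
#'   computed; defaults to [qcFilterCells()] with standard thresholds.
#' @return character vector of selected barcodes. A constant marker
#'   (SD = 0) yields an empty selection with a warning.
#' @export
selectReferenceCells <- function(sce, marker = "CD3E", zThreshold = 2,
                                 excluded = c("PRAME", "HTR2B"),
                                 cells = qcFilterCells(sce)) {
    m <- getCounts(sce)
    missing <- setdiff(c(marker, excluded), rownames(m))
    if (length(missing))
        stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
    m <- m[, cells, drop = FALSE]
    umi <- Matrix::colSums(m)
    norm <- log1p(ifelse(umi > 0, m[marker, ] / umi * 1e4, 0))
    sdv <- stats::sd(norm)
    if (length(norm) == 0L || is.na(sdv) || sdv == 0) {
        warning("marker ", marker, " has zero variance; no reference cells ",
                "selected")
        return(character())
    }
    high <- norm > mean(norm) + zThreshold * sdv
    exCounts <- m[excluded, , drop = FALSE]
    clean <- Matrix::colSums(exCounts) == 0
    cells[high & clean]
}

#' Tumor-cell filter for CNV inference
#'
#' Restricts a tumor-cell set to high-quality cells with strictly more
#' than \code{minUMI} UMIs (default 3000), the input filter applied before
#' copy-number inference.
#'
#' @inheritParams perCellQC
#' @param tumorBarcodes barcodes of tumor cells (must be a subset of the
#'   matrix barcodes).
#' @param minUMI strict lower bound on per-cell UMIs.
#' @return character vector of retained tumor barcodes.
#' @export
selectTumorCellsForCNV <- function(sce, tumorBarcodes, minUMI = 3000) {
    m <- getCounts(sce)
    missing <- setdiff(tumorBarcodes, colnames(m))
    if (length(missing))
        stop("tumor barcode(s) absent from matrix: ",
             paste(utils::head(missing, 3), collapse = ", "))
    if (length(tumorBarcodes) == 0L) return(character())
    umi <- Matrix::colSums(m[, tumorBarcodes, drop = FALSE])
    tumorBarcodes[umi > minUMI]
}
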