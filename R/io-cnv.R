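#' Read per-subclone CNV region calls and the cell-groupings table
#'
#' Consumes the HMM region-prediction table emitted by single-cell CNV
#' inference (header columns \code{cell_group_name}, \code{cnv_name},
#' \code{state}, \code{chr}, \code{start}, \code{end}; coordinates 1-based
#' closed) together with the matching cell-groupings table (columns
#' \code{cell_group_name}, \code{cell}). States follow the six-state
#' convention: 1-2 loss, 3 neutral, 4-6 gain. Chromosome names are
#' normalized; duplicate region rows are retained (deduplication happens
#' at the arm-event stage). Every region's group must exist in the
#' groupings table.
#'
#' @param regionsPath path to the region-predictions TSV.
#' @param groupingsPath path to the cell-groupings TSV.
#' @return a list with elements \code{regions} (a
#'   \linkS4class{GRanges} with metadata columns \code{group_id},
#'   \code{cnv_name}, \code{state}) and \code{groupings} (named list of
#'   cell-barcode character vectors, one per group).
#' @export
readCNVCalls <- function(regionsPath, groupingsPath) {
    if (!file.exists(regionsPath))
        stop("regions file not found: ", regionsPath)
    if (!file.exists(groupingsPath))
        stop("groupings file not found: ", groupingsPath)
    reg <- utils::read.table(regionsPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    grp <- utils::read.table(groupingsPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("cell_group_name", "cnv_name", "state", "chr", "start", "end")
    if (!all(need %in% colnames(reg)))
        stop("regions file must have columns: ", paste(need, collapse = ", "))
    if (!all(c("cell_group_name", "cell") %in% colnames(grp)))
        stop("groupings file must have columns cell_group_name, cell")
    groupings <- split(as.character(grp$cell),
                       as.character(grp$cell_group_name))
    allCells <- unlist(groupings, use.names = FALSE)
    if (anyDuplicated(allCells))
        stop("cell barcodes duplicated across groups: ",
             paste(unique(allCells[duplicated(allCells)])[1:1], collapse = ", "))
    state <- as.integer(reg$state)
    if (anyNA(state) || any(state < 1L | state > 6L))
        stop("CNV state outside {1..6} in regions file")
    unknown <- setdiff(unique(reg$cell_group_name), names(groupings))
    if (length(unknown))
        stop("region group(s) absent from groupings: ",
             paste(unknown, collapse = ", "))
    if (any(reg$start > reg$end))
        stop("region with start > end in regions file")
    regions <- GenomicRanges::GRanges(
        normalizeChrom(reg$chr),
        IRanges::IRanges(as.numeric(reg$start), as.numeric(reg$end)),
        group_id = as.character(reg$cell_group_name),
        cnv_name = as.character(reg$cnv_name),
        state = state)
    list(regions = regions, groupings = groupings)
}

#' Write CNV region calls and groupings in the format readCNVCalls() reads
#'
#' @param regions \linkS4class{GRanges} with metadata columns
#'   \code{group_id}, \code{cnv_name}, \code{state} (as returned by
#'   [readCNVCalls()]).
#' @param groupings named list of cell-barcode vectors.
#' @param regionsPath,groupingsPath output paths.
#' @return invisibly, \code{c(regionsPath, groupingsPath)}.
#' @export
writeCNVCalls <- function(regions, groupings, regionsPath, groupingsPath) {
    mc <- S4Vectors::mcols(regions)
    reg <- data.frame(cell_group_name = mc$group_id,
                      cnv_name = mc$cnv_name,
                      state = mc$state,
                      chr = paste0("chr",
                                   as.character(GenomicRanges::seqnames(regions))),
                      start = GenomicRanges::start(regions),
                      end = GenomicRanges::end(regions))
    utils::write.table(reg, regionsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    grp <- data.frame(
        cell_group_name = rep(names(groupings), lengths(groupings)),
        cell = unlist(groupings, use.names = FALSE))
    utils::write.table(grp, groupingsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(regionsPath, groupingsPath))
}
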