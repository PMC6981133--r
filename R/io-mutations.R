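#' Read a driver-mutation table
#'
#' Reads a TSV with columns \code{gene} and \code{vaf} holding bulk
#' variant allele frequencies, either as fractions in [0, 1] or as
#' percentages, and returns the standard mutation record frame used by
#' [correctVAFs()] and [assignMutations()].
#'
#' @param path path to the TSV (header required).
#' @param unit \code{"fraction"} (default) or \code{"percent"}; percent
#'   values are divided by 100 on input.
#' @return data.frame with columns \code{gene}, \code{raw_vaf},
#'   \code{corrected_vaf} (NA until corrected), \code{expected_pct} (NA),
#'   \code{node} (NA), \code{starred} (FALSE).
#' @export
readMutationTable <- function(path, unit = c("fraction", "percent")) {
    unit <- match.arg(unit)
    if (!file.exists(path))
        stop("mutation file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("gene", "vaf") %in% colnames(df)))
        stop("mutation file must have columns gene, vaf")
    vaf <- as.numeric(df$vaf)
    if (unit == "percent") vaf <- vaf / 100
    if (anyNA(vaf) || any(vaf < 0 | vaf > 1))
        stop("VAF outside [0, 1] after unit conversion")
    mutationRecords(df$gene, vaf)
}

mutationRecords <- function(gene, raw_vaf) {
    n <- length(gene)
    data.frame(gene = as.character(gene), raw_vaf = as.numeric(raw_vaf),
               corrected_vaf = rep(NA_real_, n),
               expected_pct = rep(NA_real_, n),
               node = rep(NA_character_, n), starred = rep(FALSE, n),
               stringsAsFactors = FALSE)
}

#' Write a mutation table in the format readMutationTable() reads
#'
#' @param records mutation record data.frame.
#' @param path output path.
#' @param unit write VAFs as fractions or percentages.
#' @return invisibly, \code{path}.
#' @export
writeMutationTable <- function(records, path,
                               unit = c("fraction", "percent")) {
    unit <- match.arg(unit)
    vaf <- if (unit == "percent") records$raw_vaf * 100 else records$raw_vaf
    utils::write.table(data.frame(gene = records$gene, vaf = vaf),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write the mutation-assignment report
#'
#' One row per mutation: gene, raw and corrected VAF, the expected clone
#' percentage under the heterozygous-diploid assumption, and the assigned
#' node id or \code{"*"} for mutations that could not be attributed to a
#' specific branch.
#'
#' @param tree a \linkS4class{CloneTree} after [assignMutations()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMutationReport <- function(tree, path) {
    m <- treeMutations(tree)
    out <- data.frame(gene = m$gene, raw_vaf = m$raw_vaf,
                      corrected_vaf = m$corrected_vaf,
                      expected_pct = m$expected_pct,
                      node = ifelse(m$starred | is.na(m$node), "*", m$node))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
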