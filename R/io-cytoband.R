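#' Read a UCSC cytoBand.txt file
#'
#' Parses the 5-column tab-separated UCSC cytoband layout (chrom, start, end,
#' band, Giemsa stain) into a \linkS4class{CytobandTable}. File coordinates
#' are 0-based half-open, the UCSC convention. Chromosome names are
#' normalized (leading \code{"chr"} stripped); per chromosome the p/q arm
#' boundary is taken as the start of the first q band. Chromosomes lacking a
#' p or q band (such as the mitochondrial genome) are retained but flagged
#' as not arm-callable.
#'
#' @param path path to a cytoBand-style TSV (no header).
#' @return a \linkS4class{CytobandTable}.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr3\t0\t90000000\tp21\tgneg",
#'              "chr3\t90000000\t96000000\tp11\tacen",
#'              "chr3\t96000000\t99000000\tq11\tacen",
#'              "chr3\t99000000\t198000000\tq21\tgneg"), f)
#' cb <- readCytoband(f)
#' armBoundaries(cb)   # chr3 boundary at 96000000
#' @export
readCytoband <- function(path) {
    if (!file.exists(path))
        stop("cytoband file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        return(cytobandFromFields(data.frame(chrom = character(),
                                             start = numeric(),
                                             end = numeric(),
                                             band = character(),
                                             stain = character())))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4L))
        stop("malformed cytoband line ", which(nf < 4L)[1], ": expected ",
             "5 tab-separated columns")
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(start) || anyNA(end))
        stop("malformed cytoband line ",
             which(is.na(start) | is.na(end))[1], ": non-numeric coordinates")
    df <- data.frame(
        chrom = normalizeChrom(vapply(fields, `[`, "", 1L)),
        start = start, end = end,
        band = vapply(fields, `[`, "", 4L),
        stain = vapply(fields, function(f) if (length(f) >= 5L) f[5L] else "",
                       ""),
        stringsAsFactors = FALSE)
    cytobandFromFields(df)
}

## df has 0-based half-open start/end, normalized chrom
cytobandFromFields <- function(df) {
    o <- order(df$chrom, df$start, method = "radix")
    df <- df[o, , drop = FALSE]
    chroms <- unique(df$chrom)
    boundary <- chromLen <- setNames(rep(NA_real_, length(chroms)), chroms)
    armOK <- setNames(logical(length(chroms)), chroms)
    for (ch in chroms) {
        sub <- df[df$chrom == ch, , drop = FALSE]
        if (any(sub$start[-1] < sub$end[-nrow(sub)]))
            stop("overlapping cytobands on chromosome ", ch)
        if (sub$start[1] != 0 ||
            (nrow(sub) > 1L && any(sub$start[-1] != sub$end[-nrow(sub)])))
            stop("cytobands on chromosome ", ch,
                 " are not contiguous from 0")
        chromLen[[ch]] <- max(sub$end)
        hasP <- any(startsWith(sub$band, "p"))
        qIdx <- which(startsWith(sub$band, "q"))
        if (length(qIdx)) boundary[[ch]] <- min(sub$start[qIdx])
        armOK[[ch]] <- hasP && length(qIdx) > 0L && ch %in% .ARM_CHROMS
    }
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1, df$end),
                                 band = df$band, stain = df$stain)
    new("CytobandTable", bands = gr, armBoundary = boundary,
        chromLength = chromLen, armOK = armOK)
}

#' Write a CytobandTable back to UCSC cytoBand.txt layout
#'
#' Coordinates are emitted 0-based half-open with a \code{"chr"} prefix, so
#' a written file re-parses to an identical table.
#'
#' @param x a \linkS4class{CytobandTable}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCytoband <- function(x, path) {
    b <- x@bands
    chrom <- as.character(GenomicRanges::seqnames(b))
    pfx <- ifelse(chrom == "M", "chrM", paste0("chr", chrom))
    lines <- sprintf("%s\t%d\t%d\t%s\t%s", pfx,
                     as.integer(GenomicRanges::start(b) - 1),
                     as.integer(GenomicRanges::end(b)),
                     S4Vectors::mcols(b)$band, S4Vectors::mcols(b)$stain)
    writeLines(lines, path)
    invisible(path)
}
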