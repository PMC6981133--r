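#' Assign a CNV region to chromosome arms
#'
#' Computes the overlap of a region with the p and q arms of its
#' chromosome. The arm boundary is the start of the first q band; the
#' region is clipped to the chromosome. Input coordinates are 1-based
#' closed (the region-table convention); overlap lengths are reported in
#' bases. A region entirely on one arm yields one row; a
#' centromere-spanning region yields two. Mitochondrial regions are
#' skipped (zero rows, with a message): mitochondrial CNVs are excluded
#' from arm-level analysis.
#'
#' @param bands a \linkS4class{CytobandTable}.
#' @param chrom chromosome name (with or without \code{"chr"} prefix).
#' @param start,end 1-based closed region coordinates.
#' @return data.frame with columns \code{arm} (e.g. \code{"3q"}),
#'   \code{overlap} (bases), \code{armLength} (bases), \code{fraction}
#'   (overlap / arm length).
#' @examples
#' cb <- simulateCytoband()
#' assignArm(cb, "chr3", 1, chromLengths(cb)[["3"]])
#' @export
assignArm <- function(bands, chrom, start, end) {
    stopifnot(is(bands, "CytobandTable"))
    chrom <- normalizeChrom(chrom)
    empty <- data.frame(arm = character(), overlap = numeric(),
                        armLength = numeric(), fraction = numeric())
    if (chrom == "M") {
        message("skipping mitochondrial region (excluded from arm calling)")
        return(empty)
    }
    if (!chrom %in% names(bands@chromLength))
        stop("chromosome ", chrom, " absent from cytoband table")
    if (!bands@armOK[[chrom]])
        stop("chromosome ", chrom, " has no usable p/q arm boundary")
    if (start > end) stop("region start > end")
    boundary <- bands@armBoundary[[chrom]]
    len <- bands@chromLength[[chrom]]
    s0 <- max(start - 1, 0)       # to 0-based half-open, clipped
    e0 <- min(end, len)
    out <- empty
    pOv <- min(e0, boundary) - s0
    if (pOv > 0)
        out <- rbind(out, data.frame(arm = paste0(chrom, "p"), overlap = pOv,
                                     armLength = boundary,
                                     fraction = pOv / boundary))
    qOv <- e0 - max(s0, boundary)
    if (qOv > 0)
        out <- rbind(out, data.frame(arm = paste0(chrom, "q"), overlap = qOv,
                                     armLength = len - boundary,
                                     fraction = qOv / (len - boundary)))
    out
}

#' Convert CNV region calls to deduplicated arm-level events per subclone
#'
#' Each region with a loss state (1-2) contributes a loss and each region
#' with a gain state (4-6) a gain on every arm it overlaps by at least
#' \code{minArmOverlap} of the arm length; neutral regions (state 3)
#' contribute nothing. Mitochondrial regions are excluded. Events are
#' deduplicated per group; when a group accumulates both a gain and a loss
#' on the same arm, the direction with the greater total overlapped length
#' wins (ties keep both, with a warning). Groups present in the groupings
#' table but without regions yield subclones with empty event sets
#' (CNV-free cells).
#'
#' @param regions \linkS4class{GRanges} of region calls with metadata
#'   columns \code{group_id} and \code{state} (see [readCNVCalls()]).
#' @param groupings named list mapping group ids to cell barcodes.
#' @param bands a \linkS4class{CytobandTable}.
#' @param minArmOverlap minimum overlap as a fraction of the arm length for
#'   an arm event to be called; the default 0 means any positive overlap.
#' @return a \linkS4class{SubcloneEvents} with one entry per group.
#' @export
regionsToArmEvents <- function(regions, groupings, bands,
                               minArmOverlap = 0) {
    mc <- S4Vectors::mcols(regions)
    unknown <- setdiff(unique(mc$group_id), names(groupings))
    if (length(unknown))
        stop("region group(s) absent from groupings: ",
             paste(unknown, collapse = ", "))
    chrom <- normalizeChrom(as.character(GenomicRanges::seqnames(regions)))
    starts <- GenomicRanges::start(regions)
    ends <- GenomicRanges::end(regions)
    nMito <- sum(chrom == "M")
    if (nMito > 0)
        message(nMito, " mitochondrial region(s) excluded from arm calling")
    groupNames <- sort(names(groupings))
    evSets <- vector("list", length(groupNames))
    names(evSets) <- groupNames
    for (g in groupNames) evSets[[g]] <- list(gain = list(), loss = list())
    for (i in seq_along(regions)) {
        if (chrom[i] == "M") next
        st <- mc$state[i]
        if (st == 3L) next
        dir <- if (st < 3L) "loss" else "gain"
        ov <- assignArm(bands, chrom[i], starts[i], ends[i])
        ov <- ov[ov$fraction >= minArmOverlap & ov$overlap > 0, , drop = FALSE]
        g <- mc$group_id[i]
        for (j in seq_len(nrow(ov))) {
            arm <- ov$arm[j]
            prev <- evSets[[g]][[dir]][[arm]]
            evSets[[g]][[dir]][[arm]] <-
                if (is.null(prev)) ov$overlap[j] else prev + ov$overlap[j]
        }
    }
    events <- vector("list", length(groupNames))
    for (k in seq_along(groupNames)) {
        g <- groupNames[k]
        gains <- evSets[[g]]$gain
        losses <- evSets[[g]]$loss
        both <- intersect(names(gains), names(losses))
        for (arm in both) {
            if (gains[[arm]] > losses[[arm]]) {
                losses[[arm]] <- NULL
            } else if (losses[[arm]] > gains[[arm]]) {
                gains[[arm]] <- NULL
            } else {
                warning("group ", g, ": gain and loss on arm ", arm,
                        " with equal overlapped length; keeping both")
            }
        }
        ev <- c(if (length(gains)) makeEvent(names(gains), "gain"),
                if (length(losses)) makeEvent(names(losses), "loss"))
        events[[k]] <- normalizeEventSet(ev)
    }
    SubcloneEvents(groupId = groupNames, events = events,
                   cells = groupings[groupNames])
}

#' Write per-subclone arm events as a TSV
#'
#' Columns: \code{group_id}, \code{arm}, \code{direction}, \code{n_cells}.
#' Groups with empty event sets are omitted (they carry no alterations).
#'
#' @param subclones a \linkS4class{SubcloneEvents}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeArmEvents <- function(subclones, path) {
    rows <- list()
    for (i in seq_len(length(subclones))) {
        ev <- subclones@events[[i]]
        if (length(ev) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
            group_id = subclones@groupId[i], arm = eventArm(ev),
            direction = eventDirection(ev),
            n_cells = length(subclones@cells[[i]]))
    }
    out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(group_id = character(), arm = character(),
                    direction = character(), n_cells = integer())
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
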