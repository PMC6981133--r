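#' Collapse subclones with identical arm-level event sets
#'
#' Groups whose event sets are set-equal are merged into one subclone with
#' the union of their cells. Output order is canonical: ascending event-set
#' size, then lexicographic on the joined event labels; merged groups take
#' the event-set string as their id (\code{"root"} for the empty set).
#' The operation is idempotent.
#'
#' @param subclones a \linkS4class{SubcloneEvents}.
#' @return a \linkS4class{SubcloneEvents} with distinct event sets.
#' @examples
#' s <- SubcloneEvents(c("A", "B"),
#'                     list("8q_gain", "8q_gain"),
#'                     list(paste0("a", 1:30), paste0("b", 1:20)))
#' collapseSubclones(s)   # one subclone, 50 cells
#' @export
collapseSubclones <- function(subclones) {
    n <- length(subclones)
    keys <- vapply(seq_len(n), function(i)
        eventSetId(subclones@events[[i]]), "")
    uq <- unique(keys)
    events <- lapply(uq, function(k)
        subclones@events[[match(k, keys)]])
    cells <- lapply(uq, function(k)
        unlist(subclones@cells[keys == k], use.names = FALSE))
    o <- order(lengths(events),
               vapply(events, paste, "", collapse = "+"), method = "radix")
    SubcloneEvents(groupId = uq[o], events = events[o], cells = cells[o])
}

#' Reconstruct the nested clone tree from collapsed subclones
#'
#' Subclones are ordered by event-set size and attached, each, to the
#' deepest existing node whose cumulative event set is a strict subset of
#' the subclone's set; among equally deep candidates the tie is broken
#' lexicographically on the node id. The root carries no events and
#' represents the ancestral state; a subclone with an empty event set maps
#' onto it, and cells not covered by any subclone (\code{totalCells} minus
#' assigned cells) also count at the root, so the root's inclusive
#' percentage is exactly 100. Each node's inclusive percentage is
#' \code{100 * (cells at the node and all its descendants) / totalCells}.
#'
#' The same event appearing on two incomparable branches (homoplasy) is
#' permitted but reported with a warning.
#'
#' @param subclones a \linkS4class{SubcloneEvents} with distinct event sets
#'   (see [collapseSubclones()]; duplicates raise an error).
#' @param totalCells denominator: all tumor cells entering the CNV
#'   analysis. Must be at least the number of cells in \code{subclones}.
#' @param minFraction optional noise-pruning threshold: subclones holding
#'   fewer than \code{minFraction * totalCells} cells do not become nodes;
#'   their cells are counted at the deepest node whose cumulative set is
#'   contained in theirs. The default 0 keeps every subclone.
#' @return a \linkS4class{CloneTree}.
#' @examples
#' s <- SubcloneEvents(c("A", "B"),
#'                     list("3q_loss", c("3p_loss", "3q_loss")),
#'                     list(paste0("a", 1:170), paste0("b", 1:60)))
#' tr <- buildCloneTree(s, totalCells = 1000)
#' inclusivePercentage(tr)   # root 100, 3q_loss 23, 3p_loss+3q_loss 6
#' @export
buildCloneTree <- function(subclones, totalCells, minFraction = 0) {
    totalCells <- as.integer(totalCells)
    n <- length(subclones)
    keys <- vapply(seq_len(n), function(i)
        eventSetId(subclones@events[[i]]), "")
    if (anyDuplicated(keys))
        stop("duplicate event sets; run collapseSubclones() first")
    if (sum(lengths(subclones@cells)) > totalCells)
        stop("totalCells smaller than the number of cells in subclones")
    sizes <- lengths(subclones@events)
    lbl <- vapply(seq_len(n), function(i)
        paste(subclones@events[[i]], collapse = "+"), "")
    ord <- order(sizes, lbl, method = "radix")
    minCells <- minFraction * totalCells

    ids <- "root"
    parents <- NA_character_
    added <- list(character())
    cumul <- list(character())
    cellsL <- list(character())
    deferred <- integer()

    for (i in ord) {
        ev <- subclones@events[[i]]
        cl <- as.character(subclones@cells[[i]])
        if (length(ev) == 0L) {              # CNV-free subclone -> root
            cellsL[[1L]] <- c(cellsL[[1L]], cl)
            next
        }
        if (length(cl) < minCells) {
            deferred <- c(deferred, i)
            next
        }
        compat <- which(vapply(cumul, function(s)
            length(s) < length(ev) && all(s %in% ev), TRUE))
        depth <- lengths(cumul)[compat]
        best <- compat[depth == max(depth)]
        if (length(best) > 1L)
            best <- best[order(ids[best], method = "radix")[1L]]
        parentIdx <- best[1L]
        k <- length(ids) + 1L
        ids[k] <- eventSetId(ev)
        parents[k] <- ids[parentIdx]
        cumul[[k]] <- normalizeEventSet(ev)
        added[[k]] <- sort(setdiff(ev, cumul[[parentIdx]]))
        cellsL[[k]] <- cl
    }

    ## cells of pruned subclones fall back to their deepest compatible node
    for (i in deferred) {
        ev <- subclones@events[[i]]
        compat <- which(vapply(cumul, function(s)
            length(s) <= length(ev) && all(s %in% ev), TRUE))
        depth <- lengths(cumul)[compat]
        best <- compat[depth == max(depth)]
        if (length(best) > 1L)
            best <- best[order(ids[best], method = "radix")[1L]]
        cellsL[[best[1L]]] <- c(cellsL[[best[1L]]],
                                as.character(subclones@cells[[i]]))
    }

    nCells <- lengths(cellsL)
    nCells[1L] <- nCells[1L] + (totalCells - sum(nCells))

    ## inclusive counts: node + all descendants
    inclusive <- nCells
    for (k in rev(seq_along(ids))) {
        if (!is.na(parents[k])) {
            p <- match(parents[k], ids)
            inclusive[p] <- inclusive[p] + inclusive[k]
        }
    }

    ## homoplasy: same event added on more than one branch
    allAdded <- unlist(added, use.names = FALSE)
    dup <- unique(allAdded[duplicated(allAdded)])
    if (length(dup))
        warning("homoplasy: event(s) arising on multiple branches: ",
                paste(dup, collapse = ", "))

    nd <- S4Vectors::DataFrame(
        id = ids, parent = parents,
        addedEvents = IRanges::CharacterList(added),
        cumulativeEvents = IRanges::CharacterList(cumul),
        cells = IRanges::CharacterList(cellsL),
        nCells = as.integer(nCells),
        inclusivePercentage = 100 * inclusive / totalCells)
    new("CloneTree", nodes = nd,
        mutations = mutationRecords(character(), numeric()),
        totalCells = totalCells)
}
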