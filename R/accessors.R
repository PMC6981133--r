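#' @importFrom S4Vectors mcols
NULL

## ---- CytobandTable ---------------------------------------------------------

#' @describeIn CytobandTable-class band intervals as a GRanges.
#' @param x a \linkS4class{CytobandTable}.
#' @export
bandRanges <- function(x) x@bands

#' @describeIn CytobandTable-class named vector of 0-based p/q arm boundaries
#'   (start of the first q band); NA where no q band exists.
#' @export
armBoundaries <- function(x) x@armBoundary

#' @describeIn CytobandTable-class named vector of chromosome lengths.
#' @export
chromLengths <- function(x) x@chromLength

#' @describeIn CytobandTable-class named logical: which chromosomes are
#'   eligible for arm-level calling (both arms present, not mitochondrial).
#' @export
armCallable <- function(x) x@armOK

setMethod("show", "CytobandTable", function(object) {
    cat("CytobandTable with", length(object@bands), "bands on",
        length(object@chromLength), "chromosomes\n")
    cat("  arm-callable:", sum(object@armOK), "of", length(object@armOK),
        "chromosomes\n")
})

## ---- SubcloneEvents ---------------------------------------------------------

#' Construct a SubcloneEvents collection
#'
#' @param groupId character vector of group labels.
#' @param events list (or CharacterList) of arm-event sets, one per group;
#'   each set is deduplicated and sorted.
#' @param cells list (or CharacterList) of cell barcodes, one per group.
#' @return a \linkS4class{SubcloneEvents} object.
#' @examples
#' SubcloneEvents("cloneA", list("8q_gain"), list(c("cell1", "cell2")))
#' @export
SubcloneEvents <- function(groupId = character(), events = list(),
                           cells = list()) {
    events <- IRanges::CharacterList(lapply(events, normalizeEventSet))
    cells <- IRanges::CharacterList(lapply(cells, as.character))
    new("SubcloneEvents", groupId = as.character(groupId), events = events,
        cells = cells)
}

#' @describeIn SubcloneEvents-class group labels.
#' @param x a \linkS4class{SubcloneEvents}.
#' @export
groupIds <- function(x) x@groupId

#' @describeIn SubcloneEvents-class arm-event sets as a CharacterList.
#' @export
eventSets <- function(x) x@events

#' @describeIn SubcloneEvents-class cell-barcode sets as a CharacterList.
#' @export
cellSets <- function(x) x@cells

setMethod("length", "SubcloneEvents", function(x) length(x@groupId))

setMethod("[", "SubcloneEvents", function(x, i, j, ..., drop = TRUE) {
    new("SubcloneEvents", groupId = x@groupId[i], events = x@events[i],
        cells = x@cells[i])
})

setMethod("show", "SubcloneEvents", function(object) {
    cat("SubcloneEvents with", length(object), "subclone(s)\n")
    n <- min(length(object), 10L)
    for (i in seq_len(n)) {
        cat(sprintf("  %s: {%s} [%d cells]\n", object@groupId[i],
                    paste(object@events[[i]], collapse = ", "),
                    length(object@cells[[i]])))
    }
    if (length(object) > n) cat("  ...\n")
})

## ---- CloneTree --------------------------------------------------------------

#' @describeIn CloneTree-class node table (DataFrame; one row per node).
#' @param x a \linkS4class{CloneTree}.
#' @export
treeNodes <- function(x) x@nodes

#' @describeIn CloneTree-class number of nodes including the root.
#' @export
nNodes <- function(x) nrow(x@nodes)

#' @describeIn CloneTree-class denominator used for percentages.
#' @export
totalCells <- function(x) x@totalCells

#' @describeIn CloneTree-class named numeric of inclusive percentages.
#' @export
inclusivePercentage <- function(x)
    setNames(x@nodes$inclusivePercentage, x@nodes$id)

#' @describeIn CloneTree-class CharacterList of events added on the branch
#'   into each node.
#' @export
addedEvents <- function(x) setNames(x@nodes$addedEvents, x@nodes$id)

#' @describeIn CloneTree-class CharacterList of cumulative event sets.
#' @export
cumulativeEvents <- function(x) setNames(x@nodes$cumulativeEvents, x@nodes$id)

#' @describeIn CloneTree-class CharacterList of cell barcodes whose full
#'   event set equals each node's cumulative set.
#' @export
nodeCells <- function(x) setNames(x@nodes$cells, x@nodes$id)

#' @describeIn CloneTree-class data.frame of attributed mutations.
#' @export
treeMutations <- function(x) x@mutations

#' @describeIn CloneTree-class id of the root node.
#' @export
rootId <- function(x) x@nodes$id[is.na(x@nodes$parent)]

#' @describeIn CloneTree-class children ids of a node.
#' @param node node id.
#' @export
childIds <- function(x, node)
    x@nodes$id[!is.na(x@nodes$parent) & x@nodes$parent == node]

setMethod("show", "CloneTree", function(object) {
    nd <- object@nodes
    cat("CloneTree:", nrow(nd), "node(s),", object@totalCells,
        "tumor cells\n")
    printNode <- function(id, depth) {
        i <- match(id, nd$id)
        lbl <- if (length(nd$addedEvents[[i]]) == 0L) "root"
               else paste(nd$addedEvents[[i]], collapse = "+")
        cat(sprintf("  %s%s (%.1f%%, %d cells)\n",
                    strrep("  ", depth), lbl, nd$inclusivePercentage[i],
                    nd$nCells[i]))
        for (ch in childIds(object, id)) printNode(ch, depth + 1L)
    }
    printNode(rootId(object), 0L)
    if (nrow(object@mutations) > 0L) {
        m <- object@mutations
        cat("  mutations:",
            paste(sprintf("%s->%s%s", m$gene,
                          ifelse(is.na(m$node), "root", m$node),
                          ifelse(m$starred, "*", "")), collapse = ", "), "\n")
    }
})

setMethod("show", "TreeLayout", function(object) {
    cat(sprintf("TreeLayout: %d circle(s), %d edge(s), canvas %.0fx%.0f px\n",
                nrow(object@nodes), nrow(object@edges), object@width,
                object@height))
})

setMethod("show", "SimulationSpec", function(object) {
    cat("SimulationSpec:", nrow(object@tree), "subclone node(s),",
        object@nCells, "cells\n")
    cat(sprintf("  fp=%.3g fn=%.3g purity=%.2f depth=%d seed=%d\n",
                object@fpRate, object@fnRate, object@purity, object@depth,
                object@seed))
})
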