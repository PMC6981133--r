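#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom IRanges CharacterList
NULL

#' CytobandTable: chromosome band intervals with arm boundaries
#'
#' Holds UCSC-style cytoband records and, per chromosome, the p/q arm
#' boundary (the start of the first q band, 0-based) and the chromosome
#' length. Chromosomes lacking both a p and a q band (e.g. the mitochondrial
#' genome) are parsed but flagged as unusable for arm-level calls.
#'
#' Band coordinates are stored as a \linkS4class{GRanges} in the usual
#' 1-based closed convention; the source file's 0-based half-open coordinates
#' are converted on input and restored on output. Internally all interval
#' arithmetic for arm assignment uses 0-based half-open coordinates.
#'
#' @slot bands \linkS4class{GRanges} of band intervals with metadata columns
#'   \code{band} and \code{stain}.
#' @slot armBoundary named numeric, 0-based position of the first q-band
#'   start per chromosome (NA when no q band exists).
#' @slot chromLength named numeric, chromosome lengths in bases.
#' @slot armOK named logical, whether the chromosome has both arms and is
#'   eligible for arm-level calling.
#'
#' @seealso [readCytoband()], [assignArm()]
#' @export
setClass("CytobandTable",
    slots = c(bands = "GRanges", armBoundary = "numeric",
              chromLength = "numeric", armOK = "logical"))

setValidity("CytobandTable", function(object) {
    b <- object@bands
    chroms <- names(object@armBoundary)
    if (!identical(chroms, names(object@chromLength)) ||
        !identical(chroms, names(object@armOK)))
        return("armBoundary, chromLength and armOK must share names")
    for (ch in chroms) {
        sel <- as.character(GenomicRanges::seqnames(b)) == ch
        s0 <- GenomicRanges::start(b)[sel] - 1   # back to 0-based half-open
        e0 <- GenomicRanges::end(b)[sel]
        o <- order(s0)
        s0 <- s0[o]; e0 <- e0[o]
        if (length(s0) == 0L) return(paste0("chromosome ", ch, " has no bands"))
        if (s0[1] != 0)
            return(paste0("bands on ", ch, " do not start at 0"))
        if (any(e0 <= s0))
            return(paste0("empty band interval on ", ch))
        if (length(s0) > 1L && any(s0[-1] != e0[-length(e0)]))
            return(paste0("bands on ", ch, " overlap or leave gaps"))
        if (max(e0) != object@chromLength[[ch]])
            return(paste0("chromLength mismatch on ", ch))
    }
    TRUE
})

#' SubcloneEvents: deduplicated arm-level events per subclone
#'
#' A parallel collection of subclones: group identifier, the set of
#' arm-level events (strings like \code{"8q_gain"}), and the cell barcodes
#' belonging to the group. Event sets are stored sorted and deduplicated.
#'
#' @slot groupId character vector of unique group labels.
#' @slot events [IRanges::CharacterList] of arm-event sets, parallel to
#'   \code{groupId}.
#' @slot cells [IRanges::CharacterList] of cell barcodes, parallel to
#'   \code{groupId}.
#'
#' @seealso [regionsToArmEvents()], [collapseSubclones()]
#' @export
setClass("SubcloneEvents",
    slots = c(groupId = "character", events = "CharacterList",
              cells = "CharacterList"))

setValidity("SubcloneEvents", function(object) {
    n <- length(object@groupId)
    if (length(object@events) != n || length(object@cells) != n)
        return("groupId, events and cells must have equal length")
    if (anyDuplicated(object@groupId))
        return("duplicated group ids")
    ev <- as.list(object@events)
    for (i in seq_len(n)) {
        e <- ev[[i]]
        if (anyDuplicated(e)) return("event sets must be deduplicated")
        if (length(e) && any(!grepl(.EVENT_RE, e)))
            return(paste0("invalid event label in group ", object@groupId[i]))
    }
    if (n > 0 && any(lengths(object@cells) == 0L))
        return("every subclone must contain at least one cell")
    allCells <- unlist(object@cells, use.names = FALSE)
    if (anyDuplicated(allCells))
        return("cell barcodes must be unique across subclones")
    TRUE
})

#' CloneTree: nested intra-tumor evolutionary tree of subclones
#'
#' A rooted tree whose root represents the ancestral (CNV-free) state. Each
#' node carries the arm events added on the branch leading into it, the
#' cells whose full event set equals the node's cumulative set, and an
#' inclusive percentage: the percentage of all tumor cells at the node or
#' any of its descendants. Node ids are the "+"-joined cumulative event set
#' (the root is \code{"root"}), so ids are unique and self-describing.
#'
#' @slot nodes [S4Vectors::DataFrame] with columns \code{id}, \code{parent}
#'   (NA for root), \code{addedEvents} and \code{cumulativeEvents}
#'   (CharacterList), \code{cells} (CharacterList), \code{nCells} (integer),
#'   \code{inclusivePercentage} (numeric).
#' @slot mutations data.frame of attributed mutations (columns \code{gene},
#'   \code{raw_vaf}, \code{corrected_vaf}, \code{expected_pct}, \code{node},
#'   \code{starred}); zero rows until [assignMutations()] is run.
#' @slot totalCells integer, denominator for percentages (all tumor cells
#'   entering the CNV analysis, including CNV-free cells at the root).
#'
#' @seealso [buildCloneTree()], [layoutTree()], [writeCloneTreeNewick()]
#' @export
setClass("CloneTree",
    slots = c(nodes = "DataFrame", mutations = "data.frame",
              totalCells = "integer"))

setValidity("CloneTree", function(object) {
    nd <- object@nodes
    need <- c("id", "parent", "addedEvents", "cumulativeEvents", "cells",
              "nCells", "inclusivePercentage")
    if (!all(need %in% colnames(nd)))
        return(paste("nodes must have columns:", paste(need, collapse = ", ")))
    if (nrow(nd) == 0L) return("tree must at least contain a root")
    if (anyDuplicated(nd$id)) return("node ids must be unique")
    rootIdx <- which(is.na(nd$parent))
    if (length(rootIdx) != 1L) return("exactly one root (parent NA) required")
    if (length(nd$addedEvents[[rootIdx]]) != 0L)
        return("root must carry no events")
    if (!all(nd$parent[-rootIdx] %in% nd$id))
        return("parent ids must reference existing nodes")
    if (object@totalCells < sum(nd$nCells))
        return("totalCells smaller than the number of assigned cells")
    tol <- 1e-8
    if (abs(nd$inclusivePercentage[rootIdx] - 100) > tol)
        return("root inclusive percentage must be 100")
    idx <- setNames(seq_len(nrow(nd)), nd$id)
    for (i in seq_len(nrow(nd))[-rootIdx]) {
        p <- idx[[nd$parent[i]]]
        cum <- nd$cumulativeEvents[[i]]
        pcum <- nd$cumulativeEvents[[p]]
        if (!all(pcum %in% cum) || length(cum) <= length(pcum))
            return("cumulative events must strictly grow along each branch")
        if (!setequal(cum, union(pcum, nd$addedEvents[[i]])))
            return("cumulative events must equal parent set plus added events")
        if (nd$inclusivePercentage[i] > nd$inclusivePercentage[p] + tol)
            return("child inclusive percentage exceeds parent's")
    }
    TRUE
})

#' TreeLayout: pixel geometry for a rendered clone tree
#'
#' Circle positions and edge segments computed by [layoutTree()]. Every edge
#' segment has Euclidean length \code{scale * inclusivePercentage(child) +
#' circleDiameter + 5} pixels: branch length proportional to the percentage
#' of cells plus a spacer of one circle diameter plus 5 px.
#'
#' @slot nodes data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{diameter}.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{x1}, \code{y1}, \code{x2}, \code{y2}, \code{length}.
#' @slot width,height numeric canvas size in pixels.
#' @slot scale numeric, pixels per percentage point.
#' @slot circleDiameter numeric, node circle diameter in pixels.
#' @export
setClass("TreeLayout",
    slots = c(nodes = "data.frame", edges = "data.frame",
              width = "numeric", height = "numeric",
              scale = "numeric", circleDiameter = "numeric"))

#' SimulationSpec: ground-truth scenario for the synthetic-data generator
#'
#' Describes a clone tree (node ids, parents, added arm events, exclusive
#' cell fractions), the number of cells, per-cell per-arm false-positive and
#' false-negative region-call rates, tumor purity, sequencing depth for
#' bulk VAF sampling, and a random seed. Fractions are exclusive (cells whose
#' event set equals exactly that node's cumulative set); the remainder of the
#' cells carry no CNV and sit at the root.
#'
#' @slot tree data.frame with columns \code{node}, \code{parent} (NA for
#'   children of the root), \code{events} (list of character vectors of
#'   added arm events), \code{fraction}.
#' @slot nCells integer number of tumor cells.
#' @slot fpRate,fnRate numeric per-cell per-arm spurious / missed call
#'   probabilities.
#' @slot purity numeric tumor purity in (0, 1].
#' @slot depth integer sequencing depth for binomial VAF sampling.
#' @slot seed integer random seed; identical seeds give identical output.
#' @seealso [SimulationSpec()], [simulateCellCNVCalls()]
#' @export
setClass("SimulationSpec",
    slots = c(tree = "data.frame", nCells = "integer",
              fpRate = "numeric", fnRate = "numeric",
              purity = "numeric", depth = "integer", seed = "integer"))

setValidity("SimulationSpec", function(object) {
    tr <- object@tree
    need <- c("node", "parent", "events", "fraction")
    if (!all(need %in% colnames(tr)))
        return(paste("tree must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(tr$node)) return("duplicate node ids")
    if ("root" %in% tr$node) return("'root' is reserved for the implicit root")
    if (!all(is.na(tr$parent) | tr$parent %in% tr$node))
        return("parents must be NA (root) or existing nodes")
    if (any(tr$fraction < 0)) return("fractions must be non-negative")
    if (sum(tr$fraction) > 1 + 1e-9)
        return("fractions must sum to at most 1")
    if (any(lengths(tr$events) == 0L))
        return("every node must add at least one event")
    if (object@fpRate < 0 || object@fpRate >= 1 ||
        object@fnRate < 0 || object@fnRate >= 1)
        return("fpRate and fnRate must lie in [0, 1)")
    if (object@purity <= 0 || object@purity > 1)
        return("purity must lie in (0, 1]")
    if (object@depth < 1) return("depth must be positive")
    TRUE
})
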