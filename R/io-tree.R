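#' Serialize a CloneTree to JSON
#'
#' The JSON form is lossless: [readCloneTreeJSON()] reconstructs an
#' identical tree (node table, cell sets, mutations, denominator).
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param path output path; if NULL the JSON string is returned.
#' @return invisibly \code{path}, or the JSON string when \code{path} is
#'   NULL.
#' @export
writeCloneTreeJSON <- function(tree, path = NULL) {
    nd <- tree@nodes
    nodes <- lapply(seq_len(nrow(nd)), function(i) list(
        id = nd$id[i],
        parent = if (is.na(nd$parent[i])) NULL else nd$parent[i],
        addedEvents = as.character(nd$addedEvents[[i]]),
        cumulativeEvents = as.character(nd$cumulativeEvents[[i]]),
        cells = as.character(nd$cells[[i]]),
        nCells = nd$nCells[i],
        inclusivePercentage = nd$inclusivePercentage[i]))
    obj <- list(totalCells = tree@totalCells, nodes = nodes,
                mutations = tree@mutations)
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE)
    if (is.null(path)) return(as.character(json))
    writeLines(json, path)
    invisible(path)
}

#' Read a CloneTree from its JSON serialization
#'
#' @param path path to a JSON file written by [writeCloneTreeJSON()] (or
#'   a JSON string).
#' @return a \linkS4class{CloneTree}.
#' @export
readCloneTreeJSON <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                              simplifyVector = FALSE)
    nodes <- obj$nodes
    chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
    chrv <- function(x) as.character(unlist(x, use.names = FALSE))
    nd <- S4Vectors::DataFrame(
        id = vapply(nodes, function(n) chr1(n$id), ""),
        parent = vapply(nodes, function(n) chr1(n$parent), ""),
        addedEvents = IRanges::CharacterList(lapply(nodes, function(n)
            chrv(n$addedEvents))),
        cumulativeEvents = IRanges::CharacterList(lapply(nodes, function(n)
            chrv(n$cumulativeEvents))),
        cells = IRanges::CharacterList(lapply(nodes, function(n)
            chrv(n$cells))),
        nCells = vapply(nodes, function(n) as.integer(n$nCells), 1L),
        inclusivePercentage = vapply(nodes, function(n)
            as.numeric(n$inclusivePercentage), 1))
    mut <- obj$mutations
    mutations <- if (length(mut) == 0L) mutationRecords(character(), numeric())
    else {
        num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
        data.frame(
            gene = vapply(mut, function(m) chr1(m$gene), ""),
            raw_vaf = vapply(mut, function(m) num1(m$raw_vaf), 1),
            corrected_vaf = vapply(mut, function(m) num1(m$corrected_vaf), 1),
            expected_pct = vapply(mut, function(m) num1(m$expected_pct), 1),
            node = vapply(mut, function(m) chr1(m$node), ""),
            starred = vapply(mut, function(m) isTRUE(m$starred), TRUE),
            stringsAsFactors = FALSE)
    }
    new("CloneTree", nodes = nd, mutations = mutations,
        totalCells = as.integer(obj$totalCells))
}

## canonical child ordering shared by Newick and the SVG layout:
## descending inclusive percentage, ties by added-event label
orderedChildren <- function(tree, node) {
    kids <- childIds(tree, node)
    if (length(kids) < 2L) return(kids)
    nd <- tree@nodes
    i <- match(kids, nd$id)
    lbl <- vapply(nd$addedEvents[i], paste, "", collapse = "+")
    kids[order(-nd$inclusivePercentage[i], lbl, method = "radix")]
}

#' Serialize a CloneTree to Newick
#'
#' Branch lengths encode inclusive percentages; node labels are the
#' "+"-joined arm events added on the branch into the node (Newick-safe
#' tokens: underscores, no spaces), with attributed mutation genes appended
#' and a trailing \code{"*"} marking starred mutations listed at the root.
#' A root-only tree serializes as \code{"root:100;"}.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param path optional output path; if NULL the Newick string is returned.
#' @return invisibly \code{path}, or the Newick string.
#' @export
writeCloneTreeNewick <- function(tree, path = NULL) {
    nd <- tree@nodes
    m <- tree@mutations
    label <- function(id) {
        i <- match(id, nd$id)
        base <- if (length(nd$addedEvents[[i]]) == 0L) "root"
                else paste(nd$addedEvents[[i]], collapse = "+")
        if (nrow(m) > 0L) {
            if (id == rootId(tree)) {
                genes <- m$gene[m$starred]
                if (length(genes))
                    base <- paste(c(base, paste0(genes, "*")), collapse = "+")
            } else {
                genes <- m$gene[!m$starred & !is.na(m$node) & m$node == id]
                if (length(genes))
                    base <- paste(c(base, genes), collapse = "+")
            }
        }
        base
    }
    recurse <- function(id) {
        i <- match(id, nd$id)
        kids <- orderedChildren(tree, id)
        inner <- if (length(kids))
            paste0("(", paste(vapply(kids, recurse, ""), collapse = ","), ")")
        else ""
        sprintf("%s%s:%g", inner, label(id), nd$inclusivePercentage[i])
    }
    nwk <- paste0(recurse(rootId(tree)), ";")
    if (is.null(path)) return(nwk)
    writeLines(nwk, path)
    invisible(path)
}
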