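## sibling fan-out schedule, degrees relative to the parent edge direction:
## the first child continues straight, later siblings alternate sides at
## widening angles
.angleOffset <- function(k) {
    if (k == 1L) return(0)
    j <- (k - 2L) %/% 2L        # 0, 0, 1, 1, 2, 2, ...
    a <- 40 + 25 * j
    if (k %% 2L == 0L) a else -a
}

#' Compute the pixel layout of a clone tree
#'
#' Places the root at the top-center of the canvas with the trunk drawn
#' vertically downward. Each node's children are sorted by descending
#' inclusive percentage (ties broken lexicographically on the added-event
#' labels) and fanned at deterministic angle offsets relative to the
#' parent edge direction (straight, then +40, -40, +65, -65, ... degrees).
#' Every edge's Euclidean length is exactly
#' \code{scale * inclusivePercentage(child) + circleDiameter + 5} pixels:
#' branch length proportional to the percentage of cells plus a spacer of
#' one circle diameter plus 5 px. Identical input yields an identical
#' layout.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param scale pixels per percentage point.
#' @param circleDiameter node circle diameter in pixels.
#' @param padding canvas padding in pixels.
#' @return a \linkS4class{TreeLayout}.
#' @examples
#' s <- SubcloneEvents("A", list("8q_gain"), list(paste0("c", 1:50)))
#' lay <- layoutTree(buildCloneTree(s, 100))
#' lay@edges$length   # 2 * 50 + 10 + 5 = 115
#' @export
layoutTree <- function(tree, scale = 2.0, circleDiameter = 10.0,
                       padding = 20) {
    nd <- tree@nodes
    pos <- matrix(0, nrow(nd), 2, dimnames = list(nd$id, c("x", "y")))
    edges <- list()
    recurse <- function(id, angle) {
        kids <- orderedChildren(tree, id)
        for (k in seq_along(kids)) {
            child <- kids[k]
            th <- (angle + .angleOffset(k)) * pi / 180
            ci <- match(child, nd$id)
            len <- scale * nd$inclusivePercentage[ci] + circleDiameter + 5
            p <- unname(pos[id, ])
            q <- p + len * c(sin(th), cos(th))
            pos[child, ] <<- q
            edges[[length(edges) + 1L]] <<- data.frame(
                parent = id, child = child, x1 = p[1], y1 = p[2],
                x2 = q[1], y2 = q[2], length = len)
            recurse(child, angle + .angleOffset(k))
        }
    }
    recurse(rootId(tree), 0)
    edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(parent = character(), child = character(),
                    x1 = numeric(), y1 = numeric(), x2 = numeric(),
                    y2 = numeric(), length = numeric())
    r <- circleDiameter / 2
    shift <- c(padding + r - min(pos[, 1] - r),
               padding + r - min(pos[, 2] - r))
    pos <- sweep(pos, 2, shift, "+")
    if (nrow(edges)) {
        edges$x1 <- edges$x1 + shift[1]; edges$x2 <- edges$x2 + shift[1]
        edges$y1 <- edges$y1 + shift[2]; edges$y2 <- edges$y2 + shift[2]
    }
    nodes <- data.frame(id = nd$id, x = pos[, 1], y = pos[, 2],
                        diameter = circleDiameter, row.names = NULL)
    new("TreeLayout", nodes = nodes, edges = edges,
        width = max(pos[, 1]) + r + padding,
        height = max(pos[, 2]) + r + padding,
        scale = scale, circleDiameter = circleDiameter)
}

xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a clone-tree layout as an SVG file
#'
#' Emits well-formed SVG 1.1 with one circle per node, one line per edge,
#' and a text label per edge listing the branch's added arm events and any
#' attributed mutation genes; mutations that could not be assigned to a
#' branch are listed at the root with a literal \code{"*"}. Output is
#' byte-identical for identical inputs (fixed number formatting, no
#' timestamps).
#'
#' @param layout a \linkS4class{TreeLayout} from [layoutTree()].
#' @param tree the \linkS4class{CloneTree} the layout was computed from.
#' @param path output path; if NULL the SVG text is returned as a
#'   character vector of lines.
#' @param gepClass optional gene-expression-profile class used to tint the
#'   branches: 1 = blue, 2 = red; default black.
#' @return invisibly \code{path}, or the SVG lines when \code{path} is
#'   NULL.
#' @export
renderSVG <- function(layout, tree, path = NULL, gepClass = NULL) {
    stopifnot(identical(sort(layout@nodes$id), sort(tree@nodes$id)))
    color <- if (is.null(gepClass)) "black"
             else if (gepClass == 1) "#1f4e9c"
             else if (gepClass == 2) "#c0272d"
             else "black"
    nd <- tree@nodes
    m <- tree@mutations
    lines <- c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                       "version=\"1.1\" width=\"%s\" height=\"%s\" ",
                       "viewBox=\"0 0 %s %s\">"),
                fmtNum(layout@width), fmtNum(layout@height),
                fmtNum(layout@width), fmtNum(layout@height)))
    e <- layout@edges
    for (i in seq_len(nrow(e))) {
        lines <- c(lines, sprintf(
            paste0("  <line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                   "stroke=\"%s\" stroke-width=\"2\"/>"),
            fmtNum(e$x1[i]), fmtNum(e$y1[i]), fmtNum(e$x2[i]),
            fmtNum(e$y2[i]), color))
    }
    for (i in seq_len(nrow(layout@nodes))) {
        nl <- layout@nodes[i, ]
        lines <- c(lines, sprintf(
            paste0("  <circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" ",
                   "stroke=\"%s\"/>"),
            fmtNum(nl$x), fmtNum(nl$y), fmtNum(nl$diameter / 2), color,
            color))
    }
    for (i in seq_len(nrow(e))) {
        ci <- match(e$child[i], nd$id)
        label <- paste(nd$addedEvents[[ci]], collapse = "+")
        if (nrow(m) > 0L) {
            genes <- m$gene[!m$starred & !is.na(m$node) &
                            m$node == e$child[i]]
            if (length(genes))
                label <- paste(c(label, genes), collapse = " ")
        }
        lines <- c(lines, sprintf(
            paste0("  <text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" ",
                   "font-size=\"11\">%s</text>"),
            fmtNum((e$x1[i] + e$x2[i]) / 2 + 6),
            fmtNum((e$y1[i] + e$y2[i]) / 2), xmlEscape(label)))
    }
    if (nrow(m) > 0L && any(m$starred)) {
        ri <- match(rootId(tree), layout@nodes$id)
        lines <- c(lines, sprintf(
            paste0("  <text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" ",
                   "font-size=\"11\">%s</text>"),
            fmtNum(layout@nodes$x[ri] + layout@circleDiameter),
            fmtNum(layout@nodes$y[ri] - layout@circleDiameter / 2),
            xmlEscape(paste(paste0(m$gene[m$starred], "*"),
                            collapse = " "))))
    }
    lines <- c(lines, "</svg>")
    if (is.null(path)) return(lines)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    invisible(path)
}
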