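stageTry <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop(stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full CNV-clonality pipeline
#'
#' Chains the stages: read cytoband and CNV region calls, convert regions
#' to arm-level events, collapse identical subclones, build the clone
#' tree, optionally correct and attribute driver-mutation VAFs, and write
#' the outputs: arm-events TSV, tree JSON, tree Newick, SVG, a
#' mutation-assignment report (when mutations are given) and a run report
#' logging every filter decision count.
#'
#' @param regionsPath,groupingsPath HMM region predictions and cell
#'   groupings (see [readCNVCalls()]).
#' @param cytobandPath UCSC-style cytoband file.
#' @param outDir output directory (created if needed).
#' @param mutationsPath optional driver-mutation TSV (gene, vaf).
#' @param anchorGene anchor for VAF correction (GNAQ or GNA11).
#' @param vafUnit unit of the mutation VAFs.
#' @param totalCells denominator for percentages; defaults to the number
#'   of cells in the groupings table.
#' @param minArmOverlap see [regionsToArmEvents()].
#' @param minFraction see [buildCloneTree()].
#' @param tolerance see [assignMutations()].
#' @param scale,circleDiameter see [layoutTree()].
#' @param gepClass optional GEP class for branch tinting (1 blue, 2 red).
#' @return invisibly, a list with the \linkS4class{CloneTree}, the
#'   \linkS4class{SubcloneEvents} before and after collapsing, the output
#'   paths, and the report lines.
#' @export
runFullPipeline <- function(regionsPath, groupingsPath, cytobandPath,
                            outDir, mutationsPath = NULL,
                            anchorGene = "GNAQ",
                            vafUnit = c("fraction", "percent"),
                            totalCells = NULL, minArmOverlap = 0,
                            minFraction = 0, tolerance = 5.0,
                            scale = 2.0, circleDiameter = 10.0,
                            gepClass = NULL) {
    vafUnit <- match.arg(vafUnit)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    report <- character()
    log <- function(...) report <<- c(report, sprintf(...))

    bands <- stageTry("io_formats", readCytoband(cytobandPath))
    calls <- stageTry("io_formats", readCNVCalls(regionsPath, groupingsPath))
    nMito <- sum(normalizeChrom(
        as.character(GenomicRanges::seqnames(calls$regions))) == "M")
    log("regions read: %d", length(calls$regions))
    log("mitochondrial regions excluded: %d", nMito)
    log("cell groups read: %d (%d cells)", length(calls$groupings),
        sum(lengths(calls$groupings)))

    homoplasyWarnings <- 0L
    subclones <- stageTry("armlevel", withCallingHandlers(
        regionsToArmEvents(calls$regions, calls$groupings, bands,
                           minArmOverlap = minArmOverlap),
        warning = function(w) {
            report <<- c(report, paste("warning:", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }))
    log("arm events called: %d", sum(lengths(eventSets(subclones))))

    collapsed <- stageTry("clonality", collapseSubclones(subclones))
    log("subclones: %d before, %d after collapsing identical event sets",
        length(subclones), length(collapsed))

    if (is.null(totalCells))
        totalCells <- sum(lengths(calls$groupings))
    tree <- stageTry("clonality", withCallingHandlers(
        buildCloneTree(collapsed, totalCells, minFraction = minFraction),
        warning = function(w) {
            homoplasyWarnings <<- homoplasyWarnings + 1L
            report <<- c(report, paste("warning:", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }))
    log("tree nodes: %d; homoplasy warnings: %d", nNodes(tree),
        homoplasyWarnings)

    nStarred <- 0L
    if (!is.null(mutationsPath)) {
        records <- stageTry("mutations",
                            readMutationTable(mutationsPath, vafUnit))
        records <- stageTry("mutations", correctVAFs(records, anchorGene))
        tree <- stageTry("mutations",
                         assignMutations(tree, records,
                                         tolerance = tolerance))
        nStarred <- sum(treeMutations(tree)$starred)
        log("mutations: %d read, %d starred", nrow(records), nStarred)
    }

    paths <- list(
        armEvents = file.path(outDir, "arm_events.tsv"),
        treeJSON = file.path(outDir, "tree.json"),
        treeNewick = file.path(outDir, "tree.nwk"),
        svg = file.path(outDir, "tree.svg"),
        report = file.path(outDir, "report.txt"))
    stageTry("io_formats", writeArmEvents(collapsed, paths$armEvents))
    stageTry("io_formats", writeCloneTreeJSON(tree, paths$treeJSON))
    stageTry("io_formats", writeCloneTreeNewick(tree, paths$treeNewick))
    layout <- stageTry("render",
                       layoutTree(tree, scale = scale,
                                  circleDiameter = circleDiameter))
    stageTry("render", renderSVG(layout, tree, paths$svg,
                                 gepClass = gepClass))
    if (!is.null(mutationsPath)) {
        paths$mutationReport <- file.path(outDir, "mutation_report.tsv")
        stageTry("mutations", writeMutationReport(tree,
                                                  paths$mutationReport))
    }
    writeLines(report, paths$report)
    invisible(list(tree = tree, subclones = subclones,
                   collapsed = collapsed, layout = layout, paths = paths,
                   report = report))
}
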