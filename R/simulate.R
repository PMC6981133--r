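#' Construct a SimulationSpec
#'
#' @param tree data.frame with columns \code{node}, \code{parent} (NA for
#'   children of the root), \code{events} (list column of added arm-event
#'   vectors, e.g. \code{list("3q_loss")}), \code{fraction} (exclusive cell
#'   fraction of the node). Fractions must sum to at most 1; the remainder
#'   are CNV-free cells at the root.
#' @param nCells number of tumor cells to simulate.
#' @param fpRate,fnRate per-cell per-arm spurious / missed region-call
#'   probabilities.
#' @param purity tumor purity in (0, 1] for bulk VAF simulation.
#' @param depth sequencing depth for binomial VAF sampling.
#' @param seed random seed.
#' @return a \linkS4class{SimulationSpec}.
#' @examples
#' loh3ChainSpec <- SimulationSpec(
#'     tree = data.frame(node = c("c1", "c2"), parent = c(NA, "c1"),
#'                       events = I(list("3q_loss", "3p_loss")),
#'                       fraction = c(0.17, 0.06)),
#'     nCells = 1000)
#' @export
SimulationSpec <- function(tree, nCells, fpRate = 0, fnRate = 0,
                           purity = 1, depth = 500L, seed = 1L) {
    tree$events <- lapply(tree$events, normalizeEventSet)
    tree$node <- as.character(tree$node)
    tree$parent <- as.character(tree$parent)
    new("SimulationSpec", tree = tree, nCells = as.integer(nCells),
        fpRate = fpRate, fnRate = fnRate, purity = purity,
        depth = as.integer(depth), seed = as.integer(seed))
}

#' Cumulative event sets and inclusive fractions of a SimulationSpec
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return data.frame with columns \code{node}, \code{cumulative} (list of
#'   sorted event vectors), \code{fraction} (exclusive), and
#'   \code{inclusiveFraction} (node plus descendants; the implicit root has
#'   inclusive fraction 1 and is included as node \code{"root"}).
#' @export
specCumulativeEvents <- function(spec) {
    tr <- spec@tree
    cum <- setNames(vector("list", nrow(tr)), tr$node)
    resolve <- function(node) {
        i <- match(node, tr$node)
        if (!is.null(cum[[node]])) return(cum[[node]])
        base <- if (is.na(tr$parent[i])) character() else resolve(tr$parent[i])
        cum[[node]] <<- normalizeEventSet(c(base, tr$events[[i]]))
        cum[[node]]
    }
    for (nd in tr$node) resolve(nd)
    incl <- setNames(tr$fraction, tr$node)
    ord <- names(sort(sapply(cum, length), decreasing = TRUE))
    for (nd in ord) {
        p <- tr$parent[match(nd, tr$node)]
        if (!is.na(p)) incl[p] <- incl[p] + incl[nd]
    }
    data.frame(node = c("root", tr$node),
               cumulative = I(c(list(character()), cum[tr$node])),
               fraction = c(1 - sum(tr$fraction), tr$fraction),
               inclusiveFraction = c(1, incl[tr$node]),
               stringsAsFactors = FALSE)
}

#' Deterministic synthetic cytoband table
#'
#' Builds a toy genome with UCSC-style banding: per chromosome a fixed
#' length, two p bands, flanking acen bands around the centromere, and two
#' q bands. Coordinates are deterministic functions of the chromosome
#' index, so the table is identical across calls. It is a stand-in for a
#' real cytoband annotation, intended for simulations and examples.
#'
#' @param chroms chromosomes to include.
#' @param scale length of the largest chromosome in bases.
#' @return a \linkS4class{CytobandTable}.
#' @export
simulateCytoband <- function(chroms = c(as.character(1:22), "X"),
                             scale = 200000) {
    rows <- list()
    for (k in seq_along(chroms)) {
        len <- round(scale * (1 - 0.03 * (k - 1)))
        b <- round(len * (0.38 + 0.02 * (k %% 7)))   # arm boundary
        cuts <- c(0, round(b * 0.5), round(b * 0.9), b,
                  round(b + (len - b) * 0.1), round(b + (len - b) * 0.6),
                  len)
        bandNames <- c("p15", "p11", "p10", "q10", "q21", "q31")
        stains <- c("gneg", "gpos50", "acen", "acen", "gneg", "gpos50")
        rows[[k]] <- data.frame(chrom = chroms[k], start = cuts[-7],
                                end = cuts[-1], band = bandNames,
                                stain = stains)
    }
    cytobandFromFields(do.call(rbind, rows))
}

armRegionCoords <- function(arm, bands) {
    chrom <- sub("[pq]$", "", arm)
    side <- substring(arm, nchar(arm))
    b <- bands@armBoundary[[chrom]]
    len <- bands@chromLength[[chrom]]
    if (side == "p") c(start = 1, end = b) else c(start = b + 1, end = len)
}

#' Simulate per-cell CNV region calls with known ground truth
#'
#' Cells are apportioned to the spec's nodes by largest-remainder rounding
#' of the fractions (remaining cells are CNV-free and sit at the root) and
#' barcodes are shuffled with the spec seed. Each cell's true events are
#' its node's cumulative set; each true event is dropped with probability
#' \code{fnRate} and a spurious call is added on each non-event arm with
#' probability \code{fpRate} (random direction). Cells are then grouped by
#' realized event set — one group per distinct set — and written as an
#' HMM-style region table (full-arm regions, state 2 for loss and 5 for
#' gain) plus a cell-groupings table, the formats [readCNVCalls()] reads.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param bands a \linkS4class{CytobandTable} containing every arm used in
#'   the spec.
#' @param dir output directory (created if needed).
#' @return list with \code{regionsPath}, \code{groupingsPath}, and
#'   \code{truth}, a data.frame mapping each cell barcode to its true node
#'   id (\code{"root"} for CNV-free cells).
#' @examples
#' spec <- SimulationSpec(
#'     tree = data.frame(node = c("c1", "c2"), parent = c(NA, "c1"),
#'                       events = I(list("3q_loss", "3p_loss")),
#'                       fraction = c(0.17, 0.06)),
#'     nCells = 1000)
#' sim <- simulateCellCNVCalls(spec, simulateCytoband(), tempfile())
#' table(sim$truth$node)   # 170 c1, 60 c2, 770 root
#' @export
simulateCellCNVCalls <- function(spec, bands, dir = tempfile("sim")) {
    methods::validObject(spec)
    cumdf <- specCumulativeEvents(spec)
    allArms <- unique(eventArm(unlist(cumdf$cumulative)))
    missing <- setdiff(sub("[pq]$", "", allArms), names(bands@armBoundary))
    if (length(missing))
        stop("arm chromosome(s) absent from cytoband table: ",
             paste(missing, collapse = ", "))
    callableArms <- as.vector(outer(
        names(bands@armOK)[bands@armOK], c("p", "q"), paste0))
    n <- spec@nCells
    counts <- largestRemainder(spec@tree$fraction, n)
    nodeOfSlot <- c(rep(spec@tree$node, counts),
                    rep("root", n - sum(counts)))
    barcodes <- sprintf("cell_%05d", seq_len(n))
    cumSets <- setNames(cumdf$cumulative, cumdf$node)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    withSeed(spec@seed, {
        nodeOfCell <- setNames(nodeOfSlot[sample.int(n)], barcodes)
        realized <- vector("list", n)
        for (i in seq_len(n)) {
            ev <- cumSets[[nodeOfCell[i]]]
            if (spec@fnRate > 0 && length(ev))
                ev <- ev[stats::runif(length(ev)) >= spec@fnRate]
            if (spec@fpRate > 0) {
                free <- setdiff(callableArms, eventArm(ev))
                hit <- free[stats::runif(length(free)) < spec@fpRate]
                if (length(hit))
                    ev <- c(ev, makeEvent(hit, sample(.DIRECTIONS,
                                                      length(hit),
                                                      replace = TRUE)))
            }
            realized[[i]] <- normalizeEventSet(ev)
        }
    })
    keys <- vapply(realized, eventSetId, "")
    uq <- unique(keys)
    sets <- lapply(uq, function(k) realized[[match(k, keys)]])
    o <- order(lengths(sets), vapply(sets, paste, "", collapse = "+"),
               method = "radix")
    uq <- uq[o]; sets <- sets[o]
    gid <- setNames(sprintf("s%03d", seq_along(uq)), uq)
    regRows <- list()
    for (g in seq_along(uq)) {
        for (ev in sets[[g]]) {
            arm <- eventArm(ev)
            co <- armRegionCoords(arm, bands)
            chrom <- sub("[pq]$", "", arm)
            regRows[[length(regRows) + 1L]] <- data.frame(
                cell_group_name = gid[[uq[g]]],
                cnv_name = paste0("chr", arm, "-",
                                  eventDirection(ev)),
                state = if (eventDirection(ev) == "loss") 2L else 5L,
                chr = paste0("chr", chrom),
                start = co[["start"]], end = co[["end"]])
        }
    }
    reg <- if (length(regRows)) do.call(rbind, regRows)
    else data.frame(cell_group_name = character(), cnv_name = character(),
                    state = integer(), chr = character(),
                    start = numeric(), end = numeric())
    grp <- data.frame(cell_group_name = unname(gid[keys]), cell = barcodes)
    ## stable file order: by group then barcode
    grp <- grp[order(grp$cell_group_name, grp$cell, method = "radix"), ]
    regionsPath <- file.path(dir, "pred_cnv_regions.dat")
    groupingsPath <- file.path(dir, "cell_groupings.tsv")
    utils::write.table(reg, regionsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(grp, groupingsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(regionsPath = regionsPath, groupingsPath = groupingsPath,
         truth = data.frame(cell = barcodes, node = unname(nodeOfCell),
                            stringsAsFactors = FALSE))
}

#' Simulate bulk driver-mutation VAFs from a clone-tree ground truth
#'
#' Each mutation's true VAF is \code{purity * 0.5 * inclusiveFraction} of
#' its node (heterozygous mutation carried by every cell at the node and
#' its descendants, diluted by normal contamination); the observed VAF is
#' Binomial(\code{depth}, true VAF) / \code{depth} under the spec seed.
#' Truncal mutations (e.g. the G-alpha anchor) map to node \code{"root"}
#' with inclusive fraction 1.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param truths data.frame with columns \code{gene} and \code{node}.
#' @param path optional output TSV (columns gene, vaf) readable by
#'   [readMutationTable()].
#' @return data.frame with columns \code{gene}, \code{node},
#'   \code{true_vaf}, \code{vaf}.
#' @export
simulateMutationVAFs <- function(spec, truths, path = NULL) {
    cumdf <- specCumulativeEvents(spec)
    i <- match(truths$node, cumdf$node)
    if (anyNA(i))
        stop("unknown node(s) in truths: ",
             paste(truths$node[is.na(i)], collapse = ", "))
    trueVAF <- spec@purity * 0.5 * cumdf$inclusiveFraction[i]
    obs <- withSeed(spec@seed,
                    stats::rbinom(length(trueVAF), spec@depth,
                                  trueVAF) / spec@depth)
    out <- data.frame(gene = as.character(truths$gene),
                      node = as.character(truths$node),
                      true_vaf = trueVAF, vaf = obs,
                      stringsAsFactors = FALSE)
    if (!is.null(path))
        utils::write.table(out[, c("gene", "vaf")], path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    out
}

#' Simulate a small expression matrix spanning the QC thresholds
#'
#' Generates a sparse gene-by-cell count matrix with a tumor population
#' (PRAME and HTR2B expressed, CD3E silent), a T-cell population (CD3E
#' high, PRAME/HTR2B zero), mitochondrial genes (\code{"MT-"} prefix), and
#' a fixed panel of boundary cells sitting exactly on, just above and just
#' below each QC threshold (UMI 400, 100/8000 genes, 10% mitochondrial
#' content). Identical seeds give identical matrices.
#'
#' @param nTumor,nTcells numbers of tumor and T cells.
#' @param seed random seed.
#' @return a \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @export
simulateExpressionMatrix <- function(nTumor, nTcells, seed = 1L) {
    stopifnot(nTumor > 0, nTcells > 0)
    mito <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP6"))
    nFiller <- 8200L
    genes <- c("CD3E", "PRAME", "HTR2B", mito,
               sprintf("GENE%04d", seq_len(nFiller)))
    fillerIdx <- seq_along(genes)[-(1:8)]
    cells <- c(sprintf("tumor_%04d", seq_len(nTumor)),
               sprintf("tcell_%04d", seq_len(nTcells)),
               "edge_umi_eq", "edge_umi_low", "edge_umi_above",
               "edge_genes_low", "edge_genes_high", "edge_mito_eq",
               "edge_mito_hi", "edge_mito_ok")
    ii <- jj <- xx <- list()
    add <- function(cellIdx, geneIdx, counts) {
        k <- length(ii) + 1L
        ii[[k]] <<- geneIdx; jj[[k]] <<- rep(cellIdx, length(geneIdx))
        xx[[k]] <<- counts
    }
    withSeed(seed, {
        for (c in seq_len(nTumor + nTcells)) {
            ng <- sample(150:400, 1)
            gi <- sample(fillerIdx, ng)
            cnt <- stats::rpois(ng, 2) + 1
            add(c, gi, cnt)
            umi <- sum(cnt)
            mc <- stats::rpois(length(mito), 0.006 * umi)
            add(c, 4:8, mc)
            if (c <= nTumor) {
                add(c, 2:3, c(1 + stats::rpois(1, 2), 1 + stats::rpois(1, 1)))
            } else {
                add(c, 1L, 20 + stats::rpois(1, 10))
            }
        }
    })
    ec <- function(name) nTumor + nTcells + match(name, c(
        "edge_umi_eq", "edge_umi_low", "edge_umi_above", "edge_genes_low",
        "edge_genes_high", "edge_mito_eq", "edge_mito_hi", "edge_mito_ok"))
    add(ec("edge_umi_eq"), fillerIdx[1:100], rep(4, 100))       # UMI 400
    add(ec("edge_umi_low"), fillerIdx[1:120], rep(3, 120))      # UMI 360
    add(ec("edge_umi_above"), fillerIdx[1:100], c(rep(4, 99), 5)) # UMI 401
    add(ec("edge_genes_low"), fillerIdx[1:99], rep(5, 99))      # 99 genes
    add(ec("edge_genes_high"), fillerIdx[1:8100], rep(1, 8100)) # 8100 genes
    add(ec("edge_mito_eq"), c(fillerIdx[1:150], 4L),
        c(rep(6, 150), 100))                                    # mito = 10%
    add(ec("edge_mito_hi"), c(fillerIdx[1:170], 4L),
        c(rep(5, 170), 150))                                    # mito = 15%
    add(ec("edge_mito_ok"), c(fillerIdx[1:190], 4L),
        c(rep(5, 190), 50))                                     # mito = 5%
    m <- Matrix::sparseMatrix(
        i = unlist(ii), j = unlist(jj), x = unlist(xx),
        dims = c(length(genes), length(cells)),
        dimnames = list(genes, cells))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(m, "CsparseMatrix")))
}
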