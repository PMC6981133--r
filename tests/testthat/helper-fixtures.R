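## Shared fixtures: all built in code, no stored binary data.

## Toy cytoband file with realistic Mb-scale coordinates (chr3 arm boundary
## at 96 Mb, chr8 at 45 Mb) plus a band-less mitochondrial contig.
toyCytobandFile <- function() {
    path <- tempfile(fileext = ".txt")
    writeLines(c(
        "chr3\t0\t90000000\tp21\tgneg",
        "chr3\t90000000\t96000000\tp11\tacen",
        "chr3\t96000000\t99000000\tq11\tacen",
        "chr3\t99000000\t198000000\tq21\tgneg",
        "chr8\t0\t40000000\tp21\tgneg",
        "chr8\t40000000\t45000000\tp11\tacen",
        "chr8\t45000000\t50000000\tq11\tacen",
        "chr8\t50000000\t146000000\tq21\tgneg",
        "chrM\t0\t16569\tn1\tgneg"), path)
    path
}

toyCytoband <- function() readCytoband(toyCytobandFile())

## Tiny-coordinate genome for per-base brute-force oracles.
tinyCytobandLines <- c(
    "chr1\t0\t40\tp2\tgneg",
    "chr1\t40\t60\tp1\tacen",
    "chr1\t60\t70\tq1\tacen",
    "chr1\t70\t150\tq2\tgneg",
    "chr2\t0\t25\tp1\tgneg",
    "chr2\t25\t30\tq1\tacen",
    "chr2\t30\t90\tq2\tgneg",
    "chr3\t0\t30\tp2\tgpos50",
    "chr3\t30\t50\tp1\tgneg",
    "chr3\t50\t55\tq1\tacen",
    "chr3\t55\t200\tq2\tgneg")

tinyCytobandFile <- function() {
    path <- tempfile(fileext = ".txt")
    writeLines(tinyCytobandLines, path)
    path
}

tinyCytoband <- function() readCytoband(tinyCytobandFile())

## Independent per-base oracle: label every base of a region by scanning
## the raw cytoband lines, count bases per arm.
oracleArmOverlap <- function(chrom, start, end) {
    f <- strsplit(tinyCytobandLines, "\t")
    df <- data.frame(chrom = sub("^chr", "", vapply(f, `[`, "", 1)),
                     start = as.numeric(vapply(f, `[`, "", 2)),
                     end = as.numeric(vapply(f, `[`, "", 3)),
                     band = vapply(f, `[`, "", 4))
    df <- df[df$chrom == chrom, ]
    counts <- c(p = 0, q = 0)
    for (b in start:end) {             # base b covers [b-1, b)
        row <- which(df$start <= b - 1 & b - 1 < df$end)
        if (length(row) == 1L) {
            arm <- substr(df$band[row], 1, 1)
            counts[arm] <- counts[arm] + 1
        }
    }
    counts
}

## Subclone fixture: the sequential 3q -> 3q+3p loss chain (23% / 6%).
loh3Subclones <- function(nRoot = 770, n3q = 170, nLOH = 60) {
    n <- nRoot + n3q + nLOH
    bc <- sprintf("c%04d", seq_len(n))
    SubcloneEvents(
        groupId = c("s0", "s1", "s2"),
        events = list(character(), "3q_loss", c("3q_loss", "3p_loss")),
        cells = list(bc[seq_len(nRoot)],
                     bc[nRoot + seq_len(n3q)],
                     bc[nRoot + n3q + seq_len(nLOH)]))
}

loh3ChainSpec <- function(nCells = 1000, fpRate = 0, fnRate = 0, seed = 1L,
                       purity = 1, depth = 500L) {
    SimulationSpec(
        tree = data.frame(node = c("c1", "c2"), parent = c(NA, "c1"),
                          events = I(list("3q_loss", "3p_loss")),
                          fraction = c(0.17, 0.06)),
        nCells = nCells, fpRate = fpRate, fnRate = fnRate,
        purity = purity, depth = depth, seed = seed)
}

## Random identifiable clone-tree spec: every node adds arms unused
## elsewhere in the tree, so subset containment identifies ancestry.
## Fractions are integer cell counts / nCells, so noiseless percentages
## are exact.
randomSpec <- function(seed, nCells = 400, maxNodes = 6, fpRate = 0,
                       fnRate = 0, minCount = 8) {
    set.seed(seed)
    pool <- sample(as.vector(outer(1:22, c("p", "q"), paste0)))
    k <- sample(2:maxNodes, 1)
    nodes <- sprintf("n%d", seq_len(k))
    parents <- c(NA, vapply(seq_len(k - 1), function(i)
        sample(c(NA, nodes[seq_len(i)]), 1), ""))
    events <- vector("list", k)
    used <- 0L
    for (i in seq_len(k)) {
        nEv <- sample(1:2, 1)
        arms <- pool[used + seq_len(nEv)]
        used <- used + nEv
        events[[i]] <- makeEventVec(arms, sample(c("loss", "gain"), nEv,
                                                 replace = TRUE))
    }
    maxCount <- floor(0.9 * nCells / k)
    counts <- sample(minCount:maxCount, k, replace = TRUE)
    SimulationSpec(
        tree = data.frame(node = nodes, parent = parents,
                          events = I(events), fraction = counts / nCells),
        nCells = nCells, fpRate = fpRate, fnRate = fnRate, seed = seed)
}

makeEventVec <- function(arms, dirs) paste0(arms, "_", dirs)

## Ground-truth edge set of a spec: parent cumulative-set id -> node
## cumulative-set id.
specEdgeSet <- function(spec) {
    cum <- specCumulativeEvents(spec)
    key <- function(ev) if (length(ev) == 0) "root"
        else paste(sort(ev), collapse = "+")
    keys <- setNames(vapply(cum$cumulative, key, ""), cum$node)
    tr <- spec@tree
    sort(vapply(seq_len(nrow(tr)), function(i) {
        p <- if (is.na(tr$parent[i])) "root" else keys[[tr$parent[i]]]
        paste(p, "->", keys[[tr$node[i]]])
    }, ""))
}

treeEdgeSet <- function(tree) {
    nd <- treeNodes(tree)
    sort(paste(nd$parent[!is.na(nd$parent)], "->",
               nd$id[!is.na(nd$parent)]))
}

## Run simulate -> parse -> arm events -> collapse -> tree.
simulateAndReconstruct <- function(spec, bands = simulateCytoband(),
                                   minFraction = 0) {
    sim <- simulateCellCNVCalls(spec, bands, tempfile("sim"))
    calls <- readCNVCalls(sim$regionsPath, sim$groupingsPath)
    sub <- collapseSubclones(
        regionsToArmEvents(calls$regions, calls$groupings, bands))
    tree <- buildCloneTree(sub, totalCells = spec@nCells,
                           minFraction = minFraction)
    list(tree = tree, sim = sim)
}

## Minimal SingleCellExperiment from a dense count matrix.
sceFromCounts <- function(m) {
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                           "CsparseMatrix")))
}
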