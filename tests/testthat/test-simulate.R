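test_that("cells apportion by largest remainder, exactly at round fractions", {
    sim <- simulateCellCNVCalls(loh3ChainSpec(), simulateCytoband(),
                                tempfile())
    counts <- table(sim$truth$node)
    expect_equal(as.vector(counts[c("c1", "c2", "root")]),
                 c(170, 60, 770))
    grp <- read.table(sim$groupingsPath, header = TRUE, sep = "\t")
    expect_equal(sort(as.vector(table(grp$cell_group_name))),
                 c(60, 170, 770))
})

test_that("identical seeds give byte-identical simulator output", {
    cb <- simulateCytoband()
    spec <- loh3ChainSpec(fnRate = 0.05, fpRate = 0.01, seed = 21L)
    d1 <- simulateCellCNVCalls(spec, cb, tempfile())
    d2 <- simulateCellCNVCalls(spec, cb, tempfile())
    expect_identical(readLines(d1$regionsPath), readLines(d2$regionsPath))
    expect_identical(readLines(d1$groupingsPath),
                     readLines(d2$groupingsPath))
    d3 <- simulateCellCNVCalls(loh3ChainSpec(fnRate = 0.05, fpRate = 0.01,
                                          seed = 22L), cb, tempfile())
    expect_false(identical(readLines(d1$groupingsPath),
                           readLines(d3$groupingsPath)))
})

test_that("noiseless simulation round-trips to the exact spec tree", {
    res <- simulateAndReconstruct(loh3ChainSpec())
    pct <- inclusivePercentage(res$tree)
    expect_equal(unname(pct["3q_loss"]), 23)
    expect_equal(unname(pct["3p_loss+3q_loss"]), 6)
    expect_identical(treeEdgeSet(res$tree), specEdgeSet(loh3ChainSpec()))
})

test_that("simulated VAFs follow purity times half the inclusive fraction", {
    spec <- loh3ChainSpec(purity = 0.6, depth = 500L)
    v <- simulateMutationVAFs(spec, data.frame(gene = "GNAQ",
                                               node = "root"))
    expect_equal(v$true_vaf, 0.30)   # 0.6 * 0.5 * 1.0
    v2 <- simulateMutationVAFs(loh3ChainSpec(purity = 1),
                               data.frame(gene = c("A1", "A2"),
                                          node = c("c1", "c2")))
    expect_equal(v2$true_vaf, c(0.5 * 0.23, 0.5 * 0.06))
    expect_error(simulateMutationVAFs(spec, data.frame(gene = "X",
                                                       node = "ghost")),
                 "unknown node")
})

test_that("observed VAFs converge to the truth at extreme depth", {
    spec <- loh3ChainSpec(purity = 0.8, depth = 1000000L, seed = 5L)
    v <- simulateMutationVAFs(spec, data.frame(
        gene = c("GNAQ", "B"), node = c("root", "c1")))
    expect_true(all(abs(v$vaf - v$true_vaf) < 1e-3))
})

test_that("anchor correction restores clone percentages within binomial
           error at depth 500", {
    inside <- 0; total <- 0
    for (seed in 1:100) {
        spec <- loh3ChainSpec(purity = 0.7, depth = 500L, seed = seed)
        v <- simulateMutationVAFs(spec, data.frame(
            gene = c("GNAQ", "B1", "B2"), node = c("root", "c1", "c2")))
        rec <- correctVAFs(data.frame(gene = v$gene, raw_vaf = v$vaf),
                           "GNAQ")
        expPct <- pmin(100, 200 * rec$corrected_vaf[-1])
        truePct <- c(23, 6)
        ## normal-approximation band for 100*obs_g/obs_a at depth 500
        for (k in 1:2) {
            g <- v$true_vaf[k + 1]; a <- v$true_vaf[1]
            sdPct <- sqrt((100 / a)^2 * g * (1 - g) / 500 +
                          (100 * g / a^2)^2 * a * (1 - a) / 500)
            total <- total + 1
            if (abs(expPct[k] - truePct[k]) < 3.5 * sdPct)
                inside <- inside + 1
        }
    }
    expect_gte(inside / total, 0.95)
})

test_that("false negatives and positives perturb per-cell call sets", {
    cb <- simulateCytoband()
    spec <- loh3ChainSpec(fnRate = 0.3, fpRate = 0.02, seed = 9L)
    sim <- simulateCellCNVCalls(spec, cb, tempfile())
    grp <- read.table(sim$groupingsPath, header = TRUE, sep = "\t")
    ## noise splits cells into more realized event sets than true nodes
    expect_gt(length(unique(grp$cell_group_name)), 3)
    reg <- read.table(sim$regionsPath, header = TRUE, sep = "\t")
    expect_true(all(reg$state %in% c(2L, 5L)))
})

test_that("expression matrices are seed-deterministic", {
    a <- simulateExpressionMatrix(15, 5, seed = 2)
    b <- simulateExpressionMatrix(15, 5, seed = 2)
    expect_equal(SummarizedExperiment::assay(a, "counts"),
                 SummarizedExperiment::assay(b, "counts"))
    c <- simulateExpressionMatrix(15, 5, seed = 3)
    expect_false(isTRUE(all.equal(
        SummarizedExperiment::assay(a, "counts"),
        SummarizedExperiment::assay(c, "counts"))))
})

test_that("random noiseless specs reconstruct exactly (tree and percents)", {
    cb <- simulateCytoband()
    for (seed in 1:50) {
        spec <- randomSpec(seed, nCells = 300)
        res <- simulateAndReconstruct(spec, bands = cb)
        expect_identical(treeEdgeSet(res$tree), specEdgeSet(spec))
        cum <- specCumulativeEvents(spec)
        pct <- inclusivePercentage(res$tree)
        for (i in seq_len(nrow(cum))) {
            id <- if (length(cum$cumulative[[i]]) == 0) "root"
                  else paste(sort(cum$cumulative[[i]]), collapse = "+")
            expect_equal(unname(pct[id]),
                         100 * cum$inclusiveFraction[i])
        }
    }
})
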