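mut <- function(genes, vafs) data.frame(gene = genes, raw_vaf = vafs,
                                        stringsAsFactors = FALSE)

test_that("anchor correction sets the anchor to exactly 50%", {
    for (raw in c(0.31, 0.5, 0.05, 0.97)) {
        ## low anchors can push other genes past 1 (clamped with warning);
        ## the anchor itself must still be exactly 0.5
        rec <- suppressWarnings(
            correctVAFs(mut(c("GNAQ", "BAP1"), c(raw, 0.20)), "GNAQ"))
        expect_identical(rec$corrected_vaf[1], 0.5)
    }
    rec <- correctVAFs(mut(c("GNA11", "BAP1"), c(0.25, 0.20)), "GNA11")
    expect_equal(rec$corrected_vaf, c(0.5, 0.40))
})

test_that("correction rescales by the purity factor and clamps at 1", {
    rec <- correctVAFs(mut(c("GNAQ", "SF3B1"), c(0.25, 0.10)), "GNAQ")
    expect_equal(rec$corrected_vaf[2], 0.20)
    expect_warning(
        rec2 <- correctVAFs(mut(c("GNAQ", "X"), c(0.20, 0.50)), "GNAQ"),
        "clamp")
    expect_equal(rec2$corrected_vaf[2], 1.0)
})

test_that("correction is invariant to a common purity rescaling", {
    base <- mut(c("GNAQ", "BAP1", "SF3B1"), c(0.48, 0.30, 0.12))
    for (purity in c(0.3, 0.6, 0.9)) {
        scaled <- base
        scaled$raw_vaf <- base$raw_vaf * purity
        expect_equal(correctVAFs(scaled, "GNAQ")$corrected_vaf,
                     correctVAFs(base, "GNAQ")$corrected_vaf)
    }
})

test_that("missing or zero-VAF anchors are errors", {
    expect_error(correctVAFs(mut("BAP1", 0.2), "GNAQ"), "absent")
    expect_error(correctVAFs(mut(c("GNAQ", "BAP1"), c(0, 0.2)), "GNAQ"),
                 "0")
})

test_that("mutations attach to the clone of like percentage", {
    tr <- buildCloneTree(collapseSubclones(loh3Subclones()), 1000)
    rec <- mut(c("GNAQ", "M6"), c(0.5, 0.03))
    rec <- correctVAFs(rec, "GNAQ")
    tr <- assignMutations(tr, rec)
    m <- treeMutations(tr)
    expect_identical(m$node[m$gene == "M6"], "3p_loss+3q_loss")  # 6% clone
    expect_false(m$starred[m$gene == "M6"])
    ## truncal anchor lands on the trunk
    expect_identical(m$node[m$gene == "GNAQ"], "3q_loss")
})

test_that("ambiguous and unmatched percentages are starred at the root", {
    ## two nodes equidistant from the expected percentage -> ambiguous
    s <- SubcloneEvents(c("A", "B"),
                        list("1p_loss", c("1p_loss", "8q_gain")),
                        list(sprintf("a%d", 1:5), sprintf("b%d", 1:125)))
    tr <- buildCloneTree(s, 250)    # nested nodes at 52% and 50%
    rec <- correctVAFs(mut(c("GNAQ", "MX"), c(0.5, 0.255)), "GNAQ")
    tr2 <- assignMutations(tr, rec)        # MX expected 51%, nodes 50/52
    m <- treeMutations(tr2)
    expect_true(m$starred[m$gene == "MX"])
    expect_true(is.na(m$node[m$gene == "MX"]))
    ## anchor expected 100%: single root child -> attaches to the trunk
    expect_identical(m$node[m$gene == "GNAQ"], "1p_loss")

    ## anchor expected 100% with two root children: no trunk, starred
    sFork <- SubcloneEvents(c("A", "B"), list("1p_loss", "8q_gain"),
                            list(sprintf("a%d", 1:50),
                                 sprintf("b%d", 1:30)))
    trFork <- assignMutations(buildCloneTree(sFork, 100),
                              correctVAFs(mut("GNAQ", 0.5), "GNAQ"))
    expect_true(treeMutations(trFork)$starred[1])

    ## no node within tolerance -> starred
    s2 <- SubcloneEvents(c("A", "B"), list("1p_loss", c("1p_loss", "8q_gain")),
                         list(sprintf("a%d", 1:70), sprintf("b%d", 1:10)))
    tr3 <- assignMutations(buildCloneTree(s2, 100),
                           correctVAFs(mut(c("GNAQ", "MY"), c(0.5, 0.20)),
                                       "GNAQ"))
    m3 <- treeMutations(tr3)
    expect_true(m3$starred[m3$gene == "MY"])   # expected 40%, nodes 80/10
})

test_that("shrinking the tolerance never un-stars a mutation", {
    set.seed(7)
    for (rep in 1:20) {
        spec <- randomSpec(seed = 900 + rep, nCells = 200)
        tr <- simulateAndReconstruct(spec)$tree
        genes <- sprintf("g%d", 1:6)
        vafs <- round(runif(6, 0.02, 0.5), 3)
        rec <- correctVAFs(mut(c("GNAQ", genes), c(0.5, vafs)), "GNAQ")
        prevStarred <- character()
        for (tol in c(10, 5, 2, 0.5)) {
            m <- treeMutations(assignMutations(tr, rec, tolerance = tol))
            starred <- m$gene[m$starred]
            expect_true(all(prevStarred %in% starred))
            prevStarred <- starred
        }
    }
})

test_that("attribution recovers the true clone from deep binomial VAFs", {
    ## clones >= 15 percentage points apart, depth 500, 100 replicates;
    ## tolerance of 10 points, matched to the 15-point clone separation
    nMut <- 0; nCorrect <- 0
    for (seed in 1:100) {
        chain <- seed %% 2 == 0
        spec <- if (chain) SimulationSpec(
            tree = data.frame(node = c("n1", "n2", "n3"),
                              parent = c(NA, "n1", "n2"),
                              events = I(list("3q_loss", "8q_gain",
                                              "6p_loss")),
                              fraction = c(0.20, 0.15, 0.10)),
            nCells = 400, depth = 500L, seed = seed)
        else SimulationSpec(
            tree = data.frame(node = c("n1", "n2", "n3"),
                              parent = c(NA, "n1", "n1"),
                              events = I(list("3q_loss", "8q_gain",
                                              "6p_loss")),
                              fraction = c(0.20, 0.15, 0.30)),
            nCells = 400, depth = 500L, seed = seed)
        tr <- simulateAndReconstruct(spec)$tree
        truths <- data.frame(gene = c("GNAQ", "g1", "g2", "g3"),
                             node = c("root", "n1", "n2", "n3"))
        vafs <- simulateMutationVAFs(spec, truths)
        rec <- correctVAFs(mut(vafs$gene, vafs$vaf), "GNAQ")
        tr <- assignMutations(tr, rec, tolerance = 10)
        m <- treeMutations(tr)
        cum <- specCumulativeEvents(spec)
        trueNode <- setNames(vapply(cum$cumulative, function(ev)
            if (length(ev)) paste(sort(ev), collapse = "+") else "root",
            ""), cum$node)
        for (g in c("g1", "g2", "g3")) {
            nMut <- nMut + 1
            want <- trueNode[[truths$node[truths$gene == g]]]
            got <- m$node[m$gene == g]
            if (!is.na(got) && got == want) nCorrect <- nCorrect + 1
        }
    }
    expect_gte(nCorrect / nMut, 0.95)
})
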