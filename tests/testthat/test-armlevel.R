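test_that("regions map to the correct arm with 1-based closed overlap", {
    cb <- toyCytoband()
    ov <- assignArm(cb, "chr3", 100000000, 150000000)
    expect_equal(ov$arm, "3q")
    expect_equal(ov$overlap, 50000001)   # wholly q-side of the 96 Mb boundary

    both <- assignArm(cb, "chr3", 80000000, 150000000)
    expect_equal(both$arm, c("3p", "3q"))
    expect_equal(both$overlap[both$arm == "3p"], 96000000 - 80000000 + 1)
    expect_equal(both$overlap[both$arm == "3q"], 150000000 - 96000000)
})

test_that("mitochondrial regions are skipped, absent chromosomes error", {
    cb <- toyCytoband()
    expect_message(ov <- assignArm(cb, "chrM", 1, 16569), "mitochondrial")
    expect_equal(nrow(ov), 0)
    expect_error(assignArm(cb, "chr12", 1, 100), "absent")
})

test_that("arm assignment matches the per-base brute-force oracle", {
    cb <- tinyCytoband()
    lens <- chromLengths(cb)
    set.seed(42)
    for (i in 1:1000) {
        chrom <- sample(c("1", "2", "3"), 1)
        len <- lens[[chrom]]
        pos <- sort(sample(seq_len(len + 20), 2))  # may overhang the end
        got <- assignArm(cb, chrom, pos[1], pos[2])
        want <- oracleArmOverlap(chrom, pos[1], pos[2])
        gotv <- c(p = 0, q = 0)
        for (j in seq_len(nrow(got)))
            gotv[substring(got$arm[j], nchar(got$arm[j]))] <- got$overlap[j]
        expect_equal(unname(gotv), unname(want))
    }
})

test_that("states map to directions and neutral regions contribute nothing", {
    cb <- toyCytoband()
    rf <- tempfile(); gf <- tempfile()
    writeLines(c("cell_group_name\tcnv_name\tstate\tchr\tstart\tend",
                 "g1\tr1\t5\tchr8\t48000000\t146000000",
                 "g1\tr2\t3\tchr8\t1\t40000000"), rf)
    writeLines(c("cell_group_name\tcell", sprintf("g1\tb%d", 1:5)), gf)
    calls <- readCNVCalls(rf, gf)
    sub <- regionsToArmEvents(calls$regions, calls$groupings, cb)
    expect_identical(as.character(eventSets(sub)[[1]]), "8q_gain")
})

test_that("events deduplicate within a group and chrM regions are dropped", {
    cb <- toyCytoband()
    gr <- GenomicRanges::GRanges(
        c("3", "3", "M"),
        IRanges::IRanges(c(100e6, 150e6, 1), c(140e6, 198e6, 16569)),
        group_id = "g1", cnv_name = c("a", "b", "m"),
        state = c(2L, 2L, 5L))
    expect_message(
        sub <- regionsToArmEvents(gr, list(g1 = c("b1", "b2")), cb),
        "mitochondrial")
    expect_identical(as.character(eventSets(sub)[[1]]), "3q_loss")
})

test_that("centromere-spanning losses produce events on both arms", {
    cb <- toyCytoband()
    gr <- GenomicRanges::GRanges("3", IRanges::IRanges(80e6, 150e6),
                                 group_id = "g1", cnv_name = "r",
                                 state = 1L)
    sub <- regionsToArmEvents(gr, list(g1 = "b1"), cb)
    expect_setequal(as.character(eventSets(sub)[[1]]),
                    c("3p_loss", "3q_loss"))
})

test_that("gain/loss conflicts resolve by overlapped length, ties warn", {
    cb <- toyCytoband()
    ## gain covers the whole q arm, loss only part of it -> gain wins
    gr <- GenomicRanges::GRanges(
        c("8", "8"), IRanges::IRanges(c(45000001, 50e6), c(146e6, 60e6)),
        group_id = "g1", cnv_name = c("g", "l"), state = c(5L, 2L))
    sub <- regionsToArmEvents(gr, list(g1 = "b1"), cb)
    expect_identical(as.character(eventSets(sub)[[1]]), "8q_gain")

    ## identical extents in both directions -> keep both, warn
    gr2 <- GenomicRanges::GRanges(
        c("8", "8"), IRanges::IRanges(c(50e6, 50e6), c(60e6, 60e6)),
        group_id = "g1", cnv_name = c("g", "l"), state = c(5L, 2L))
    expect_warning(
        sub2 <- regionsToArmEvents(gr2, list(g1 = "b1"), cb),
        "equal overlapped length")
    expect_setequal(as.character(eventSets(sub2)[[1]]),
                    c("8q_gain", "8q_loss"))
})

test_that("minArmOverlap suppresses small-overlap arm calls", {
    cb <- toyCytoband()
    gr <- GenomicRanges::GRanges("3", IRanges::IRanges(95e6, 150e6),
                                 group_id = "g1", cnv_name = "r",
                                 state = 5L)
    loose <- regionsToArmEvents(gr, list(g1 = "b1"), cb)
    expect_setequal(as.character(eventSets(loose)[[1]]),
                    c("3p_gain", "3q_gain"))
    strict <- regionsToArmEvents(gr, list(g1 = "b1"), cb,
                                 minArmOverlap = 0.10)
    expect_identical(as.character(eventSets(strict)[[1]]), "3q_gain")
})

test_that("arm events are invariant to region order and splitting", {
    cb <- toyCytoband()
    whole <- GenomicRanges::GRanges("3", IRanges::IRanges(99e6, 198e6),
                                    group_id = "g1", cnv_name = "w",
                                    state = 2L)
    split2 <- GenomicRanges::GRanges(
        c("3", "3"), IRanges::IRanges(c(130e6, 99e6), c(198e6, 129999999)),
        group_id = "g1", cnv_name = c("b", "a"), state = 2L)
    g <- list(g1 = "b1")
    expect_identical(
        as.list(eventSets(regionsToArmEvents(whole, g, cb))),
        as.list(eventSets(regionsToArmEvents(split2, g, cb))))
    expect_identical(
        as.list(eventSets(regionsToArmEvents(split2, g, cb))),
        as.list(eventSets(regionsToArmEvents(rev(split2), g, cb))))
})

test_that("groups without regions yield empty event sets", {
    cb <- toyCytoband()
    gr <- GenomicRanges::GRanges("8", IRanges::IRanges(50e6, 146e6),
                                 group_id = "g1", cnv_name = "r",
                                 state = 5L)
    sub <- regionsToArmEvents(gr, list(g1 = "b1", g0 = c("b2", "b3")), cb)
    expect_length(eventSets(sub)[[match("g0", groupIds(sub))]], 0)
})

test_that("arm-events TSV lists one row per event with cell counts", {
    sub <- collapseSubclones(loh3Subclones())
    f <- tempfile()
    writeArmEvents(sub, f)
    tab <- read.table(f, header = TRUE, sep = "\t")
    expect_equal(nrow(tab), 3)   # 3q_loss + (3p_loss, 3q_loss)
    expect_setequal(tab$direction, "loss")
    expect_equal(sort(unique(tab$n_cells)), c(60, 170))
})
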