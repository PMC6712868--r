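mkGenes <- function(scaf, start, end, id = "g1") {
    gr <- GenomicRanges::GRanges(scaf, IRanges::IRanges(start, end))
    S4Vectors::mcols(gr)$gene_id <- id
    gr
}

mkMap <- function(df) {
    readSyntenyMap(writeTempSynteny(df))
}

mkAsm <- function(lens) {
    seqs <- lapply(lens, function(n) strrep("A", n))
    readGenome(writeTempFasta(seqs), "target")
}

cfg0 <- defaultRunConfig()

test_that("a gene inside one identity block maps to itself", {
    sm <- mkMap(synRow("c1", 1, 1000, "d1", 1, 1000))
    asm <- mkAsm(list(d1 = 1200))
    si <- inferSearchIntervals(mkGenes("c1", 101, 200), sm, asm, cfg0)
    expect_equal(nrow(si), 1L)
    expect_equal(si$tstart, 101L)
    expect_equal(si$tend, 200L)
    expect_true(si$left_bounded && si$right_bounded)
    expect_equal(si$scramble_score, 0)
    expect_false(si$at_scaffold_edge)
})

test_that("the gap-span rule bridges consistent anchors", {
    sm <- mkMap(rbind(synRow("c1", 1, 100, "d1", 1, 100),
                      synRow("c1", 501, 600, "d1", 701, 800)))
    asm <- mkAsm(list(d1 = 1000))
    si <- inferSearchIntervals(mkGenes("c1", 201, 400), sm, asm, cfg0)
    expect_equal(nrow(si), 1L)
    expect_equal(si$tstart, 101L)
    expect_equal(si$tend, 700L)
    expect_true(si$left_bounded && si$right_bounded)
})

test_that("minus-strand anchors swap left and right target sides", {
    ## block reversed: query left edge maps to target right edge
    sm <- mkMap(synRow("c1", 1, 1000, "d1", 1, 1000, strand = "-"))
    asm <- mkAsm(list(d1 = 1000))
    si <- inferSearchIntervals(mkGenes("c1", 101, 200), sm, asm, cfg0)
    expect_equal(si$tstart, 801L)
    expect_equal(si$tend, 900L)
})

test_that("a gene beyond the last block projects to the scaffold end", {
    sm <- mkMap(synRow("c1", 1, 1000, "d1", 1, 1000))
    asm <- mkAsm(list(d1 = 1000))   # block flush with scaffold end
    si <- inferSearchIntervals(mkGenes("c1", 1100, 1300), sm, asm, cfg0)
    expect_equal(nrow(si), 1L)
    expect_true(si$at_scaffold_edge)
    expect_false(si$right_bounded)
    expect_true(si$left_bounded)
    expect_equal(pmax(0L, si$tend - si$tstart + 1L), 0L)  # empty tail
})

test_that("discordant anchors emit two flanking projections and scramble", {
    sm <- mkMap(rbind(synRow("c1", 1, 100, "d1", 701, 800),
                      synRow("c1", 501, 600, "d1", 1, 100)))
    asm <- mkAsm(list(d1 = 1000))
    si <- inferSearchIntervals(mkGenes("c1", 201, 400), sm, asm, cfg0)
    expect_equal(nrow(si), 2L)
    expect_true(all(si$scramble_score > 0.5))
    expect_equal(sort(si$rule), c("flank", "flank"))
    expect_equal(sum(si$left_bounded), 1L)
    expect_equal(sum(si$right_bounded), 1L)
})

test_that("a scaffold with no blocks yields an explicit unmapped record", {
    sm <- mkMap(synRow("cOther", 1, 100, "d1", 1, 100))
    asm <- mkAsm(list(d1 = 200))
    si <- inferSearchIntervals(mkGenes("c1", 10, 50), sm, asm, cfg0)
    expect_equal(nrow(si), 1L)
    expect_true(si$unmapped)
})

test_that("every query gene yields at least one record per target", {
    set.seed(31)
    for (rep in 1:10) {
        nb <- sample(1:6, 1)
        qs <- sort(sample(1:5000, nb * 2))
        blks <- do.call(rbind, lapply(seq_len(nb), function(i)
            synRow("c1", qs[2 * i - 1], qs[2 * i], "d1",
                   ts <- sample(1:5000, 1), ts + (qs[2 * i] - qs[2 * i - 1]),
                   strand = sample(c("+", "-"), 1))))
        sm <- mkMap(blks)
        asm <- mkAsm(list(d1 = 12000))
        g <- sort(sample(1:6000, 2))
        si <- inferSearchIntervals(mkGenes("c1", g[1], g[2]), sm, asm, cfg0)
        expect_gte(nrow(si), 1L)
        si2 <- inferSearchIntervals(mkGenes("c1", g[1], g[2]), sm, asm,
                                    cfg0)
        expect_identical(si, si2)   # determinism
    }
})

test_that("endpoint interpolation brackets genes inside single blocks", {
    ## per-base mapping oracle: walk every base of the block
    set.seed(32)
    for (rep in 1:20) {
        qs <- sample(1:500, 1); w <- sample(200:800, 1)
        ts <- sample(1:500, 1)
        strand <- sample(c("+", "-"), 1)
        blk <- synRow("c1", qs, qs + w, "d1", ts, ts + w, strand = strand)
        g1 <- sample(qs:(qs + w - 10), 1); g2 <- g1 + sample(1:9, 1)
        oracle_map <- function(q) {
            if (strand == "+") ts + (q - qs) else (ts + w) - (q - qs)
        }
        si <- inferSearchIntervals(mkGenes("c1", g1, g2), mkMap(blk),
                                   mkAsm(list(d1 = 3000)), cfg0)
        expect_equal(si$tstart, min(oracle_map(g1), oracle_map(g2)))
        expect_equal(si$tend, max(oracle_map(g1), oracle_map(g2)))
    }
})

test_that("enlarging a gene never shrinks its search space", {
    set.seed(33)
    covered <- function(si) {
        m <- si[!si$unmapped & si$tend >= si$tstart, , drop = FALSE]
        if (!nrow(m)) return(IRanges::IRanges())
        IRanges::reduce(IRanges::IRanges(m$tstart, m$tend))
    }
    for (rep in 1:15) {
        nb <- sample(2:5, 1)
        pos <- sort(sample(1:4000, nb * 2))
        blks <- do.call(rbind, lapply(seq_len(nb), function(i)
            synRow("c1", pos[2 * i - 1], pos[2 * i], "d1",
                   ts <- sample(1:4000, 1),
                   ts + (pos[2 * i] - pos[2 * i - 1]),
                   strand = sample(c("+", "-"), 1))))
        sm <- mkMap(blks)
        asm <- mkAsm(list(d1 = 9000))
        g1 <- sample(1:4000, 1); g2 <- g1 + sample(50:500, 1)
        small <- covered(inferSearchIntervals(mkGenes("c1", g1, g2), sm,
                                              asm, cfg0))
        big <- covered(inferSearchIntervals(
            mkGenes("c1", max(1, g1 - 200), g2 + 200), sm, asm, cfg0))
        ## every base covered for the small gene stays covered
        leftover <- IRanges::setdiff(small, big)
        expect_equal(sum(IRanges::width(leftover)), 0L)
    }
})

test_that("contradictory blocks are a hard error", {
    sm <- mkMap(synRow("c1", 1, 100, "d1", 1, 100))
    sm@blocks$tend[1] <- 50L
    sm@blocks$tstart[1] <- 90L
    asm <- mkAsm(list(d1 = 200))
    expect_error(inferSearchIntervals(mkGenes("c1", 10, 50), sm, asm, cfg0),
                 "contradictory")
})

test_that("interval diagnostics flag indels, N runs and oversize", {
    asm <- mkAsm(list(d1 = 5000))
    si <- data.frame(query_gene_id = "g1", tseqid = "d1", tstart = 101L,
                     tend = 110L, left_bounded = TRUE, right_bounded = TRUE,
                     at_scaffold_edge = FALSE, scramble_score = 0,
                     rule = "gap", source_blocks = "1", unmapped = FALSE,
                     stringsAsFactors = FALSE)
    d <- intervalDiagnostics(si, geneLength = 1000L, asm, cfg0)
    expect_equal(d$length_ratio, 0.01)
    expect_lt(d$length_ratio, cfg0$indel_ratio)   # indel-eligible

    ## planted 50-nt N run inside the interval
    asmN <- readGenome(writeTempFasta(list(
        d1 = paste0(strrep("A", 200), strrep("N", 50), strrep("A", 200)))),
        "target")
    siN <- si; siN$tstart <- 150L; siN$tend <- 400L
    dN <- intervalDiagnostics(siN, 300L, asmN, cfg0)
    expect_true(dN$contains_n_run)

    cfgBig <- cfg0; cfgBig$max_interval_nt <- 100
    siBig <- si; siBig$tend <- 1000L
    dBig <- intervalDiagnostics(siBig, 300L, asm, cfgBig)
    expect_true(dBig$oversize)
})
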