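test_that("readGenome loads scaffolds and indexes N runs", {
    fa <- writeTempFasta(list(s1 = "ACGT"))
    g <- readGenome(fa, "sp")
    expect_equal(unname(scaffoldLengths(g)), 4L)
    expect_equal(names(scaffoldLengths(g)), "s1")
    expect_equal(length(nRuns(g)[["s1"]]), 0L)

    fa2 <- writeTempFasta(list(s1 = "ACNNNNA"))
    g2 <- readGenome(fa2, "sp")
    r <- nRuns(g2)[["s1"]]
    expect_equal(IRanges::start(r), 3L)
    expect_equal(IRanges::end(r), 6L)
})

test_that("readGenome rejects malformed input with precise errors", {
    dup <- tempfile(fileext = ".fa")
    writeLines(c(">s1", "ACGT", ">s1", "GGGG"), dup)
    expect_error(readGenome(dup), "duplicate scaffold")

    empty <- tempfile(fileext = ".fa")
    file.create(empty)
    expect_error(readGenome(empty), "empty|read")

    bad <- writeTempFasta(list(sX = "ACGTQACGT"))
    err <- tryCatch(readGenome(bad), error = conditionMessage)
    expect_match(err, "sX")
    expect_match(err, "5")   # offset of the offending character
})

test_that("FASTA round-trip reproduces sequences byte-identically", {
    set.seed(11)
    seqs <- stats::setNames(
        lapply(1:50, function(i) rdna(sample(50:300, 1))),
        paste0("scf", 1:50))
    fa <- writeTempFasta(seqs)
    g <- readGenome(fa, "sp")
    out <- tempfile(fileext = ".fa")
    writeGenome(g, out)
    g2 <- readGenome(out, "sp")
    expect_identical(as.character(g2@sequences), as.character(g@sequences))
    expect_identical(as.character(g@sequences[["scf7"]]), seqs[["scf7"]])
})

test_that("N-run index equals a naive linear scan", {
    set.seed(12)
    for (i in 1:20) {
        n <- sample(50:200, 1)
        ch <- sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                     prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
        s <- paste(ch, collapse = "")
        fa <- writeTempFasta(list(x = s))
        g <- readGenome(fa, "sp")
        r <- nRuns(g)[["x"]]
        expected <- nRunOracle(s)
        expect_equal(length(r), length(expected))
        for (k in seq_along(expected)) {
            expect_equal(IRanges::start(r)[k], expected[[k]][1])
            expect_equal(IRanges::end(r)[k], expected[[k]][2])
        }
    }
})

test_that("readGeneModels keeps GFF3 coordinates and flags bad CDS", {
    fa <- writeTempFasta(list(c1 = strrep("ACGT", 20)))
    asm <- readGenome(fa, "sp")
    gff <- writeTempGff(c(
        gffFeature("c1", "gene", 5, 40, "+", "ID=g1"),
        gffFeature("c1", "mRNA", 5, 40, "+", "ID=t1;Parent=g1"),
        gffFeature("c1", "exon", 5, 40, "+", "ID=e1;Parent=t1"),
        gffFeature("c1", "CDS", 11, 16, "+", "ID=c1cds;Parent=t1")))
    m <- readGeneModels(gff, asm)
    cd <- m@cds[["t1"]]
    expect_equal(IRanges::start(cd), 11L)   # 1-based closed, as in the file
    expect_equal(IRanges::end(cd), 16L)
    expect_equal(nrow(m@invalid), 0L)

    gff2 <- writeTempGff(c(
        gffFeature("c1", "gene", 5, 40, "+", "ID=g1"),
        gffFeature("c1", "mRNA", 5, 40, "+", "ID=t1;Parent=g1"),
        gffFeature("c1", "exon", 5, 40, "+", "ID=e1;Parent=t1"),
        gffFeature("c1", "CDS", 11, 20, "+", "ID=c1cds;Parent=t1")))
    m2 <- readGeneModels(gff2, asm)
    expect_equal(nrow(m2@invalid), 1L)
    expect_match(m2@invalid$reason, "multiple of 3")
    expect_true("t1" %in% m2@transcripts$tx_id)  # retained, not dropped
})

test_that("orphan CDS are grouped and unknown scaffolds reported", {
    fa <- writeTempFasta(list(c1 = strrep("ACGT", 20)))
    asm <- readGenome(fa, "sp")
    gff <- writeTempGff(c(
        gffFeature("c1", "CDS", 10, 18, "+", "ID=loner"),
        gffFeature("c9", "gene", 1, 10, "+", "ID=offmap")))
    m <- readGeneModels(gff, asm)
    expect_true(any(grepl("synthesized", m@transcripts$tx_id)))
    expect_true(any(grepl("unknown scaffold", m@invalid$reason)))
})

test_that("cyclic Parent links are a hard error", {
    fa <- writeTempFasta(list(c1 = strrep("ACGT", 20)))
    asm <- readGenome(fa, "sp")
    gff <- writeTempGff(c(
        gffFeature("c1", "gene", 1, 40, "+", "ID=a;Parent=b"),
        gffFeature("c1", "gene", 1, 40, "+", "ID=b;Parent=a")))
    expect_error(readGeneModels(gff, asm), "cyclic")
})

test_that("readSyntenyMap validates, converts and sorts", {
    p <- writeTempSynteny(synRow("c1", 1, 100, "d1", 201, 300, 50, "+"))
    sm <- readSyntenyMap(p)
    b <- blocks(sm)
    expect_equal(b$qstart, 1L); expect_equal(b$qend, 100L)
    expect_equal(b$tstart, 201L); expect_equal(b$tend, 300L)

    empty <- tempfile(); file.create(empty)
    expect_warning(sm0 <- readSyntenyMap(empty), "empty")
    expect_equal(nrow(blocks(sm0)), 0L)

    badp <- writeTempSynteny(synRow("c1", 100, 1, "d1", 1, 50))
    expect_error(readSyntenyMap(badp), "qstart > qend")
    bads <- writeTempSynteny(synRow("c1", 1, 100, "d1", 1, 100,
                                    strand = "?"))
    expect_error(readSyntenyMap(bads), "strand")

    ## sorted order against a comparison-sort oracle
    set.seed(13)
    rows <- do.call(rbind, lapply(1:30, function(i)
        synRow(sample(c("cA", "cB", "cC"), 1), s <- sample(1:1000, 1),
               s + 10, "d1", u <- sample(1:1000, 1), u + 10)))
    p2 <- writeTempSynteny(rows)
    got <- blocks(readSyntenyMap(p2))
    oracle <- rows[order(rows$qseqid, rows$qstart), ]
    expect_equal(got$qstart, oracle$qstart)
    expect_equal(got$qseqid, oracle$qseqid)
})

test_that("readSpeciesTree derives the ancestor path and cousin sets", {
    tr <- readSpeciesTree("((F,S1),(S2,S3));", "F")
    expect_equal(length(ancestorPath(tr)), 2L)  # K = 1
    expect_equal(cousinSets(tr)[[1]], "S1")
    expect_setequal(cousinSets(tr)[[2]], c("S2", "S3"))

    ## deeper caterpillar-with-cherry topology
    tr2 <- readSpeciesTree("(((F,At),Cr),(Es,Br));", "F")
    expect_equal(cousinSets(tr2)[[1]], "At")
    expect_equal(cousinSets(tr2)[[2]], "Cr")
    expect_setequal(cousinSets(tr2)[[3]], c("Es", "Br"))

    expect_error(readSpeciesTree("((A,B),C);", "F"), "focal")
})

test_that("cousin sets partition the non-focal leaves on random trees", {
    set.seed(14)
    for (i in 1:15) {
        tree <- ape::rtree(12)
        focal <- sample(tree$tip.label, 1)
        path <- tempfile(fileext = ".nwk")
        ape::write.tree(tree, path)
        tr <- readSpeciesTree(path, focal)
        sets <- cousinSets(tr)
        flat <- unlist(sets, use.names = FALSE)
        expect_equal(anyDuplicated(flat), 0L)
        expect_setequal(flat, setdiff(tree$tip.label, focal))
        oracle <- cousinOracle(tree, focal)
        expect_equal(length(sets), length(oracle))
        for (k in seq_along(sets))
            expect_setequal(sets[[k]], oracle[[k]])
    }
})

test_that("multifurcating trees are accepted", {
    tr <- readSpeciesTree("(F,A,B,(C,D));", "F")
    expect_equal(length(cousinSets(tr)), 1L)
    expect_setequal(cousinSets(tr)[[1]], c("A", "B", "C", "D"))
})
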