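mkModels <- function(seqs, gffLines) {
    fa <- writeTempFasta(seqs)
    asm <- readGenome(fa, "sp")
    m <- readGeneModels(writeTempGff(gffLines), asm)
    list(asm = asm, models = m)
}

test_that("plus-strand CDS translates directly", {
    x <- mkModels(list(c1 = paste0("TTTT", "ATGAAATAA", "GGGG")),
                  c(gffFeature("c1", "gene", 5, 13, "+", "ID=g1"),
                    gffFeature("c1", "mRNA", 5, 13, "+", "ID=t1;Parent=g1"),
                    gffFeature("c1", "exon", 5, 13, "+", "ID=e;Parent=t1"),
                    gffFeature("c1", "CDS", 5, 13, "+", "ID=c;Parent=t1")))
    d <- deriveSequences(x$asm, x$models)
    expect_equal(as.character(d@proteins[["t1"]]), "MK")
    expect_true(d@flags$valid[d@flags$tx_id == "t1"])
})

test_that("minus-strand CDS is reverse-complemented before translation", {
    ## genome stores the reverse complement of ATGAAATAA = TTATTTCAT
    x <- mkModels(list(c1 = paste0("TTTT", "TTATTTCAT", "GGGG")),
                  c(gffFeature("c1", "gene", 5, 13, "-", "ID=g1"),
                    gffFeature("c1", "mRNA", 5, 13, "-", "ID=t1;Parent=g1"),
                    gffFeature("c1", "exon", 5, 13, "-", "ID=e;Parent=t1"),
                    gffFeature("c1", "CDS", 5, 13, "-", "ID=c;Parent=t1")))
    d <- deriveSequences(x$asm, x$models)
    expect_equal(as.character(d@proteins[["t1"]]), "MK")
})

test_that("internal stops and missing starts are flagged and excluded", {
    x <- mkModels(list(c1 = paste0("ATGTAAAAATAA", "CCCAAATAA")),
                  c(gffFeature("c1", "gene", 1, 12, "+", "ID=g1"),
                    gffFeature("c1", "mRNA", 1, 12, "+", "ID=t1;Parent=g1"),
                    gffFeature("c1", "exon", 1, 12, "+", "ID=e1;Parent=t1"),
                    gffFeature("c1", "CDS", 1, 12, "+", "ID=cd1;Parent=t1"),
                    gffFeature("c1", "gene", 13, 21, "+", "ID=g2"),
                    gffFeature("c1", "mRNA", 13, 21, "+", "ID=t2;Parent=g2"),
                    gffFeature("c1", "exon", 13, 21, "+", "ID=e2;Parent=t2"),
                    gffFeature("c1", "CDS", 13, 21, "+", "ID=cd2;Parent=t2")))
    d <- deriveSequences(x$asm, x$models)
    fl <- as.data.frame(d@flags)
    expect_true(fl$internal_stop[fl$tx_id == "t1"])
    expect_true(fl$missing_start[fl$tx_id == "t2"])
    expect_false("t1" %in% names(d@proteins))
    expect_false("t2" %in% names(d@proteins))
})

test_that("CDS beyond the scaffold end is flagged, not fatal", {
    x <- mkModels(list(c1 = "ATGAAATAA"),
                  c(gffFeature("c1", "gene", 1, 30, "+", "ID=g1"),
                    gffFeature("c1", "mRNA", 1, 30, "+", "ID=t1;Parent=g1"),
                    gffFeature("c1", "exon", 1, 30, "+", "ID=e;Parent=t1"),
                    gffFeature("c1", "CDS", 1, 30, "+", "ID=c;Parent=t1")))
    d <- deriveSequences(x$asm, x$models)
    expect_true(d@flags$out_of_bounds[1])
    expect_equal(length(d@proteins), 0L)
})

test_that("multi-exon splicing assembles the CDS across introns", {
    ## CDS split ATGAAA | TAA around an intron of Gs
    x <- mkModels(list(c1 = paste0("ATGAAA", "GGGGGGG", "TAA", "TT")),
                  c(gffFeature("c1", "gene", 1, 16, "+", "ID=g1"),
                    gffFeature("c1", "mRNA", 1, 16, "+", "ID=t1;Parent=g1"),
                    gffFeature("c1", "exon", 1, 6, "+", "ID=e1;Parent=t1"),
                    gffFeature("c1", "exon", 14, 16, "+", "ID=e2;Parent=t1"),
                    gffFeature("c1", "CDS", 1, 6, "+", "ID=c1a;Parent=t1"),
                    gffFeature("c1", "CDS", 14, 16, "+", "ID=c1b;Parent=t1")))
    d <- deriveSequences(x$asm, x$models)
    expect_equal(as.character(d@cdsSeqs[["t1"]]), "ATGAAATAA")
    expect_equal(as.character(d@proteins[["t1"]]), "MK")
})

test_that("planted proteins are recovered from a generated fixture", {
    fx <- generateFixture(file.path(tempdir(), "fx-derive"), seed = 101,
                          nTargets = 1L)
    sp <- loadFixtureSpecies(fx$dir, "focal")
    expect_equal(length(sp$derived@proteins), 9L)
    ## every planted CDS translates cleanly: M start, no internal stop,
    ## protein length = CDS/3 - 1
    expect_true(all(sp$derived@flags$valid))
    expect_true(all(substr(as.character(sp$derived@proteins), 1, 1) == "M"))
    expect_true(all(Biostrings::width(sp$derived@proteins) == 396 / 3 - 1))
})

test_that("findOrfs matches hand-checked minimal cases", {
    o <- findOrfs("ATGAAATAA", minCodons = 2, bothStrands = FALSE)
    expect_equal(nrow(o), 1L)
    expect_equal(o$aa, "MK")
    expect_equal(o$start, 1L)
    expect_equal(o$end, 6L)     # stop codon excluded from the interval

    ## the default 30-codon cutoff suppresses short ORFs
    expect_equal(nrow(findOrfs("ATGAAATAA", minCodons = 30)), 0L)

    ## longest-per-stop: a nested ATG does not spawn a second ORF
    o2 <- findOrfs("ATGCCCATGAAATAA", minCodons = 2, bothStrands = FALSE)
    expect_equal(nrow(o2), 1L)
    expect_equal(o2$aa, "MPMK")
})

test_that("ORF finding is case-insensitive and strand-symmetric", {
    set.seed(21)
    s <- rdna(3000)
    a <- findOrfs(s, minCodons = 10)
    b <- findOrfs(tolower(s), minCodons = 10)
    expect_equal(a, b)

    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    fwd <- findOrfs(s, minCodons = 10, bothStrands = TRUE)
    rev <- findOrfs(rc, minCodons = 10, bothStrands = TRUE)
    ## ORFs of the reverse complement are the strand-flipped, mirrored ORFs
    n <- nchar(s)
    mirrored <- data.frame(start = n - rev$end + 1L, end = n - rev$start + 1L,
                           strand = ifelse(rev$strand == "+", "-", "+"),
                           aa = rev$aa, stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$end,
                               mirrored$strand), ]
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$end, mirrored$end)
    expect_equal(fwd$strand, mirrored$strand)
    expect_setequal(fwd$aa, mirrored$aa)
})

test_that("ambiguity codons never act as start or stop", {
    o <- findOrfs("ATNAAATAA", minCodons = 1, bothStrands = FALSE)
    expect_false(any(o$start == 1L & o$strand == "+"))
})

test_that("stop-to-stop mode is available", {
    ## no ATG anywhere, but a stop-terminated frame segment
    o <- findOrfs("CCCAAACCCTAA", minCodons = 3, bothStrands = FALSE,
                  requireAtg = FALSE)
    expect_equal(o$start[1], 1L)
    expect_equal(o$end[1], 9L)
})

test_that("non-CDS transcript ORFs exclude exactly the annotated CDS", {
    ## transcript = CDS only: no secondary ORFs
    x <- mkModels(list(c1 = "ATGAAACCCGGGTAA"),
                  c(gffFeature("c1", "gene", 1, 15, "+", "ID=g1"),
                    gffFeature("c1", "mRNA", 1, 15, "+", "ID=t1;Parent=g1"),
                    gffFeature("c1", "exon", 1, 15, "+", "ID=e;Parent=t1"),
                    gffFeature("c1", "CDS", 1, 15, "+", "ID=c;Parent=t1")))
    d <- deriveSequences(x$asm, x$models)
    expect_equal(nrow(nonCdsTranscriptOrfs(d, "t1", minCodons = 2)), 0L)

    ## an independent ORF in the 3' UTR is reported
    utr_orf <- paste0("ATG", strrep("GCT", 35), "TAA")
    x2 <- mkModels(
        list(c1 = paste0("ATGAAACCCGGGTAA", "TT", utr_orf)),
        c(gffFeature("c1", "gene", 1, 17 + nchar(utr_orf), "+", "ID=g1"),
          gffFeature("c1", "mRNA", 1, 17 + nchar(utr_orf), "+",
                     "ID=t1;Parent=g1"),
          gffFeature("c1", "exon", 1, 17 + nchar(utr_orf), "+",
                     "ID=e;Parent=t1"),
          gffFeature("c1", "CDS", 1, 15, "+", "ID=c;Parent=t1")))
    d2 <- deriveSequences(x2$asm, x2$models)
    o <- nonCdsTranscriptOrfs(d2, "t1", minCodons = 30)
    expect_equal(nrow(o), 1L)
    expect_equal(o$aa, paste0("M", strrep("A", 35)))
})

test_that("transcript ORFs equal findOrfs minus exact-CDS matches", {
    set.seed(22)
    for (i in 1:5) {
        body <- rdna(600)
        x <- mkModels(list(c1 = body),
                      c(gffFeature("c1", "gene", 1, 600, "+", "ID=g1"),
                        gffFeature("c1", "mRNA", 1, 600, "+",
                                   "ID=t1;Parent=g1"),
                        gffFeature("c1", "exon", 1, 600, "+",
                                   "ID=e;Parent=t1"),
                        gffFeature("c1", "CDS", 7, 42, "+",
                                   "ID=c;Parent=t1")))
        d <- deriveSequences(x$asm, x$models)
        got <- nonCdsTranscriptOrfs(d, "t1", minCodons = 5)
        all_orfs <- findOrfs(body, minCodons = 5, bothStrands = FALSE)
        keep <- !(all_orfs$start == 7L & all_orfs$end == 42L - 3L)
        expect_equal(got$start, all_orfs$start[keep])
        expect_equal(got$end, all_orfs$end[keep])
    }
})

test_that("representative protein is the longest valid CDS of each gene", {
    x <- mkModels(
        list(c1 = paste0("ATGAAATAA", "T", "ATGAAACCCGGGTAA")),
        c(gffFeature("c1", "gene", 1, 24, "+", "ID=g1"),
          gffFeature("c1", "mRNA", 1, 9, "+", "ID=t1;Parent=g1"),
          gffFeature("c1", "exon", 1, 9, "+", "ID=e1;Parent=t1"),
          gffFeature("c1", "CDS", 1, 9, "+", "ID=c1a;Parent=t1"),
          gffFeature("c1", "mRNA", 11, 24, "+", "ID=t2;Parent=g1"),
          gffFeature("c1", "exon", 11, 25, "+", "ID=e2;Parent=t2"),
          gffFeature("c1", "CDS", 11, 25, "+", "ID=c2a;Parent=t2")))
    d <- deriveSequences(x$asm, x$models)
    reps <- representativeProteins(d)
    expect_equal(names(reps), "g1")
    expect_equal(as.character(reps[[1]]), "MKPG")
})
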