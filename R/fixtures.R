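## Seeded generator of miniature focal + target genome bundles with planted,
## labelled evolutionary scenarios.  Each scenario occupies its own scaffold
## pair, so expected homology classes are provable by construction:
##
##   conserved_annotated  ortholog kept and annotated            -> A_gen
##   utr_orf_homolog      homology moved into a 3' UTR ORF of an
##                        annotated (otherwise unrelated) gene    -> A_trn
##   unannotated_ortholog ortholog kept, annotation dropped       -> A_orf
##   de_novo_precursor    nucleotide identity kept, reading frame
##                        destroyed (no ORF >= 30 codons left)    -> N_dna
##   indel_loss           locus cleanly deleted between anchors   -> U_ind
##   scrambled_region     local anchor order reversed, locus gone -> U_scr
##   scaffold_truncated   target scaffold ends before the locus   -> U_una
##   n_gap                locus replaced by a run of Ns           -> U_nst
##   no_match             locus replaced by random sequence       -> U_nm
##
## Mutation is substitution-only (structural change is scenario-level), so
## the expected labels stay provable.  Every scenario's defining property is
## asserted at generation time by independent brute-force checks, not by
## the pipeline under test.

FIXTURE_SCENARIOS <- c("conserved_annotated", "utr_orf_homolog",
                       "unannotated_ortholog", "de_novo_precursor",
                       "indel_loss", "scrambled_region",
                       "scaffold_truncated", "n_gap", "no_match")

.SCENARIO_LABEL <- c(conserved_annotated = "A_gen",
                     utr_orf_homolog = "A_trn",
                     unannotated_ortholog = "A_orf",
                     de_novo_precursor = "N_dna",
                     indel_loss = "U_ind",
                     scrambled_region = "U_scr",
                     scaffold_truncated = "U_una",
                     n_gap = "U_nst",
                     no_match = "U_nm")

.randSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.SENSE_CODONS <- local({
    all3 <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T"), paste0)),
                            c("A", "C", "G", "T"), paste0))
    setdiff(all3, c("TAA", "TAG", "TGA"))
})

## ATG + (nCodons - 1) sense codons + TAA; protein length = nCodons aa.
.randCds <- function(nCodons) {
    paste0("ATG",
           paste(sample(.SENSE_CODONS, nCodons - 1L, replace = TRUE),
                 collapse = ""),
           "TAA")
}

.revComp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Mutate a sequence with i.i.d. substitutions
#'
#' Each site is substituted with probability \code{rate} (to a uniformly
#' chosen different base).  Uses the current RNG stream.  The realized
#' substitution count is attached as attribute \code{n_substitutions}.
#'
#' @param seq a character string or \link[Biostrings]{DNAString}.
#' @param rate per-site substitution probability in [0, 0.5].
#' @return the mutated sequence (character) with attribute
#'   \code{n_substitutions}.
#' @export
mutateSequence <- function(seq, rate) {
    stopifnot(rate >= 0, rate <= 0.5)
    s <- strsplit(toupper(as.character(seq)), "")[[1]]
    hit <- which(stats::runif(length(s)) < rate & s %in% c("A", "C", "G", "T"))
    for (i in hit)
        s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
    out <- paste(s, collapse = "")
    attr(out, "n_substitutions") <- length(hit)
    out
}

## Substitution-only mutation of a CDS that provably keeps it a valid ORF:
## the ATG start and terminal stop are untouched and any substitution that
## would create an internal stop codon is reverted.
.mutateKeepOrf <- function(cds, rate) {
    s <- strsplit(cds, "")[[1]]
    n <- length(s)
    hit <- which(stats::runif(n) < rate)
    hit <- hit[hit > 3L & hit <= n - 3L]
    for (i in hit) {
        old <- s[i]
        s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
        cstart <- i - ((i - 1L) %% 3L)
        codon <- paste(s[cstart:(cstart + 2L)], collapse = "")
        if (codon %in% c("TAA", "TAG", "TGA")) s[i] <- old
    }
    paste(s, collapse = "")
}

## Independent brute-force ORF presence check (plain codon loop; kept free
## of the package's findOrfs so generation-time assertions do not depend on
## the code under test).
.bruteHasOrf <- function(seq, minCodons) {
    for (str in c(seq, .revComp(seq))) {
        n <- nchar(str)
        for (off in 0:2) {
            run <- 0L; started <- FALSE
            i <- off + 1L
            while (i + 2L <= n) {
                codon <- substr(str, i, i + 2L)
                if (codon %in% c("TAA", "TAG", "TGA")) {
                    if (started && run >= minCodons) return(TRUE)
                    started <- FALSE; run <- 0L
                } else if (started) {
                    run <- run + 1L
                } else if (codon == "ATG") {
                    started <- TRUE; run <- 1L
                }
                i <- i + 3L
            }
        }
    }
    FALSE
}

## Frameshift-disrupt a CDS copy: light substitution noise, then 1-nt
## deletions on a grid; any surviving ORF >= minCodons is broken by planting
## a stop inside it, re-checked with the brute-force scan.
.frameshiftDisrupt <- function(cds, minCodons, subRate = 0.02,
                               delEvery = 60L) {
    s <- mutateSequence(cds, subRate)
    v <- strsplit(s, "")[[1]]
    del <- seq(delEvery, length(v) - 10L, by = delEvery)
    v <- v[-del]
    out <- paste(v, collapse = "")
    ## a planted forward stop (TAA) can overwrite a reverse-strand stop
    ## (its complement reads TTA), so single fixes may uncover new ORFs on
    ## the other strand; jittered plant positions make the loop converge
    for (iter in 1:200) {
        if (!.bruteHasOrf(out, minCodons)) break
        found <- FALSE
        for (strand in c("+", "-")) {
            str <- if (strand == "+") out else .revComp(out)
            n <- nchar(str)
            for (off in 0:2) {
                start <- NA
                i <- off + 1L
                while (i + 2L <= n) {
                    codon <- substr(str, i, i + 2L)
                    if (codon %in% c("TAA", "TAG", "TGA")) {
                        start <- NA
                    } else if (codon == "ATG" && is.na(start)) {
                        start <- i
                    } else if (!is.na(start) &&
                               (i - start) / 3L + 1L >= minCodons) {
                        k <- sample(seq(3L, minCodons - 3L), 1L)
                        mid <- start + 3L * k
                        substr(str, mid, mid + 2L) <-
                            sample(c("TAA", "TAG", "TGA"), 1L)
                        out <- if (strand == "+") str else .revComp(str)
                        found <- TRUE
                        break
                    }
                    i <- i + 3L
                }
                if (found) break
            }
            if (found) break
        }
        if (!found) break
    }
    if (.bruteHasOrf(out, minCodons))
        stop("fixture self-check failed: de novo precursor still carries ",
             "an ORF of >= ", minCodons, " codons")
    out
}

.gffLine <- function(seqid, type, start, end, strand, attrs) {
    paste(seqid, "synphylo", type, start, end, ".", strand, ".", attrs,
          sep = "\t")
}

## gene + single mRNA + exon + CDS records
.gffGene <- function(seqid, gid, start, end, strand,
                     cds_start = start, cds_end = end,
                     exon_start = start, exon_end = end) {
    tid <- paste0(gid, ".t1")
    c(.gffLine(seqid, "gene", start, end, strand, paste0("ID=", gid)),
      .gffLine(seqid, "mRNA", start, end, strand,
               paste0("ID=", tid, ";Parent=", gid)),
      .gffLine(seqid, "exon", exon_start, exon_end, strand,
               paste0("ID=", tid, ".e1;Parent=", tid)),
      .gffLine(seqid, "CDS", cds_start, cds_end, strand,
               paste0("ID=", tid, ".c1;Parent=", tid)))
}

.writeFasta <- function(seqs, path, width = 70L) {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
        writeLines(paste0(">", nm), con)
        s <- seqs[[nm]]
        starts <- seq(1L, nchar(s), by = width)
        writeLines(substring(s, starts, pmin(starts + width - 1L,
                                             nchar(s))), con)
    }
    invisible(path)
}

## One target genome: per scenario, an edited copy of the focal scaffold,
## plus the matching GFF lines and synteny-map rows.
.buildTarget <- function(focal, targetId, geneLen, segLen, nSeg, mutRate,
                         minOrfCodons) {
    seqs <- list(); gff <- character(); syn <- list(); truth <- list()
    flankLen <- segLen * nSeg
    gStart <- flankLen + 1L
    gEnd <- flankLen + geneLen
    synRow <- function(qs, q1, q2, ts, t1, t2, strand = "+")
        data.frame(qseqid = qs, qstart = q1, qend = q2, tseqid = ts,
                   tstart = t1, tend = t2,
                   score = as.numeric(q2 - q1 + 1L), strand = strand,
                   stringsAsFactors = FALSE)

    for (sc in FIXTURE_SCENARIOS) {
        f <- focal[[sc]]
        qs <- f$scaffold_id
        ts <- paste0(targetId, "_", sc)
        fa <- mutateSequence(f$flankA, mutRate)
        fb <- mutateSequence(f$flankB, mutRate)
        qlen <- nchar(f$seq)
        if (sc == "conserved_annotated" || sc == "unannotated_ortholog") {
            cds_t <- .mutateKeepOrf(f$cds, mutRate)
            locus <- if (f$strand == "+") cds_t else .revComp(cds_t)
            seqs[[ts]] <- paste0(fa, locus, fb)
            syn[[length(syn) + 1L]] <- synRow(qs, 1L, qlen, ts, 1L, qlen)
            if (sc == "conserved_annotated")
                gff <- c(gff, .gffGene(ts, paste0(targetId, "_", sc, "_g"),
                                       gStart, gEnd, f$strand))
        } else if (sc == "utr_orf_homolog") {
            decoy <- .randCds(60L)
            spacer <- .randSeq(30L)
            utr_orf <- .mutateKeepOrf(f$cds, mutRate)
            locus <- paste0(decoy, spacer, utr_orf)
            stopifnot(.bruteHasOrf(utr_orf, minOrfCodons))
            seqs[[ts]] <- paste0(fa, locus, fb)
            tEnd <- gStart + nchar(locus) - 1L
            gff <- c(gff, .gffGene(ts, paste0(targetId, "_", sc, "_g"),
                                   gStart, tEnd, "+",
                                   cds_start = gStart,
                                   cds_end = gStart + nchar(decoy) - 1L))
            syn[[length(syn) + 1L]] <- synRow(qs, 1L, flankLen, ts, 1L,
                                              flankLen)
            syn[[length(syn) + 1L]] <- synRow(qs, gEnd + 1L, qlen, ts,
                                              tEnd + 1L,
                                              tEnd + flankLen)
        } else if (sc == "de_novo_precursor") {
            sense <- if (f$strand == "+") f$cds else .revComp(f$cds)
            locus <- .frameshiftDisrupt(sense, minOrfCodons)
            ## self-check: the edit budget keeps nucleotide identity high
            if (nchar(locus) < 0.93 * geneLen)
                stop("fixture self-check failed: de novo precursor lost ",
                     "too much sequence")
            seqs[[ts]] <- paste0(fa, locus, fb)
            tEnd <- gStart + nchar(locus) - 1L
            syn[[length(syn) + 1L]] <- synRow(qs, 1L, flankLen, ts, 1L,
                                              flankLen)
            syn[[length(syn) + 1L]] <- synRow(qs, gEnd + 1L, qlen, ts,
                                              tEnd + 1L, tEnd + flankLen)
        } else if (sc == "indel_loss") {
            seqs[[ts]] <- paste0(fa, fb)
            syn[[length(syn) + 1L]] <- synRow(qs, 1L, flankLen, ts, 1L,
                                              flankLen)
            syn[[length(syn) + 1L]] <- synRow(qs, gEnd + 1L, qlen, ts,
                                              flankLen + 1L, 2L * flankLen)
        } else if (sc == "scrambled_region") {
            pad1 <- .randSeq(500L); pad2 <- .randSeq(500L)
            segs_q <- c(f$segsA, f$segsB)          # s1..s8 in query order
            perm <- c(4L, 3L, 2L, 1L, 8L, 7L, 6L, 5L)
            segs_t <- lapply(segs_q[perm],
                             function(s) mutateSequence(s, mutRate))
            seqs[[ts]] <- paste0(pad1, paste(unlist(segs_t), collapse = ""),
                                 pad2)
            qStarts <- c((seq_len(nSeg) - 1L) * segLen + 1L,
                         gEnd + (seq_len(nSeg) - 1L) * segLen + 1L)
            tStarts <- 500L + (order(perm) - 1L) * segLen + 1L
            for (i in seq_along(segs_q)) {
                syn[[length(syn) + 1L]] <- synRow(
                    qs, qStarts[i], qStarts[i] + segLen - 1L,
                    ts, tStarts[i], tStarts[i] + segLen - 1L)
            }
        } else if (sc == "scaffold_truncated") {
            seqs[[ts]] <- fa
            syn[[length(syn) + 1L]] <- synRow(qs, 1L, flankLen, ts, 1L,
                                              flankLen)
        } else if (sc == "n_gap") {
            nRun <- strrep("N", geneLen + 100L)
            seqs[[ts]] <- paste0(fa, nRun, fb)
            tEnd <- gStart + nchar(nRun) - 1L
            syn[[length(syn) + 1L]] <- synRow(qs, 1L, flankLen, ts, 1L,
                                              flankLen)
            syn[[length(syn) + 1L]] <- synRow(qs, gEnd + 1L, qlen, ts,
                                              tEnd + 1L, tEnd + flankLen)
        } else if (sc == "no_match") {
            locus <- .randSeq(geneLen)
            seqs[[ts]] <- paste0(fa, locus, fb)
            tEnd <- gStart + geneLen - 1L
            syn[[length(syn) + 1L]] <- synRow(qs, 1L, flankLen, ts, 1L,
                                              flankLen)
            syn[[length(syn) + 1L]] <- synRow(qs, gEnd + 1L, qlen, ts,
                                              tEnd + 1L, tEnd + flankLen)
        }
        truth[[length(truth) + 1L]] <- data.frame(
            query_gene_id = f$gene_id, target_species = targetId,
            scenario = sc, expected_label = unname(.SCENARIO_LABEL[sc]),
            stringsAsFactors = FALSE)
    }
    syn <- do.call(rbind, syn)
    syn <- syn[order(syn$qseqid, syn$qstart), , drop = FALSE]
    list(seqs = seqs, gff = gff, syn = syn,
         truth = do.call(rbind, truth))
}

#' Generate a planted-scenario fixture bundle
#'
#' Writes a complete miniature input set - focal genome FASTA + GFF3, one
#' genome/GFF3/synteny-map triple per target, a Newick species tree and a
#' YAML run configuration - into \code{dir}, together with a ground-truth
#' table of expected homology labels, UNA vectors and phylostrata.  The
#' same seed always reproduces the bundle byte for byte.
#'
#' The focal species carries one query gene per scenario on its own
#' scaffold (coding length \code{geneLen}, flanked by \code{nSeg} anchor
#' segments of \code{segLen} nt on each side).  Targets on a caterpillar
#' tree are edited copies of the focal scaffolds; both targets receive the
#' same scenario for a given gene, so the expected UNA vector is the
#' scenario's collapsed label repeated.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; all randomness derives from it.
#' @param nTargets number of target species (2-4).
#' @param geneLen query CDS length in nt (multiple of 3).
#' @param segLen anchor segment length in nt.
#' @param nSeg anchor segments per flank.
#' @param mutRate per-site substitution rate applied to target copies.
#' @param minOrfCodons ORF cutoff used for generation-time self-checks.
#' @return invisible list: \code{dir}, \code{config} (path),
#'   \code{ground_truth} (data.frame, also written as
#'   \code{ground_truth.tsv}), and per-file paths.
#' @export
generateFixture <- function(dir, seed = 1L, nTargets = 2L, geneLen = 396L,
                            segLen = 400L, nSeg = 4L, mutRate = 0.05,
                            minOrfCodons = 30L) {
    stopifnot(geneLen %% 3L == 0L, nTargets >= 1L, nTargets <= 4L)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old_seed))
            assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)

    flankLen <- segLen * nSeg
    gStart <- flankLen + 1L
    gEnd <- flankLen + geneLen

    ## focal scaffolds: one per scenario
    focal <- list()
    focal_seqs <- list()
    focal_gff <- character()
    strands <- rep(c("+", "-"), length.out = length(FIXTURE_SCENARIOS))
    for (i in seq_along(FIXTURE_SCENARIOS)) {
        sc <- FIXTURE_SCENARIOS[i]
        segsA <- lapply(seq_len(nSeg), function(j) .randSeq(segLen))
        segsB <- lapply(seq_len(nSeg), function(j) .randSeq(segLen))
        cds <- .randCds(geneLen / 3L - 1L)   # protein geneLen/3 - 1 aa
        strand <- strands[i]
        locus <- if (strand == "+") cds else .revComp(cds)
        scaffold_id <- paste0("f_", sc)
        seq <- paste0(paste(unlist(segsA), collapse = ""), locus,
                      paste(unlist(segsB), collapse = ""))
        gene_id <- paste0("g_", sc)
        focal[[sc]] <- list(scaffold_id = scaffold_id, gene_id = gene_id,
                            cds = cds, strand = strand, seq = seq,
                            flankA = paste(unlist(segsA), collapse = ""),
                            flankB = paste(unlist(segsB), collapse = ""),
                            segsA = segsA, segsB = segsB)
        focal_seqs[[scaffold_id]] <- seq
        focal_gff <- c(focal_gff,
                       .gffGene(scaffold_id, gene_id, gStart, gEnd, strand))
    }

    paths <- list(
        focal_fa = file.path(dir, "focal.fa"),
        focal_gff = file.path(dir, "focal.gff3"),
        tree = file.path(dir, "tree.nwk"),
        config = file.path(dir, "config.yaml"),
        ground_truth = file.path(dir, "ground_truth.tsv"))
    .writeFasta(focal_seqs, paths$focal_fa)
    writeLines(c("##gff-version 3", focal_gff), paths$focal_gff)

    target_ids <- paste0("target", seq_len(nTargets))
    truth_all <- list()
    target_cfg <- list()
    for (ti in seq_len(nTargets)) {
        tid <- target_ids[ti]
        tg <- .buildTarget(focal, tid, geneLen, segLen, nSeg, mutRate,
                           minOrfCodons)
        fa_path <- file.path(dir, paste0(tid, ".fa"))
        gff_path <- file.path(dir, paste0(tid, ".gff3"))
        syn_path <- file.path(dir, paste0("focal_vs_", tid, ".tsv"))
        .writeFasta(tg$seqs, fa_path)
        writeLines(c("##gff-version 3", tg$gff), gff_path)
        utils::write.table(tg$syn, syn_path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        truth_all[[ti]] <- tg$truth
        target_cfg[[ti]] <- list(id = tid, genome = fa_path,
                                 gff = gff_path, synteny = syn_path)
        paths[[paste0(tid, "_fa")]] <- fa_path
    }

    ## caterpillar tree: focal pairs with target1, deeper targets nest out
    nwk <- "focal"
    for (ti in seq_len(nTargets))
        nwk <- paste0("(", nwk, ",", target_ids[ti], ")")
    writeLines(paste0(nwk, ";"), paths$tree)

    ## ground truth: labels per pair, plus UNA vector and stratum per gene
    truth <- do.call(rbind, truth_all)
    ancestors <- paste0("p", seq_len(nTargets) - 1L)
    per_gene <- lapply(FIXTURE_SCENARIOS, function(sc) {
        lab <- .SCENARIO_LABEL[[sc]]
        grp <- substr(lab, 1, 1)
        una_def <- strrep(grp, nTargets)
        grp_strict <- if (lab %in% c("A_trn", "A_orf")) "U" else grp
        una_str <- strrep(grp_strict, nTargets)
        str_of <- function(una) {
            g <- substr(una, 1, 1)
            if (g == "A") ancestors[nTargets]
            else if (g == "N") "focal_specific"
            else "unknown"
        }
        data.frame(query_gene_id = focal[[sc]]$gene_id, scenario = sc,
                   expected_una_default = una_def,
                   expected_una_strict = una_str,
                   expected_stratum_default = str_of(una_def),
                   expected_stratum_strict = str_of(una_str),
                   stringsAsFactors = FALSE)
    })
    truth <- merge(truth, do.call(rbind, per_gene),
                   by = c("query_gene_id", "scenario"), sort = FALSE)
    truth <- truth[order(truth$query_gene_id, truth$target_species), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    writeTsv(truth, paths$ground_truth)

    cfg <- list(
        focal = list(id = "focal", genome = paths$focal_fa,
                     gff = paths$focal_gff),
        targets = target_cfg,
        tree = paths$tree,
        outdir = file.path(dir, "out"),
        seed = seed)
    yaml::write_yaml(cfg, paths$config)

    invisible(list(dir = dir, config = paths$config, ground_truth = truth,
                   paths = paths))
}
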