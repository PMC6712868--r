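## Independent brute-force oracles and small fixture builders.  These stay
## deliberately naive (plain loops, direct table lookups) so they share no
## code path with the implementations they check.

## ---- affine-gap local alignment, O(nm) Gotoh --------------------------
## Gap of length L costs gapOpen + L * gapExt (matching the package's
## scoring convention).  The empty alignment scores 0.
swOracle <- function(a, b, submat, gapOpen, gapExt) {
    A <- strsplit(toupper(a), "")[[1]]
    B <- strsplit(toupper(b), "")[[1]]
    n <- length(A); m <- length(B)
    M <- matrix(0, n + 1L, m + 1L)
    Ix <- matrix(-Inf, n + 1L, m + 1L)
    Iy <- matrix(-Inf, n + 1L, m + 1L)
    best <- 0
    for (i in seq_len(n) + 1L) {
        for (j in seq_len(m) + 1L) {
            Ix[i, j] <- max(M[i - 1L, j] - gapOpen - gapExt,
                            Ix[i - 1L, j] - gapExt)
            Iy[i, j] <- max(M[i, j - 1L] - gapOpen - gapExt,
                            Iy[i, j - 1L] - gapExt)
            s <- submat[A[i - 1L], B[j - 1L]]
            M[i, j] <- max(0,
                           M[i - 1L, j - 1L] + s,
                           Ix[i - 1L, j - 1L] + s,
                           Iy[i - 1L, j - 1L] + s)
            if (M[i, j] > best) best <- M[i, j]
        }
    }
    best
}

ntOracleMatrix <- function(match = 2, mismatch = -3) {
    b <- c("A", "C", "G", "T")
    m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
    diag(m) <- match
    m
}

blosum62 <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            cache <<- e$BLOSUM62
        }
        cache
    }
})

## ---- naive per-frame ORF scan -----------------------------------------
codonTable <- Biostrings::GENETIC_CODE

orfOracleStrand <- function(s, minCodons, requireAtg, strand, fullLen) {
    n <- nchar(s)
    rows <- list()
    for (off in 0:2) {
        ncod <- (n - off) %/% 3L
        if (ncod < 1L) next
        pos <- off + 1L + 3L * (seq_len(ncod) - 1L)
        codons <- substring(s, pos, pos + 2L)
        start_ci <- NA_integer_
        for (ci in seq_len(ncod)) {
            codon <- codons[ci]
            if (codon == "TAA" || codon == "TAG" || codon == "TGA") {
                if (!is.na(start_ci) && ci - start_ci >= minCodons) {
                    fs <- off + 1L + 3L * (start_ci - 1L)
                    fe <- off + 3L * (ci - 1L)
                    cds <- codons[start_ci:(ci - 1L)]
                    aa <- paste(ifelse(cds %in% names(codonTable),
                                       codonTable[cds], "X"),
                                collapse = "")
                    st <- if (strand == "+") fs else fullLen - fe + 1L
                    en <- if (strand == "+") fe else fullLen - fs + 1L
                    rows[[length(rows) + 1L]] <- data.frame(
                        start = st, end = en, strand = strand,
                        frame = off + 1L, aa = aa,
                        stringsAsFactors = FALSE)
                }
                start_ci <- if (requireAtg) NA_integer_ else ci + 1L
            } else if (codon == "ATG" && requireAtg && is.na(start_ci)) {
                start_ci <- ci
            } else if (!requireAtg && is.na(start_ci)) {
                start_ci <- ci
            }
        }
    }
    rows
}

orfOracle <- function(seq, minCodons, bothStrands = TRUE,
                      requireAtg = TRUE) {
    s <- toupper(as.character(seq))
    rows <- orfOracleStrand(s, minCodons, requireAtg, "+", nchar(s))
    if (bothStrands) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        rows <- c(rows, orfOracleStrand(rc, minCodons, requireAtg, "-",
                                        nchar(s)))
    }
    if (!length(rows))
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), frame = integer(),
                          aa = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## ---- Eq-style subtree collapse, literal reading -----------------------
collapseOracle <- function(groups) {
    any_A <- FALSE; all_N <- TRUE
    for (g in groups) {
        if (g == "AAic") any_A <- TRUE
        if (g != "NTic") all_N <- FALSE
    }
    if (any_A) "A" else if (all_N) "N" else "U"
}

## ---- cousin sets via ape::extract.clade -------------------------------
cousinOracle <- function(tree, focal) {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node <- which(tree$tip.label == focal)
    path <- integer()
    while (node != root) {
        node <- tree$edge[tree$edge[, 2] == node, 1]
        path <- c(path, node)
    }
    sets <- list()
    prev <- focal
    for (nd in path) {
        tips <- if (nd == root) tree$tip.label
                else ape::extract.clade(tree, nd)$tip.label
        sets[[length(sets) + 1L]] <- setdiff(tips, prev)
        prev <- tips
    }
    sets
}

## ---- naive N-run scan -------------------------------------------------
nRunOracle <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    runs <- list(); in_run <- FALSE; st <- 0L
    for (i in seq_along(ch)) {
        if (ch[i] == "N" && !in_run) { in_run <- TRUE; st <- i }
        if (ch[i] != "N" && in_run) {
            in_run <- FALSE
            runs[[length(runs) + 1L]] <- c(st, i - 1L)
        }
    }
    if (in_run) runs[[length(runs) + 1L]] <- c(st, length(ch))
    runs
}

## ---- tiny on-disk fixtures --------------------------------------------
writeTempFasta <- function(seqs) {
    path <- tempfile(fileext = ".fa")
    con <- file(path, "w")
    for (nm in names(seqs)) {
        writeLines(paste0(">", nm), con)
        writeLines(seqs[[nm]], con)
    }
    close(con)
    path
}

writeTempGff <- function(lines) {
    path <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", lines), path)
    path
}

gffFeature <- function(seqid, type, start, end, strand, attrs) {
    paste(seqid, "test", type, start, end, ".", strand, ".", attrs,
          sep = "\t")
}

writeTempSynteny <- function(df) {
    path <- tempfile(fileext = ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
}

synRow <- function(qseqid, qstart, qend, tseqid, tstart, tend, score = 100,
                   strand = "+") {
    data.frame(qseqid = qseqid, qstart = qstart, qend = qend,
               tseqid = tseqid, tstart = tstart, tend = tend,
               score = score, strand = strand, stringsAsFactors = FALSE)
}

## random DNA of length n
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

## load one species of a generated fixture through the public readers
loadFixtureSpecies <- function(dir, id) {
    fa <- file.path(dir, paste0(id, ".fa"))
    gff <- file.path(dir, paste0(id, ".gff3"))
    assembly <- readGenome(fa, speciesId = id)
    models <- readGeneModels(gff, assembly)
    derived <- deriveSequences(assembly, models)
    list(assembly = assembly, models = models, derived = derived)
}
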