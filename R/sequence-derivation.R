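#' @importFrom Biostrings DNAString DNAStringSet AAStringSet translate
#'   reverseComplement subseq xscat
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Splice one transcript: extract exon (or CDS) pieces in genomic order and
## concatenate; reverse-complement afterwards for minus-strand models, so the
## result reads 5'->3'.
.spliceParts <- function(scafSeq, parts, strand) {
    parts <- BiocGenerics::sort(parts)
    pieces <- lapply(seq_along(parts), function(i)
        Biostrings::subseq(scafSeq, IRanges::start(parts)[i],
                           IRanges::end(parts)[i]))
    s <- do.call(Biostrings::xscat, pieces)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    s
}

#' Derive transcripts, CDS and proteins from gene models
#'
#' For every transcript, splices the exon sequence and the CDS sequence
#' (reverse-complemented for minus-strand models) and translates the CDS with
#' the standard genetic code.  The terminal stop codon is excluded from the
#' protein string.  Transcripts failing any validity check (CDS beyond the
#' scaffold end, CDS length not a multiple of three, missing ATG start,
#' internal stop codon) are flagged and yield no protein; they are excluded
#' from homology search but still counted in validation summaries.
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param models the matching \linkS4class{GeneModels}.
#' @return a \linkS4class{DerivedSequences}.
#' @export
deriveSequences <- function(assembly, models) {
    tx  <- models@transcripts
    n   <- length(tx)
    txs <- vector("list", n)
    cdss <- vector("list", n)
    prots <- list()
    cds_in_tx <- IRanges::IRanges()
    cds_tx_names <- character()
    io_invalid <- models@invalid$tx_id

    flags <- S4Vectors::DataFrame(
        tx_id = as.character(tx$tx_id),
        gene_id = as.character(tx$gene_id),
        valid = logical(n),
        internal_stop = logical(n),
        missing_start = logical(n),
        not_mult3 = logical(n),
        out_of_bounds = logical(n))

    seqs <- assembly@sequences
    slen <- scaffoldLengths(assembly)

    for (i in seq_len(n)) {
        tid <- flags$tx_id[i]
        scaf <- as.character(GenomicRanges::seqnames(tx))[i]
        strand <- as.character(GenomicRanges::strand(tx))[i]
        if (!(scaf %in% names(seqs))) {
            flags$out_of_bounds[i] <- TRUE
            txs[[i]] <- Biostrings::DNAString("")
            cdss[[i]] <- Biostrings::DNAString("")
            next
        }
        ex <- models@exons[[tid]]
        cd <- models@cds[[tid]]
        if (any(IRanges::end(ex) > slen[scaf]) ||
            (length(cd) && any(IRanges::end(cd) > slen[scaf])) ||
            any(IRanges::start(ex) < 1L)) {
            flags$out_of_bounds[i] <- TRUE
            txs[[i]] <- Biostrings::DNAString("")
            cdss[[i]] <- Biostrings::DNAString("")
            next
        }
        scafSeq <- seqs[[scaf]]
        txSeq <- .spliceParts(scafSeq, GenomicRanges::ranges(ex), strand)
        txs[[i]] <- txSeq
        if (length(cd) == 0L) {
            cdss[[i]] <- Biostrings::DNAString("")
            next
        }
        cdSeq <- .spliceParts(scafSeq, GenomicRanges::ranges(cd), strand)
        cdss[[i]] <- cdSeq

        ## CDS footprint in spliced transcript coordinates
        exs <- BiocGenerics::sort(GenomicRanges::ranges(ex))
        cdr <- range(GenomicRanges::ranges(cd))
        offs <- cumsum(c(0L, IRanges::width(exs)))
        hit <- which(IRanges::start(exs) <= IRanges::start(cdr) &
                     IRanges::end(exs) >= IRanges::start(cdr))
        if (length(hit)) {
            plus_start <- offs[hit[1]] +
                (IRanges::start(cdr) - IRanges::start(exs)[hit[1]]) + 1L
            w <- sum(IRanges::width(cd))
            tx_len <- sum(IRanges::width(exs))
            if (strand == "+") {
                ctx <- IRanges::IRanges(plus_start, width = w)
            } else {
                ## genomic CDS end maps to transcript start on minus strand
                hit2 <- which(IRanges::start(exs) <= IRanges::end(cdr) &
                              IRanges::end(exs) >= IRanges::end(cdr))
                pe <- offs[hit2[1]] +
                    (IRanges::end(cdr) - IRanges::start(exs)[hit2[1]]) + 1L
                ctx <- IRanges::IRanges(tx_len - pe + 1L, width = w)
            }
            cds_in_tx <- c(cds_in_tx, ctx)
            cds_tx_names <- c(cds_tx_names, tid)
        }

        if (tid %in% io_invalid || length(cdSeq) %% 3L != 0L) {
            flags$not_mult3[i] <- length(cdSeq) %% 3L != 0L
            next
        }
        aa <- suppressWarnings(as.character(
            Biostrings::translate(cdSeq, if.fuzzy.codon = "X")))
        has_term <- nchar(aa) > 0L &&
            substring(aa, nchar(aa), nchar(aa)) == "*"
        core <- if (has_term) substring(aa, 1L, nchar(aa) - 1L) else aa
        flags$missing_start[i] <- substring(aa, 1L, 1L) != "M"
        flags$internal_stop[i] <- grepl("*", core, fixed = TRUE)
        if (!flags$missing_start[i] && !flags$internal_stop[i] &&
            nchar(core) > 0L) {
            flags$valid[i] <- TRUE
            prots[[tid]] <- core
        }
    }
    names(cds_in_tx) <- cds_tx_names
    txSet <- Biostrings::DNAStringSet(txs); names(txSet) <- flags$tx_id
    cdsSet <- Biostrings::DNAStringSet(cdss); names(cdsSet) <- flags$tx_id
    protSet <- Biostrings::AAStringSet(unlist(prots))
    methods::new("DerivedSequences", speciesId = models@speciesId,
                 transcripts = txSet, cdsSeqs = cdsSet, proteins = protSet,
                 cdsInTx = cds_in_tx, flags = flags)
}

#' Representative protein per gene
#'
#' Picks, for each gene, the protein of its longest valid CDS.  Used for the
#' query side of homology search, keeping exactly one query sequence per
#' gene; all transcripts' proteins remain available target-side.
#'
#' @param derived a \linkS4class{DerivedSequences}.
#' @return named \link[Biostrings]{AAStringSet}; names are gene ids, with a
#'   \code{tx_id} metadata column recording the chosen transcript.
#' @export
representativeProteins <- function(derived) {
    fl <- derived@flags
    ok <- fl[fl$valid, , drop = FALSE]
    if (nrow(ok) == 0L) {
        out <- Biostrings::AAStringSet()
        return(out)
    }
    cl <- Biostrings::width(derived@cdsSeqs[ok$tx_id])
    pick <- vapply(split(seq_len(nrow(ok)), ok$gene_id), function(ix) {
        ix[which.max(cl[ix])]
    }, integer(1))
    sel <- ok[pick, , drop = FALSE]
    out <- derived@proteins[sel$tx_id]
    names(out) <- sel$gene_id
    S4Vectors::mcols(out)$tx_id <- sel$tx_id
    out
}

## Scan the codon string of one frame for ORFs.  Returns a data.frame of
## codon-index start/end (1-based, inclusive, in codon units).
.frameOrfs <- function(codons, min_codons, require_atg) {
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    stops <- which(is_stop)
    out_start <- integer(); out_end <- integer()
    prev_stop <- 0L
    for (s in stops) {
        if (s - 1L >= prev_stop + 1L) {
            if (require_atg) {
                cand <- which(is_atg[(prev_stop + 1L):(s - 1L)])
                if (length(cand)) {
                    st <- prev_stop + cand[1]   # longest per stop
                    if (s - st >= min_codons) {
                        out_start <- c(out_start, st)
                        out_end <- c(out_end, s - 1L)
                    }
                }
            } else {
                st <- prev_stop + 1L
                if (s - st >= min_codons) {
                    out_start <- c(out_start, st)
                    out_end <- c(out_end, s - 1L)
                }
            }
        }
        prev_stop <- s
    }
    data.frame(cstart = out_start, cend = out_end)
}

#' Find open reading frames
#'
#' Scans all three frames (six when \code{bothStrands}) for maximal
#' ATG-initiated, stop-terminated ORFs of at least \code{minCodons} amino
#' acids (the stop codon is not counted and its residue is excluded from the
#' translation).  Nested ATGs sharing a stop do not spawn extra ORFs: the
#' longest ORF per stop is reported.  ORFs without a terminating stop codon
#' inside the sequence are discarded.  Codons containing ambiguity characters
#' are never starts or stops.  With \code{requireAtg = FALSE} the scan
#' switches to stop-to-stop segments.
#'
#' Coordinates are 1-based closed positions on the forward strand of
#' \code{seq}; for minus-strand ORFs they delimit the reverse-complement
#' footprint on the forward strand.  The reported interval covers the codons
#' from start through the last codon before the stop (the stop codon is not
#' included).
#'
#' @param seq a \link[Biostrings]{DNAString}, or a single character string.
#' @param minCodons minimum ORF length in codons (amino acids), >= 1.
#' @param bothStrands scan the reverse complement too?
#' @param requireAtg require an ATG start (default) or report stop-to-stop
#'   frames.
#' @return data.frame with columns start, end, strand, frame, aa.
#' @export
findOrfs <- function(seq, minCodons = 30L, bothStrands = TRUE,
                     requireAtg = TRUE) {
    stopifnot(minCodons >= 1L)
    s <- toupper(as.character(seq))
    n <- nchar(s)
    res <- list()
    code <- Biostrings::GENETIC_CODE
    scan_strand <- function(str, strand) {
        for (off in 0:2) {
            ncod <- (nchar(str) - off) %/% 3L
            if (ncod < 1L) next
            idx <- off + 1L + 3L * (seq_len(ncod) - 1L)
            codons <- substring(str, idx, idx + 2L)
            hits <- .frameOrfs(codons, minCodons, requireAtg)
            if (nrow(hits) == 0L) next
            fs <- off + 1L + 3L * (hits$cstart - 1L)  # nt start, this strand
            fe <- off + 3L * hits$cend                # nt end
            if (strand == "+") {
                st <- fs; en <- fe
            } else {
                st <- n - fe + 1L; en <- n - fs + 1L
            }
            tr <- unname(code[codons])
            tr[is.na(tr)] <- "X"      # ambiguity codons translate to X
            aa <- vapply(seq_len(nrow(hits)), function(k)
                paste(tr[hits$cstart[k]:hits$cend[k]], collapse = ""),
                character(1))
            res[[length(res) + 1L]] <<- data.frame(
                start = st, end = en, strand = strand, frame = off + 1L,
                aa = aa, stringsAsFactors = FALSE)
        }
    }
    scan_strand(s, "+")
    if (bothStrands) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        scan_strand(rc, "-")
    }
    if (length(res) == 0L)
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), frame = integer(),
                          aa = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' ORFs on a spliced transcript other than the annotated CDS
#'
#' Finds forward-strand ORFs on the spliced transcript of one transcript
#' model and drops any ORF whose nucleotide footprint on the transcript is
#' identical to the annotated CDS (so that only secondary ORFs - upstream
#' ORFs, ORFs in UTRs, nested frames - remain).
#'
#' @param derived a \linkS4class{DerivedSequences}.
#' @param txId transcript id.
#' @param minCodons minimum ORF length in codons.
#' @return data.frame as \code{\link{findOrfs}} (forward strand only).
#' @export
nonCdsTranscriptOrfs <- function(derived, txId, minCodons = 30L) {
    if (!(txId %in% names(derived@transcripts)))
        stop("unknown transcript id: ", txId)
    txSeq <- derived@transcripts[[txId]]
    orfs <- findOrfs(txSeq, minCodons = minCodons, bothStrands = FALSE)
    if (txId %in% names(derived@cdsInTx) && nrow(orfs)) {
        cr <- derived@cdsInTx[names(derived@cdsInTx) == txId]
        ## the annotated CDS footprint includes its stop codon; the ORF
        ## interval stops short of the stop, so compare start + stop-clipped
        ## end
        same <- orfs$start == IRanges::start(cr)[1] &
                orfs$end == (IRanges::end(cr)[1] - 3L)
        orfs <- orfs[!same, , drop = FALSE]
    }
    rownames(orfs) <- NULL
    orfs
}

#' Genomic ORFs for a whole assembly
#'
#' Convenience wrapper running \code{\link{findOrfs}} over every scaffold;
#' genomic ORFs are single-exon by construction.
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param minCodons minimum ORF length in codons.
#' @return data.frame with a leading \code{seqid} column.
#' @export
genomicOrfs <- function(assembly, minCodons = 30L) {
    res <- lapply(names(assembly@sequences), function(nm) {
        o <- findOrfs(assembly@sequences[[nm]], minCodons = minCodons,
                      bothStrands = TRUE)
        if (nrow(o)) cbind(seqid = nm, o, stringsAsFactors = FALSE)
        else NULL
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
        return(data.frame(seqid = character(), start = integer(),
                          end = integer(), strand = character(),
                          frame = integer(), aa = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Export derived sequences to FASTA
#' @param derived a \linkS4class{DerivedSequences}.
#' @param what one of "proteins", "transcripts", "cds".
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportDerivedFasta <- function(derived,
                               what = c("proteins", "transcripts", "cds"),
                               path) {
    what <- match.arg(what)
    x <- switch(what, proteins = derived@proteins,
                transcripts = derived@transcripts,
                cds = derived@cdsSeqs)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}
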