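## Syntenic search-interval inference.
##
## The contract is a contiguous-anchor interpolation over the pairwise block
## map.  For each query gene, one of four situations applies:
##   (a) blocks overlapping the gene contribute their target intervals,
##       with query-side overhangs extended by linear interpolation;
##   (b) a gene strictly between two anchors whose target intervals lie on
##       one scaffold in consistent orientation maps to the target gap
##       between them; inconsistent anchors instead each project a flanking
##       interval and raise the scramble score;
##   (c) a gene outside all blocks on its scaffold projects from the nearest
##       block's target edge to the scaffold end in the inferred direction,
##       with the unanchored side's bounded flag FALSE;
##   (d) a gene whose scaffold has no blocks at all gets an explicit
##       "unmapped" record.
## Minus-strand anchors swap left and right on the target side throughout.

## Linear interpolation of one query position through a block (1-based).
.mapThroughBlock <- function(q, qs, qe, ts, te, strand) {
    span_q <- max(1L, qe - qs)
    off <- round((q - qs) * (te - ts) / span_q)
    if (strand == "+") ts + off else te - off
}

## Concordance of one ordered (by query) anchor pair.
.pairConcordant <- function(b1, b2) {
    if (b1$tseqid != b2$tseqid) return(FALSE)
    if (b1$strand != b2$strand) return(FALSE)
    if (b1$strand == "+") b2$tstart >= b1$tstart else b2$tend <= b1$tend
}

## Fraction of discordant adjacent anchor pairs within a window around the
## gene (up to `window` anchors on each side).
.scrambleScore <- function(blk, geneStart, window) {
    if (nrow(blk) < 2L) return(0)
    pos <- findInterval(geneStart, blk$qstart)
    lo <- max(1L, pos - window + 1L)
    hi <- min(nrow(blk), pos + window)
    sub <- blk[lo:hi, , drop = FALSE]
    if (nrow(sub) < 2L) return(0)
    disc <- vapply(seq_len(nrow(sub) - 1L), function(i)
        !.pairConcordant(sub[i, ], sub[i + 1L, ]), logical(1))
    mean(disc)
}

.siRow <- function(gene_id, tseqid = NA_character_, tstart = NA_integer_,
                   tend = NA_integer_, left_bounded = FALSE,
                   right_bounded = FALSE, at_scaffold_edge = FALSE,
                   scramble_score = 0, rule = "unmapped",
                   source_blocks = "", unmapped = FALSE) {
    data.frame(query_gene_id = gene_id, tseqid = tseqid,
               tstart = as.integer(tstart), tend = as.integer(tend),
               left_bounded = left_bounded, right_bounded = right_bounded,
               at_scaffold_edge = at_scaffold_edge,
               scramble_score = scramble_score, rule = rule,
               source_blocks = source_blocks, unmapped = unmapped,
               stringsAsFactors = FALSE)
}

.clipRow <- function(row, slen) {
    ## clip to scaffold; an interval may be empty (tend == tstart - 1)
    row$tstart <- max(1L, row$tstart)
    row$tend <- min(slen, row$tend)
    if (row$tend < row$tstart) row$tend <- row$tstart - 1L
    row$at_scaffold_edge <- row$tstart <= 1L || row$tend >= slen ||
        row$tstart > slen
    row
}

#' Infer syntenic search intervals for query genes
#'
#' Projects each query gene through the focal-to-target synteny map onto the
#' target genome, yielding one or more search intervals per gene (or an
#' explicit unmapped record when the gene's scaffold has no blocks to that
#' target).  See the package vignette for the full projection contract.
#'
#' Coordinates are 1-based closed; an empty interval (a clean deletion
#' between two abutting anchors) is encoded as \code{tend == tstart - 1}.
#'
#' @param models focal-species \linkS4class{GeneModels} (the \code{genes}
#'   ranges are projected), or a \link[GenomicRanges]{GRanges} with a
#'   \code{gene_id} metadata column.
#' @param synmap a \linkS4class{SyntenyMap} from the focal species to one
#'   target.
#' @param targetAssembly the target \linkS4class{GenomeAssembly} (for
#'   scaffold lengths and edge flags).
#' @param cfg a run configuration (\code{\link{defaultRunConfig}}).
#' @param queryIds optional character vector restricting the genes projected.
#' @return data.frame with one row per search interval, columns:
#'   query_gene_id, tseqid, tstart, tend, left_bounded, right_bounded,
#'   at_scaffold_edge, scramble_score, rule, source_blocks, unmapped.
#' @export
inferSearchIntervals <- function(models, synmap, targetAssembly,
                                 cfg = defaultRunConfig(),
                                 queryIds = NULL) {
    genes <- if (methods::is(models, "GeneModels")) models@genes else models
    if (!is.null(queryIds))
        genes <- genes[genes$gene_id %in% queryIds]
    blk_all <- blocks(synmap)
    if (nrow(blk_all) && any(blk_all$tend < blk_all$tstart))
        stop("contradictory synteny block: tend < tstart")
    slen <- scaffoldLengths(targetAssembly)
    out <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
        gid <- genes$gene_id[gi]
        gscaf <- as.character(GenomicRanges::seqnames(genes))[gi]
        gs <- IRanges::start(genes)[gi]
        ge <- IRanges::end(genes)[gi]
        blk <- blk_all[blk_all$qseqid == gscaf, , drop = FALSE]
        if (nrow(blk) == 0L) {
            out[[gi]] <- .siRow(gid, unmapped = TRUE)
            next
        }
        scr <- .scrambleScore(blk, gs, cfg$scramble_window)
        rows <- list()
        add <- function(r, sl) rows[[length(rows) + 1L]] <<- .clipRow(r, sl)

        ## (a) blocks overlapping the gene, overhangs extended
        ov <- which(blk$qstart <= ge & blk$qend >= gs)
        for (k in ov) {
            b <- blk[k, ]
            sl <- slen[[b$tseqid]]
            g1 <- max(gs, b$qstart); g2 <- min(ge, b$qend)
            t1 <- .mapThroughBlock(g1, b$qstart, b$qend, b$tstart,
                                   b$tend, b$strand)
            t2 <- .mapThroughBlock(g2, b$qstart, b$qend, b$tstart,
                                   b$tend, b$strand)
            lo <- min(t1, t2); hi <- max(t1, t2)
            over_l <- max(0L, b$qstart - gs)  # query overhang left
            over_r <- max(0L, ge - b$qend)    # query overhang right
            if (b$strand == "+") {
                lo <- lo - over_l; hi <- hi + over_r
            } else {
                lo <- lo - over_r; hi <- hi + over_l
            }
            add(.siRow(gid, b$tseqid, lo, hi, TRUE, TRUE,
                       scramble_score = scr, rule = "overlap",
                       source_blocks = as.character(k)), sl)
        }

        ## (b) inter-anchor gaps the gene reaches into
        if (nrow(blk) >= 2L) {
            for (k in seq_len(nrow(blk) - 1L)) {
                L <- blk[k, ]; R <- blk[k + 1L, ]
                gap_lo <- L$qend + 1L; gap_hi <- R$qstart - 1L
                if (gap_hi < gap_lo) next         # abutting blocks, no gap
                if (ge < gap_lo || gs > gap_hi) next
                if (.pairConcordant(L, R)) {
                    sl <- slen[[L$tseqid]]
                    r <- if (L$strand == "+")
                        .siRow(gid, L$tseqid, L$tend + 1L, R$tstart - 1L,
                               TRUE, TRUE, scramble_score = scr,
                               rule = "gap",
                               source_blocks = paste(k, k + 1L, sep = ","))
                    else
                        .siRow(gid, L$tseqid, R$tend + 1L, L$tstart - 1L,
                               TRUE, TRUE, scramble_score = scr,
                               rule = "gap",
                               source_blocks = paste(k, k + 1L, sep = ","))
                    add(r, sl)
                } else {
                    ## discordant anchors: project the gene through each
                    scr2 <- max(scr, 0.5 + 1e-9)
                    wL <- ge - L$qend            # span from L to gene far end
                    wR <- R$qstart - gs
                    rL <- if (L$strand == "+")
                        .siRow(gid, L$tseqid, L$tend + 1L, L$tend + wL,
                               TRUE, FALSE, scramble_score = scr2,
                               rule = "flank", source_blocks = as.character(k))
                    else
                        .siRow(gid, L$tseqid, L$tstart - wL, L$tstart - 1L,
                               TRUE, FALSE, scramble_score = scr2,
                               rule = "flank", source_blocks = as.character(k))
                    rR <- if (R$strand == "+")
                        .siRow(gid, R$tseqid, R$tstart - wR, R$tstart - 1L,
                               FALSE, TRUE, scramble_score = scr2,
                               rule = "flank",
                               source_blocks = as.character(k + 1L))
                    else
                        .siRow(gid, R$tseqid, R$tend + 1L, R$tend + wR,
                               FALSE, TRUE, scramble_score = scr2,
                               rule = "flank",
                               source_blocks = as.character(k + 1L))
                    add(rL, slen[[L$tseqid]])
                    add(rR, slen[[R$tseqid]])
                }
            }
        }

        ## (c) gene extends beyond the outermost anchors: open-ended tails
        if (gs < min(blk$qstart)) {
            k <- 1L; b <- blk[k, ]
            sl <- slen[[b$tseqid]]
            r <- if (b$strand == "+")
                .siRow(gid, b$tseqid, 1L, b$tstart - 1L, FALSE, TRUE,
                       scramble_score = scr, rule = "tail",
                       source_blocks = as.character(k))
            else
                .siRow(gid, b$tseqid, b$tend + 1L, sl, FALSE, TRUE,
                       scramble_score = scr, rule = "tail",
                       source_blocks = as.character(k))
            add(r, sl)
        }
        if (ge > max(blk$qend)) {
            k <- which.max(blk$qend); b <- blk[k, ]
            sl <- slen[[b$tseqid]]
            r <- if (b$strand == "+")
                .siRow(gid, b$tseqid, b$tend + 1L, sl, TRUE, FALSE,
                       scramble_score = scr, rule = "tail",
                       source_blocks = as.character(k))
            else
                .siRow(gid, b$tseqid, 1L, b$tstart - 1L, TRUE, FALSE,
                       scramble_score = scr, rule = "tail",
                       source_blocks = as.character(k))
            add(r, sl)
        }
        out[[gi]] <- do.call(rbind, rows)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Diagnose the search intervals of one query gene
#'
#' Summarizes one gene's intervals on one target into the quantities the
#' decision tree consumes: total interval length, the interval/query length
#' ratio (indel evidence when small), whether an assembly gap (N run of at
#' least \code{n_run_min} nt) intersects an interval, whether the total
#' length exceeds the searchable maximum, whether any interval touches a
#' scaffold edge, and whether the local anchor context is scrambled.
#'
#' @param si search-interval rows for one query gene on one target (from
#'   \code{\link{inferSearchIntervals}}).
#' @param geneLength query gene length in nt.
#' @param targetAssembly the target \linkS4class{GenomeAssembly}.
#' @param cfg run configuration.
#' @return one-row data.frame: query_gene_id, n_intervals, total_length,
#'   length_ratio, contains_n_run, oversize, at_edge, scrambled, unmapped.
#' @export
intervalDiagnostics <- function(si, geneLength, targetAssembly,
                                cfg = defaultRunConfig()) {
    stopifnot(length(unique(si$query_gene_id)) == 1L)
    unmapped <- all(si$unmapped)
    mapped <- si[!si$unmapped, , drop = FALSE]
    widths <- pmax(0L, mapped$tend - mapped$tstart + 1L)
    total <- sum(widths)
    n_run <- FALSE
    if (nrow(mapped)) {
        runs <- nRuns(targetAssembly)
        for (i in seq_len(nrow(mapped))) {
            if (widths[i] == 0L) next
            r <- runs[[mapped$tseqid[i]]]
            if (is.null(r) || length(r) == 0L) next
            r <- r[IRanges::width(r) >= cfg$n_run_min]
            if (length(r) == 0L) next
            q <- IRanges::IRanges(mapped$tstart[i], mapped$tend[i])
            if (any(IRanges::overlapsAny(r, q))) { n_run <- TRUE; break }
        }
    }
    data.frame(
        query_gene_id = si$query_gene_id[1],
        n_intervals = nrow(mapped),
        total_length = total,
        length_ratio = if (unmapped) NA_real_ else total / geneLength,
        contains_n_run = n_run,
        oversize = !unmapped && total > cfg$max_interval_nt,
        at_edge = !unmapped && any(mapped$at_scaffold_edge),
        scrambled = !unmapped &&
            any(mapped$scramble_score > cfg$scramble_threshold),
        unmapped = unmapped,
        stringsAsFactors = FALSE)
}
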