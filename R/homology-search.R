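## Alignment-based evidence layer.
##
## Similarity is scored with affine-gap Smith-Waterman local alignment.
## Significance of a raw score is estimated against a Gumbel (type-I
## extreme-value) null fitted by the method of moments to scores of aligned
## shuffled sequences of matched lengths; adjusted p-values (BH) below alpha
## mark a hit significant.  Evidence *flags* additionally require identity
## coverage - the fraction of query positions matched identically in the
## local alignment - of at least min_query_coverage: marginal local
## alignments of unrelated sequences reach p < alpha at roughly the rate
## alpha, but cannot match a substantial fraction of the query identically
## (accumulating that many identities in a random alignment drives the
## score negative first), so the identity-coverage requirement stabilizes
## per-gene classifications without sacrificing sensitivity: any homolog
## with >= 25% identity over the query passes.

.EULER_GAMMA <- 0.5772156649015329

## Full-alphabet nucleotide scoring matrix: identity on A/C/G/T scores
## `match`, every other letter pair (including any ambiguity code, N in
## particular) scores `mismatch`.  Ambiguous bases therefore never support
## an alignment.
.ntScoringMatrix <- function(match, mismatch) {
    letters <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")
    m <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
    for (b in c("A", "C", "G", "T")) m[b, b] <- match
    m
}

.aaMatrix <- local({
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

.guessAlphabet <- function(x) {
    s <- toupper(as.character(x))
    if (grepl("^[ACGTUMRWSYKVHDBN]*$", s)) "nt" else "aa"
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gap penalties (a gap of length L
#' costs \code{gapOpening + L * gapExtension}).  The empty alignment is
#' admissible, so the score is never negative.  Defaults: BLOSUM62 with gap
#' open 10 / extend 1 for amino acids; match +2 / mismatch -3 with gap open
#' 5 / extend 2 for nucleotides.  Aligning an amino-acid sequence against a
#' nucleotide sequence is a hard error.
#'
#' @param a,b sequences (character, \link[Biostrings]{DNAString} or
#'   \link[Biostrings]{AAString}).
#' @param type "aa" or "nt"; guessed from the sequence content by default.
#' @param cfg run configuration supplying the scoring defaults.
#' @return list with elements \code{score}, \code{pattern_range} and
#'   \code{subject_range} (\link[IRanges]{IRanges} of the aligned spans;
#'   empty when the best local alignment is empty), \code{n_match} (number
#'   of identically matched positions) and \code{coverage} (identity
#'   coverage: matched positions as a fraction of the length of \code{a}).
#' @export
smithWaterman <- function(a, b, type = NULL, cfg = defaultRunConfig()) {
    ta <- .guessAlphabet(a); tb <- .guessAlphabet(b)
    if (is.null(type)) {
        if (ta != tb)
            stop("mixed alphabets: one sequence is nucleotide, ",
                 "the other amino acid")
        type <- ta
    } else {
        type <- match.arg(type, c("aa", "nt"))
        if (type == "nt" && (ta == "aa" || tb == "aa"))
            stop("mixed alphabets: amino-acid sequence in nucleotide ",
                 "alignment")
    }
    if (nchar(as.character(a)) == 0L || nchar(as.character(b)) == 0L)
        return(list(score = 0, pattern_range = IRanges::IRanges(),
                    subject_range = IRanges::IRanges(), n_match = 0L,
                    coverage = 0))
    if (type == "aa") {
        pa <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(toupper(as.character(a))),
            Biostrings::AAString(toupper(as.character(b))),
            type = "local", substitutionMatrix = .aaMatrix(),
            gapOpening = cfg$aa_gap_opening,
            gapExtension = cfg$aa_gap_extension)
    } else {
        pa <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(toupper(as.character(a))),
            Biostrings::DNAString(toupper(as.character(b))),
            type = "local",
            substitutionMatrix = .ntScoringMatrix(cfg$nt_match,
                                                  cfg$nt_mismatch),
            gapOpening = cfg$nt_gap_opening,
            gapExtension = cfg$nt_gap_extension)
    }
    sc <- Biostrings::score(pa)
    if (sc <= 0)
        return(list(score = 0, pattern_range = IRanges::IRanges(),
                    subject_range = IRanges::IRanges(), n_match = 0L,
                    coverage = 0))
    pr <- IRanges::IRanges(BiocGenerics::start(Biostrings::pattern(pa)),
                           BiocGenerics::end(Biostrings::pattern(pa)))
    sr <- IRanges::IRanges(BiocGenerics::start(Biostrings::subject(pa)),
                           BiocGenerics::end(Biostrings::subject(pa)))
    nm <- Biostrings::nmatch(pa)
    list(score = sc, pattern_range = pr, subject_range = sr, n_match = nm,
         coverage = nm / nchar(as.character(a)))
}

#' Fit a shuffled-sequence score null model
#'
#' Aligns shuffles of the two sequences \code{n} times and fits a Gumbel
#' distribution to the scores by the method of moments.  A degenerate null
#' (zero score variance, e.g. when one sequence is all Ns) is recorded and
#' later forces p = 1.
#'
#' @param a,b the sequences whose score is to be calibrated.
#' @param type "aa" or "nt".
#' @param n number of shuffled alignments (>= 100 recommended).
#' @param cfg run configuration.
#' @return list with \code{mu}, \code{beta}, \code{degenerate}, \code{n},
#'   \code{max_score}.
#' @export
fitScoreNull <- function(a, b, type = NULL, n = 100L,
                         cfg = defaultRunConfig()) {
    sa <- toupper(as.character(a)); sb <- toupper(as.character(b))
    if (is.null(type)) type <- .guessAlphabet(sa)
    ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
    ## batched for speed: each shuffled subject is paired with a fresh set
    ## of shuffled patterns in one vectorized scoreOnly alignment call
    batch <- 10L
    n_batches <- ceiling(n / batch)
    as_set <- if (type == "aa") Biostrings::AAStringSet
              else Biostrings::DNAStringSet
    as_one <- if (type == "aa") Biostrings::AAString
              else Biostrings::DNAString
    mat <- if (type == "aa") .aaMatrix()
           else .ntScoringMatrix(cfg$nt_match, cfg$nt_mismatch)
    go <- if (type == "aa") cfg$aa_gap_opening else cfg$nt_gap_opening
    ge <- if (type == "aa") cfg$aa_gap_extension else cfg$nt_gap_extension
    scores <- unlist(lapply(seq_len(n_batches), function(j) {
        k <- min(batch, n - (j - 1L) * batch)
        pats <- as_set(vapply(seq_len(k), function(i)
            paste(sample(ca), collapse = ""), character(1)))
        subj <- as_one(paste(sample(cb), collapse = ""))
        pmax(0, Biostrings::pairwiseAlignment(
            pats, subj, type = "local", substitutionMatrix = mat,
            gapOpening = go, gapExtension = ge, scoreOnly = TRUE))
    }))
    s <- stats::sd(scores)
    if (!is.finite(s) || s == 0) {
        return(list(mu = mean(scores), beta = NA_real_, degenerate = TRUE,
                    n = n, max_score = max(scores)))
    }
    beta <- s * sqrt(6) / pi
    mu <- mean(scores) - .EULER_GAMMA * beta
    list(mu = mu, beta = beta, degenerate = FALSE, n = n,
         max_score = max(scores))
}

#' Score significance under a fitted Gumbel null
#'
#' Returns p = P(null score >= raw score), the Gumbel survival function at
#' the raw score.  Degenerate nulls give p = 1 with a warning.
#'
#' @param rawScore observed alignment score.
#' @param null a null model from \code{\link{fitScoreNull}}.
#' @return p-value in (0, 1].
#' @export
scoreSignificance <- function(rawScore, null) {
    if (isTRUE(null$degenerate)) {
        warning("degenerate score null (zero variance); p set to 1")
        return(1)
    }
    z <- (rawScore - null$mu) / null$beta
    p <- 1 - exp(-exp(-z))
    max(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg adjustment within evidence groups
#'
#' Adjusts hit p-values within each (query gene x target species x evidence
#' kind) group, preserving row order.
#'
#' @param hits data.frame with at least \code{p_value} and the grouping
#'   columns.
#' @param groupCols character vector of grouping column names.
#' @param method adjustment method passed to \code{\link[stats]{p.adjust}}.
#' @param alpha significance threshold applied to the adjusted values.
#' @return \code{hits} with columns \code{p_adjusted} and \code{significant}.
#' @export
adjustPvalues <- function(hits,
                          groupCols = c("query_gene_id", "target_species",
                                        "kind"),
                          method = "BH", alpha = 0.05) {
    if (nrow(hits) == 0L) {
        hits$p_adjusted <- numeric(0)
        hits$significant <- logical(0)
        return(hits)
    }
    key <- interaction(hits[groupCols], drop = TRUE)
    hits$p_adjusted <- stats::ave(hits$p_value, key,
                                  FUN = function(p) stats::p.adjust(p, method))
    hits$significant <- hits$p_adjusted < alpha
    hits
}

## ---- null-model cache -------------------------------------------------

## Nulls are cached per (alphabet, log2 length bin of each sequence) within
## one pipeline run; re-fitting per hit would dominate the runtime without
## changing any call.
.nullKey <- function(a, b, type) {
    paste(type, round(log2(max(1, nchar(as.character(a))))),
          round(log2(max(1, nchar(as.character(b))))), sep = ":")
}

.getNull <- function(cache, a, b, type, cfg) {
    key <- .nullKey(a, b, type)
    if (!is.null(cache) && !is.null(cache[[key]])) {
        ## a cached stratum null is reused unless degenerate while the new
        ## pair is alignable (an all-N interval must not poison the stratum)
        nl <- cache[[key]]
        if (!nl$degenerate) return(nl)
    }
    nl <- fitScoreNull(a, b, type = type, n = cfg$null_shuffles, cfg = cfg)
    if (!is.null(cache)) cache[[key]] <- nl
    nl
}

## ---- evidence bundle --------------------------------------------------

.emptyHits <- function() {
    data.frame(query_gene_id = character(), target_species = character(),
               kind = character(), feature_id = character(),
               raw_score = numeric(), p_value = numeric(),
               coverage = numeric(),
               t_seqid = character(), t_start = integer(),
               t_end = integer(), stringsAsFactors = FALSE)
}

## One alignment test -> one hit row (or NULL if score 0).
.hitRow <- function(cache, query, subject, type, cfg, gene_id, target_sp,
                    kind, feature_id, t_seqid = NA, t_start = NA,
                    t_end = NA) {
    aln <- smithWaterman(query, subject, type = type, cfg = cfg)
    if (aln$score <= 0) return(NULL)
    null <- .getNull(cache, query, subject, type, cfg)
    p <- suppressWarnings(scoreSignificance(aln$score, null))
    fp_start <- t_start; fp_end <- t_end
    if (!is.na(t_start) && length(aln$subject_range)) {
        fp_start <- t_start + IRanges::start(aln$subject_range)[1] - 1L
        fp_end <- t_start + IRanges::end(aln$subject_range)[1] - 1L
    }
    data.frame(query_gene_id = gene_id, target_species = target_sp,
               kind = kind, feature_id = feature_id,
               raw_score = aln$score, p_value = p,
               coverage = aln$coverage,
               t_seqid = as.character(t_seqid),
               t_start = as.integer(fp_start), t_end = as.integer(fp_end),
               stringsAsFactors = FALSE)
}

## Classify a nucleotide hit footprint against the target annotation.
## Per-base priority CDS > exon > intron > intergenic, then majority vote
## with ties toward the more genic category.
.ntHitCategory <- function(seqid, start, end, targetModels) {
    fp <- GenomicRanges::GRanges(seqid, IRanges::IRanges(start, end))
    w <- IRanges::width(fp)
    cds_all <- unlist(targetModels@cds)
    exon_all <- unlist(targetModels@exons)
    gene_all <- targetModels@genes
    ov_w <- function(x) {
        if (length(x) == 0L) return(0L)
        x <- GenomicRanges::reduce(x, ignore.strand = TRUE)
        hits <- GenomicRanges::pintersect(
            IRanges::findOverlapPairs(fp, x, ignore.strand = TRUE))
        sum(IRanges::width(hits))
    }
    w_cds <- ov_w(cds_all)
    w_exon <- max(0L, ov_w(exon_all) - w_cds)
    w_gene <- ov_w(gene_all)
    w_intron <- max(0L, w_gene - w_cds - w_exon)
    w_inter <- max(0L, w - w_gene)
    cats <- c(cds = w_cds, exo = w_exon, rna = w_intron, dna = w_inter)
    names(cats)[which.max(cats)]  # which.max takes the first (most genic) tie
}

#' Collect alignment evidence for one query gene on one target
#'
#' Runs the full evidence battery inside the gene's search intervals:
#' \itemize{
#'   \item query protein vs annotated target proteins whose gene overlaps an
#'     interval (\code{aa_gen} evidence);
#'   \item query protein vs non-CDS ORFs on those annotated mRNAs
#'     (\code{aa_trn});
#'   \item query protein vs ORFs of the interval DNA (both strands) that do
#'     not overlap any annotated mRNA (\code{aa_orf});
#'   \item query gene nucleotide sequence vs interval DNA on both strands,
#'     each significant hit located against the annotation as CDS / exon /
#'     intron / intergenic (\code{nt_cds}, \code{nt_exo}, \code{nt_rna},
#'     \code{nt_dna}).
#' }
#' Oversize intervals are skipped (their flag feeds the technical Unknown
#' class).  A flag is raised by a hit that is significant after BH
#' adjustment within its (query x target x kind) group and spans at least
#' \code{min_query_coverage} of the query.
#'
#' @param geneId query gene id.
#' @param queryProtein the gene's representative protein (or NULL if none).
#' @param queryGeneSeq the gene's full unspliced nucleotide sequence.
#' @param si search-interval rows for this gene on this target.
#' @param targetAssembly target \linkS4class{GenomeAssembly}.
#' @param targetModels target \linkS4class{GeneModels}.
#' @param targetDerived target \linkS4class{DerivedSequences}.
#' @param cfg run configuration.
#' @param nullCache an environment used to cache fitted score nulls across
#'   calls (one per pipeline run).
#' @return list with logical flags \code{aa_gen}, \code{aa_trn},
#'   \code{aa_orf}, \code{nt_cds}, \code{nt_exo}, \code{nt_rna},
#'   \code{nt_dna}, plus \code{hits} (all scored hits with adjusted
#'   p-values) and \code{best_hit} (feature id of the strongest significant
#'   hit or NA).
#' @export
searchIntervalEvidence <- function(geneId, queryProtein, queryGeneSeq, si,
                                   targetAssembly, targetModels,
                                   targetDerived,
                                   cfg = defaultRunConfig(),
                                   nullCache = new.env(parent = emptyenv())) {
    target_sp <- speciesId(targetAssembly)
    flags <- list(aa_gen = FALSE, aa_trn = FALSE, aa_orf = FALSE,
                  nt_cds = FALSE, nt_exo = FALSE, nt_rna = FALSE,
                  nt_dna = FALSE)
    mapped <- si[!si$unmapped, , drop = FALSE]
    widths <- pmax(0L, mapped$tend - mapped$tstart + 1L)
    searchable <- sum(widths) <= cfg$max_interval_nt
    mapped <- mapped[widths > 0L, , drop = FALSE]
    hits <- list()
    if (nrow(mapped) && searchable) {
        iv <- GenomicRanges::GRanges(
            mapped$tseqid, IRanges::IRanges(mapped$tstart, mapped$tend))

        ## target genes overlapping any interval
        ov_genes <- targetModels@genes[
            IRanges::overlapsAny(targetModels@genes, iv,
                                       ignore.strand = TRUE)]
        ov_tx <- targetModels@transcripts[
            targetModels@transcripts$gene_id %in% ov_genes$gene_id]

        if (!is.null(queryProtein)) {
            ## aa vs annotated proteins of overlapping genes
            for (tid in ov_tx$tx_id) {
                if (!(tid %in% names(targetDerived@proteins))) next
                hits[[length(hits) + 1L]] <- .hitRow(
                    nullCache, queryProtein, targetDerived@proteins[[tid]],
                    "aa", cfg, geneId, target_sp, "aa_gen", tid)
            }
            ## aa vs non-CDS ORFs on overlapping annotated mRNAs
            for (tid in ov_tx$tx_id) {
                if (!(tid %in% names(targetDerived@transcripts))) next
                orfs <- nonCdsTranscriptOrfs(targetDerived, tid,
                                             minCodons = cfg$min_orf_codons)
                for (j in seq_len(nrow(orfs))) {
                    hits[[length(hits) + 1L]] <- .hitRow(
                        nullCache, queryProtein, orfs$aa[j], "aa", cfg,
                        geneId, target_sp, "aa_trn",
                        paste0(tid, ":orf", j))
                }
            }
        }

        ## per-interval DNA: genomic ORFs and nucleotide search
        for (i in seq_len(nrow(mapped))) {
            sseq <- Biostrings::subseq(
                targetAssembly@sequences[[mapped$tseqid[i]]],
                mapped$tstart[i], mapped$tend[i])
            if (!is.null(queryProtein)) {
                orfs <- findOrfs(sseq, minCodons = cfg$min_orf_codons,
                                 bothStrands = TRUE,
                                 requireAtg = cfg$orf_require_atg)
                for (j in seq_len(nrow(orfs))) {
                    o_start <- mapped$tstart[i] + orfs$start[j] - 1L
                    o_end <- mapped$tstart[i] + orfs$end[j] - 1L
                    o_gr <- GenomicRanges::GRanges(
                        mapped$tseqid[i], IRanges::IRanges(o_start, o_end))
                    if (length(targetModels@transcripts) &&
                        IRanges::overlapsAny(
                            o_gr, targetModels@transcripts,
                            ignore.strand = TRUE))
                        next  # overlaps an annotated mRNA: aa_gen/aa_trn turf
                    hits[[length(hits) + 1L]] <- .hitRow(
                        nullCache, queryProtein, orfs$aa[j], "aa", cfg,
                        geneId, target_sp, "aa_orf",
                        paste0(mapped$tseqid[i], ":", o_start, "-", o_end,
                               orfs$strand[j]),
                        mapped$tseqid[i], o_start, o_end)
                }
            }
            ## nt: query gene vs interval DNA, both strands
            for (strand in c("+", "-")) {
                subj <- if (strand == "+") sseq
                        else Biostrings::reverseComplement(sseq)
                h <- .hitRow(nullCache, queryGeneSeq, subj, "nt", cfg,
                             geneId, target_sp, "nt",
                             paste0(mapped$tseqid[i], ":", mapped$tstart[i],
                                    "-", mapped$tend[i], strand),
                             mapped$tseqid[i], mapped$tstart[i],
                             mapped$tend[i])
                if (!is.null(h) && strand == "-" &&
                    !is.na(h$t_start)) {
                    ## mirror the footprint back to the forward strand
                    w <- length(sseq)
                    a <- h$t_start - mapped$tstart[i]
                    b <- h$t_end - mapped$tstart[i]
                    h$t_start <- mapped$tstart[i] + (w - 1L - b)
                    h$t_end <- mapped$tstart[i] + (w - 1L - a)
                }
                hits[[length(hits) + 1L]] <- h
            }
        }
    }
    hits <- hits[!vapply(hits, is.null, logical(1))]
    hits <- if (length(hits)) do.call(rbind, hits) else .emptyHits()
    hits <- adjustPvalues(hits, method = cfg$p_adjust_method,
                          alpha = cfg$alpha)
    counts <- hits$significant & hits$coverage >= cfg$min_query_coverage
    for (k in c("aa_gen", "aa_trn", "aa_orf"))
        flags[[k]] <- any(counts & hits$kind == k)
    nt_sig <- which(counts & hits$kind == "nt")
    for (j in nt_sig) {
        cat_j <- .ntHitCategory(hits$t_seqid[j], hits$t_start[j],
                                hits$t_end[j], targetModels)
        flags[[paste0("nt_", cat_j)]] <- TRUE
    }
    best <- NA_character_
    if (any(counts))
        best <- hits$feature_id[counts][which.max(hits$raw_score[counts])]
    c(flags, list(hits = hits, best_hit = best,
                  best_p = if (any(counts))
                      min(hits$p_adjusted[counts]) else NA_real_))
}
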