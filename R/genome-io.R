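#' @importFrom Biostrings readBStringSet DNAStringSet width
#' @importFrom IRanges IRanges IRangesList
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom S4Vectors DataFrame mcols
NULL

IUPAC_NT <- c("A", "C", "G", "T", "U", "M", "R", "W", "S", "Y", "K",
              "V", "H", "D", "B", "N")

## Maximal runs of N/n in one sequence string, as an IRanges (1-based closed).
.nRunsOne <- function(s) {
    m <- gregexpr("[Nn]+", s)[[1]]
    if (m[1] == -1L) return(IRanges::IRanges())
    IRanges::IRanges(start = as.integer(m),
                     width = attr(m, "match.length"))
}

#' Read a genome FASTA into a GenomeAssembly
#'
#' Loads all scaffolds, checks that every character is an IUPAC nucleotide
#' code, and indexes the maximal runs of the ambiguity character N per
#' scaffold.  Duplicate scaffold ids, empty files and non-IUPAC characters
#' are hard errors; the character error names the scaffold and offset.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param speciesId species label to attach; defaults to the file base name.
#' @return a \linkS4class{GenomeAssembly}.
#' @export
readGenome <- function(path, speciesId = NULL) {
    if (!file.exists(path))
        stop("genome FASTA not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("empty FASTA file: ", path)
    ## FASTA headers may carry descriptions; the scaffold id is word one
    names(raw) <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(names(raw)))
        stop("duplicate scaffold id in ", path, ": ",
             names(raw)[duplicated(names(raw))][1])
    chr <- toupper(as.character(raw))
    bad_pat <- paste0("[^", paste(IUPAC_NT, collapse = ""), "]")
    for (i in seq_along(chr)) {
        hit <- regexpr(bad_pat, chr[[i]])
        if (hit != -1L)
            stop("non-IUPAC character '", substring(chr[[i]], hit, hit),
                 "' in scaffold '", names(raw)[i], "' at position ", hit)
    }
    seqs <- Biostrings::DNAStringSet(chr)
    names(seqs) <- names(raw)
    runs <- IRanges::IRangesList(lapply(chr, .nRunsOne))
    names(runs) <- names(seqs)
    if (is.null(speciesId))
        speciesId <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
    methods::new("GenomeAssembly", speciesId = speciesId,
                 sequences = seqs, nRuns = runs)
}

#' Write a GenomeAssembly back to FASTA
#'
#' @param assembly a \linkS4class{GenomeAssembly}.
#' @param path output file.
#' @param width line width for wrapping.
#' @return invisibly, \code{path}.
#' @export
writeGenome <- function(assembly, path, width = 70L) {
    Biostrings::writeXStringSet(assembly@sequences, path, width = width)
    invisible(path)
}

## ---- GFF3 -------------------------------------------------------------

.gffAttr <- function(gr, field) {
    if (field %in% names(S4Vectors::mcols(gr)))
        S4Vectors::mcols(gr)[[field]]
    else
        rep(NA_character_, length(gr))
}

.firstParent <- function(parent) {
    ## rtracklayer gives Parent as a CharacterList
    p <- as.list(parent)
    vapply(p, function(x) if (length(x)) x[[1]] else NA_character_,
           character(1))
}

#' Read GFF3 gene models
#'
#' Parses gene/mRNA/exon/CDS features linked by ID/Parent into a
#' \linkS4class{GeneModels} object.  Orphan CDS features (whose Parent is not
#' a known mRNA) are grouped by Parent (or by their own ID) under a
#' synthesized single-mRNA gene.  Features on scaffolds absent from
#' \code{assembly} are rejected and reported in the \code{invalid} table.
#' Models whose total CDS length is not a positive multiple of three are
#' flagged invalid, not dropped.  Cyclic ID/Parent links are a hard error.
#'
#' @param path path to a GFF3 file.
#' @param assembly the matching \linkS4class{GenomeAssembly}; used to reject
#'   features on unknown scaffolds.  May be NULL to skip that check.
#' @return a \linkS4class{GeneModels}.
#' @export
readGeneModels <- function(path, assembly = NULL) {
    if (!file.exists(path))
        stop("GFF3 file not found: ", path)
    gr <- tryCatch(
        rtracklayer::import(path, format = "gff3"),
        error = function(e) stop("failed to parse GFF3 ", path, ": ",
                                 conditionMessage(e)))
    ids     <- .gffAttr(gr, "ID")
    parents <- .firstParent(.gffAttr(gr, "Parent"))

    ## cycle check over the ID/Parent graph
    pmap <- stats::setNames(parents[!is.na(ids)], ids[!is.na(ids)])
    for (start in names(pmap)) {
        seen <- character(); node <- start
        while (!is.na(node) && node %in% names(pmap)) {
            if (node %in% seen)
                stop("cyclic Parent links in ", path, " involving '",
                     node, "'")
            seen <- c(seen, node)
            node <- pmap[[node]]
        }
    }

    type <- as.character(gr$type)
    rejected <- DataFrame(tx_id = character(), reason = character())
    if (!is.null(assembly)) {
        known <- names(assembly@sequences)
        off <- !(as.character(GenomicRanges::seqnames(gr)) %in% known)
        if (any(off)) {
            lab <- ifelse(is.na(ids[off]), paste0("line-", which(off)),
                          ids[off])
            rejected <- DataFrame(
                tx_id = lab,
                reason = paste0("unknown scaffold '",
                                as.character(GenomicRanges::seqnames(gr))[off],
                                "'"))
            gr <- gr[!off]; ids <- ids[!off]; parents <- parents[!off]
            type <- type[!off]
        }
    }

    is_gene <- type == "gene"
    is_mrna <- type %in% c("mRNA", "transcript")
    is_exon <- type == "exon"
    is_cds  <- type == "CDS"

    gene_gr <- GenomicRanges::granges(gr[is_gene])
    gene_id <- ids[is_gene]
    gene_id[is.na(gene_id)] <- paste0("gene-", which(is.na(gene_id)))
    mrna_gr <- GenomicRanges::granges(gr[is_mrna])
    tx_id   <- ids[is_mrna]
    tx_id[is.na(tx_id)] <- paste0("tx-", which(is.na(tx_id)))
    tx_gene <- parents[is_mrna]

    ## orphan mRNAs get a synthesized gene record
    orphan_tx <- is.na(tx_gene) | !(tx_gene %in% gene_id)
    tx_gene[orphan_tx] <- tx_id[orphan_tx]

    exon_parent <- parents[is_exon]
    cds_parent  <- parents[is_cds]
    cds_ids <- ids[is_cds]
    exon_gr <- GenomicRanges::granges(gr[is_exon])
    cds_gr  <- GenomicRanges::granges(gr[is_cds])

    ## orphan CDS: Parent missing or not an mRNA -> synthesized gene + mRNA
    cds_orphan <- is.na(cds_parent) | !(cds_parent %in% tx_id)
    if (any(cds_orphan)) {
        key <- cds_parent[cds_orphan]
        own <- cds_ids[cds_orphan]
        key[is.na(key)] <- ifelse(is.na(own[is.na(key)]),
                                  paste0("orphan-cds-",
                                         seq_len(sum(is.na(key)))),
                                  own[is.na(key)])
        for (k in unique(key)) {
            sel <- which(cds_orphan)[key == k]
            span <- range(cds_gr[sel])
            if (length(span) > 1L) span <- span[1]
            new_tx <- paste0(k, ".synthesized")
            mrna_gr <- c(mrna_gr, span)
            tx_id   <- c(tx_id, new_tx)
            tx_gene <- c(tx_gene, k)
            gene_gr <- c(gene_gr, span)
            gene_id <- c(gene_id, k)
            cds_parent[sel] <- new_tx
            ## CDS implies its own exon for a synthesized model
            exon_gr <- c(exon_gr, cds_gr[sel])
            exon_parent <- c(exon_parent, rep(new_tx, length(sel)))
        }
    }

    exonsL <- S4Vectors::split(exon_gr, factor(exon_parent, levels = tx_id))
    cdsL   <- S4Vectors::split(cds_gr,  factor(cds_parent,  levels = tx_id))
    exonsL <- GenomicRanges::GRangesList(lapply(exonsL, BiocGenerics::sort))
    cdsL   <- GenomicRanges::GRangesList(lapply(cdsL, BiocGenerics::sort))

    ## transcripts with CDS but no exons: exons default to the CDS footprint;
    ## with neither: the mRNA span
    for (i in seq_along(tx_id)) {
        if (length(exonsL[[i]]) == 0L) {
            exonsL[[i]] <- if (length(cdsL[[i]]))
                GenomicRanges::reduce(cdsL[[i]])
            else
                GenomicRanges::granges(mrna_gr[i])
        }
    }

    invalid <- rejected
    for (i in seq_along(tx_id)) {
        ex <- exonsL[[i]]; cd <- cdsL[[i]]
        reasons <- character()
        if (length(ex) > 1L) {
            o <- BiocGenerics::sort(ex)
            if (any(IRanges::start(o)[-1] <= IRanges::end(o)[-length(o)]))
                reasons <- c(reasons, "overlapping exons")
        }
        if (length(cd)) {
            covered <- sum(IRanges::width(IRanges::intersect(
                GenomicRanges::ranges(cd), GenomicRanges::ranges(ex))))
            if (covered < sum(IRanges::width(cd)))
                reasons <- c(reasons, "CDS outside exons")
            tot <- sum(IRanges::width(cd))
            if (tot %% 3L != 0L)
                reasons <- c(reasons, "CDS length not multiple of 3")
        }
        if (length(reasons))
            invalid <- rbind(invalid, DataFrame(
                tx_id = tx_id[i], reason = paste(reasons, collapse = "; ")))
    }

    genes <- GenomicRanges::granges(gene_gr)
    S4Vectors::mcols(genes)$gene_id <- gene_id
    txs <- GenomicRanges::granges(mrna_gr)
    S4Vectors::mcols(txs)$tx_id <- tx_id
    S4Vectors::mcols(txs)$gene_id <- tx_gene

    sp <- if (!is.null(assembly)) assembly@speciesId else
        sub("\\.gff3?(\\.gz)?$", "", basename(path))
    methods::new("GeneModels", speciesId = sp, genes = genes,
                 transcripts = txs,
                 exons = exonsL, cds = cdsL, invalid = invalid)
}

## ---- synteny map ------------------------------------------------------

#' Read a pairwise synteny map
#'
#' Expects the 8-column tabular block format
#' \code{qseqid qstart qend tseqid tstart tend score strand} with 1-based
#' inclusive coordinates, as produced by whole-genome aligner post-processing.
#' Blocks are validated and sorted by (qseqid, qstart).  An empty file yields
#' an empty map with a warning.
#'
#' @param path path to the TSV file (no header).
#' @param focal,target species labels for the two genomes.
#' @return a \linkS4class{SyntenyMap}.
#' @export
readSyntenyMap <- function(path, focal = "focal", target = "target") {
    if (!file.exists(path))
        stop("synteny map not found: ", path)
    cols <- c("qseqid", "qstart", "qend", "tseqid", "tstart", "tend",
              "score", "strand")
    if (file.size(path) == 0L ||
        length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
        warning("empty synteny map: ", path)
        b <- data.frame(qseqid = character(), qstart = integer(),
                        qend = integer(), tseqid = character(),
                        tstart = integer(), tend = integer(),
                        score = numeric(), strand = character(),
                        stringsAsFactors = FALSE)
        return(methods::new("SyntenyMap", focal = focal, target = target,
                            blocks = b))
    }
    b <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = cols,
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer", "integer",
                                          "numeric", "character"))
    if (any(b$qstart > b$qend))
        stop("synteny block with qstart > qend at row ",
             which(b$qstart > b$qend)[1])
    if (any(b$tstart > b$tend))
        stop("synteny block with tstart > tend at row ",
             which(b$tstart > b$tend)[1])
    if (!all(b$strand %in% c("+", "-")))
        stop("unknown strand symbol '",
             setdiff(unique(b$strand), c("+", "-"))[1], "' in ", path)
    b <- b[order(b$qseqid, b$qstart), , drop = FALSE]
    rownames(b) <- NULL
    methods::new("SyntenyMap", focal = focal, target = target, blocks = b)
}

#' Write a synteny map in the 8-column block format
#' @param synmap a \linkS4class{SyntenyMap}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSyntenyMap <- function(synmap, path) {
    utils::write.table(synmap@blocks, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## ---- species tree -----------------------------------------------------

.treeChildren <- function(tree, node) {
    tree$edge[tree$edge[, 1] == node, 2]
}

.descendantTips <- function(tree, node) {
    ntip <- length(tree$tip.label)
    if (node <= ntip) return(tree$tip.label[node])
    out <- character()
    stack <- node
    while (length(stack)) {
        n <- stack[[1]]; stack <- stack[-1]
        kids <- .treeChildren(tree, n)
        out <- c(out, tree$tip.label[kids[kids <= ntip]])
        stack <- c(stack, kids[kids > ntip])
    }
    out
}

#' Read a rooted species tree and derive the focal lineage structure
#'
#' Reads a Newick tree, checks that the focal species is a leaf, and computes
#' the ancestor path p_0..p_K (parent of the focal leaf up to the root) plus
#' the cousin sets t_0..t_K.  Multifurcating trees are accepted; cousin sets
#' are defined purely by the ancestor path and remain a disjoint, exhaustive
#' partition of the non-focal leaves.
#'
#' @param path path to a Newick file, or a Newick string.
#' @param focal focal leaf label.
#' @return a \linkS4class{SpeciesTreePath}.
#' @export
readSpeciesTree <- function(path, focal) {
    tree <- if (file.exists(path)) ape::read.tree(path)
            else ape::read.tree(text = path)
    if (is.null(tree))
        stop("could not parse Newick tree from ", path)
    if (!(focal %in% tree$tip.label))
        stop("focal species '", focal, "' is not a leaf of the tree")
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    tip <- which(tree$tip.label == focal)
    ## parent chain from focal tip to root
    anc <- integer()
    node <- tip
    while (node != root) {
        node <- tree$edge[tree$edge[, 2] == node, 1]
        anc <- c(anc, node)
    }
    labels <- vapply(seq_along(anc), function(i) {
        j <- anc[i] - ntip
        lb <- if (!is.null(tree$node.label) && j <= length(tree$node.label))
            tree$node.label[j] else ""
        if (is.na(lb) || !nzchar(lb)) paste0("p", i - 1L) else lb
    }, character(1))
    sets <- vector("list", length(anc))
    prev <- focal
    for (i in seq_along(anc)) {
        below <- .descendantTips(tree, anc[i])
        sets[[i]] <- setdiff(below, prev)
        prev <- below
    }
    names(sets) <- labels
    methods::new("SpeciesTreePath", tree = tree, focal = focal,
                 ancestors = labels, cousinSets = sets)
}

## ---- run configuration ------------------------------------------------

#' Default run configuration
#'
#' Returns the full default parameter set.  All thresholds are surfaced here
#' and echoed into the run manifest, so a run is reproducible from its
#' manifest alone.
#'
#' Key parameters: \code{min_orf_codons} (ORF cutoff, amino acids, default
#' 30), \code{alpha} (significance threshold on adjusted p-values, default
#' 0.05), \code{indel_ratio} (search-interval/query length ratio below which
#' the interval is indel-eligible), \code{n_run_min} (minimum N-run length,
#' nt, to call an assembly gap), \code{max_interval_nt} (intervals longer
#' than this are skipped as technically unsearchable),
#' \code{scramble_window}/\code{scramble_threshold} (anchor-pair window and
#' discordance fraction that call scrambled synteny),
#' \code{min_query_coverage} (identity coverage: the fraction of query
#' positions a significant alignment must match identically before it
#' counts as evidence), and the alignment scoring parameters.
#'
#' @return a named list.
#' @export
defaultRunConfig <- function() {
    list(
        focal   = NULL,   # list(id=, genome=, gff=)
        targets = list(), # list of list(id=, genome=, gff=, synteny=)
        tree    = NULL,
        queries = NULL,   # path to one-gene-id-per-line file, or NULL = all
        outdir  = ".",
        seed    = 1L,
        min_orf_codons     = 30L,
        orf_require_atg    = TRUE,
        alpha              = 0.05,
        p_adjust_method    = "BH",
        indel_ratio        = 0.25,
        n_run_min          = 10L,
        max_interval_nt    = 1e6,
        scramble_window    = 5L,
        scramble_threshold = 0.5,
        min_query_coverage = 0.25,
        null_shuffles      = 100L,
        aa_gap_opening     = 10,
        aa_gap_extension   = 1,
        nt_match           = 2,
        nt_mismatch        = -3,
        nt_gap_opening     = 5,
        nt_gap_extension   = 2,
        decision_tree      = NULL  # NULL = default node order
    )
}

#' Validate a run configuration
#' @param cfg a configuration list.
#' @return the validated list (invisibly errors otherwise).
#' @export
validateRunConfig <- function(cfg) {
    stopifnot(is.list(cfg))
    num_pos <- c("min_orf_codons", "indel_ratio", "n_run_min",
                 "max_interval_nt", "scramble_window", "null_shuffles",
                 "aa_gap_opening", "aa_gap_extension",
                 "nt_gap_opening", "nt_gap_extension")
    for (p in num_pos) {
        if (is.null(cfg[[p]]) || !is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
            stop("configuration parameter '", p,
                 "' must be strictly positive")
    }
    if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
        stop("alpha must lie in (0, 1)")
    if (cfg$indel_ratio >= 1)
        stop("indel_ratio must lie in (0, 1)")
    if (!is.numeric(cfg$min_query_coverage) ||
        cfg$min_query_coverage < 0 || cfg$min_query_coverage > 1)
        stop("min_query_coverage must lie in [0, 1]")
    if (!is.numeric(cfg$scramble_threshold) ||
        cfg$scramble_threshold < 0 || cfg$scramble_threshold > 1)
        stop("scramble_threshold must lie in [0, 1]")
    invisible(cfg)
}

#' Read a YAML run configuration
#'
#' Unset parameters fall back to \code{\link{defaultRunConfig}}.  Relative
#' input paths are resolved against the directory of the YAML file.
#'
#' @param path path to a YAML file.
#' @return a validated configuration list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- defaultRunConfig()
    for (k in names(user)) cfg[[k]] <- user[[k]]
    base <- dirname(normalizePath(path))
    fix <- function(p) {
        if (is.null(p) || file.exists(p)) return(p)
        cand <- file.path(base, p)
        if (file.exists(cand)) cand else p
    }
    if (!is.null(cfg$focal)) {
        cfg$focal$genome <- fix(cfg$focal$genome)
        cfg$focal$gff    <- fix(cfg$focal$gff)
    }
    cfg$targets <- lapply(cfg$targets, function(t) {
        t$genome <- fix(t$genome); t$gff <- fix(t$gff)
        t$synteny <- fix(t$synteny); t
    })
    cfg$tree <- fix(cfg$tree)
    cfg$queries <- fix(cfg$queries)
    validateRunConfig(cfg)
    cfg
}

## ---- tabular output ---------------------------------------------------

#' Write a table as TSV with a header row
#' @param df a data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Export search intervals as BED
#'
#' BED uses 0-based half-open coordinates; internal 1-based closed intervals
#' are converted at this boundary only.
#'
#' @param si a search-interval table from \code{\link{inferSearchIntervals}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportBed <- function(si, path) {
    mapped <- si[!si$unmapped, , drop = FALSE]
    bed <- data.frame(chrom = mapped$tseqid,
                      chromStart = mapped$tstart - 1L,
                      chromEnd = mapped$tend,
                      name = mapped$query_gene_id,
                      score = 0L,
                      strand = ".")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
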