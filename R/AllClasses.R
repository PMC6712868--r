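#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' GenomeAssembly: a loaded genome with its N-run index
#'
#' Holds one species' assembly as a \link[Biostrings]{DNAStringSet} together
#' with, per scaffold, the maximal runs of the ambiguity character N.  N runs
#' are pre-indexed because downstream interval diagnostics repeatedly ask
#' whether a syntenic search interval crosses a gap in the assembly.
#'
#' @slot speciesId single character label for the species.
#' @slot sequences \link[Biostrings]{DNAStringSet}, one entry per scaffold.
#' @slot nRuns \link[IRanges]{IRangesList} parallel to \code{sequences};
#'   maximal runs of N/n in 1-based closed coordinates.
#'
#' @aliases GenomeAssembly-class
#' @exportClass GenomeAssembly
setClass("GenomeAssembly",
    representation(
        speciesId = "character",
        sequences = "DNAStringSet",
        nRuns     = "IRangesList"
    )
)

setValidity("GenomeAssembly", function(object) {
    msg <- character()
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "scaffold names must be present and unique")
    if (length(object@speciesId) != 1L)
        msg <- c(msg, "speciesId must be a single string")
    if (length(object@nRuns) != length(object@sequences))
        msg <- c(msg, "nRuns must be parallel to sequences")
    if (length(object@sequences) && length(object@nRuns) == length(object@sequences)) {
        len <- Biostrings::width(object@sequences)
        bad <- vapply(seq_along(object@nRuns), function(i) {
            r <- object@nRuns[[i]]
            length(r) > 0L && (min(IRanges::start(r)) < 1L ||
                               max(IRanges::end(r)) > len[i])
        }, logical(1))
        if (any(bad))
            msg <- c(msg, "all N runs must lie within their scaffold")
    }
    if (length(msg)) msg else TRUE
})

#' GeneModels: gene/mRNA/exon/CDS structures for one species
#'
#' Gene models are kept at transcript resolution: \code{exons} and \code{cds}
#' are \link[GenomicRanges]{GRangesList}s named by transcript id, and
#' \code{transcripts} links each transcript to its gene and scaffold.  Models
#' that fail structural checks (CDS length not a multiple of three, CDS
#' outside its exons, CDS beyond the scaffold end) are flagged in
#' \code{invalid} rather than dropped: they are excluded from protein-based
#' search but still occupy genomic space for overlap tests.
#'
#' @slot speciesId species label.
#' @slot genes \link[GenomicRanges]{GRanges} of gene spans with metadata
#'   column \code{gene_id}.
#' @slot transcripts \link[GenomicRanges]{GRanges} of mRNA spans with
#'   metadata columns \code{tx_id} and \code{gene_id}.
#' @slot exons \link[GenomicRanges]{GRangesList} of exons per transcript.
#' @slot cds \link[GenomicRanges]{GRangesList} of CDS parts per transcript.
#' @slot invalid \link[S4Vectors]{DataFrame} with columns \code{tx_id} and
#'   \code{reason}; transcripts listed here yield no protein.
#'
#' @aliases GeneModels-class
#' @exportClass GeneModels
setClass("GeneModels",
    representation(
        speciesId   = "character",
        genes       = "GRanges",
        transcripts = "GRanges",
        exons       = "GRangesList",
        cds         = "GRangesList",
        invalid     = "DataFrame"
    )
)

setValidity("GeneModels", function(object) {
    msg <- character()
    if (anyDuplicated(object@genes$gene_id))
        msg <- c(msg, "gene_id values must be unique")
    if (anyDuplicated(object@transcripts$tx_id))
        msg <- c(msg, "tx_id values must be unique")
    if (!all(names(object@exons) %in% object@transcripts$tx_id))
        msg <- c(msg, "exons must be named by known tx_id")
    if (!all(names(object@cds) %in% object@transcripts$tx_id))
        msg <- c(msg, "cds must be named by known tx_id")
    if (length(msg)) msg else TRUE
})

#' SyntenyMap: pairwise synteny blocks between a focal and a target genome
#'
#' One row per aligned block.  Coordinates are 1-based closed on both sides
#' (converted once at file read from whatever the upstream aligner emitted).
#' \code{strand} is the orientation of the target interval relative to the
#' query interval.  Blocks are kept sorted by (qseqid, qstart).
#'
#' @slot focal focal species label.
#' @slot target target species label.
#' @slot blocks data.frame with columns qseqid, qstart, qend, tseqid,
#'   tstart, tend, score, strand.
#'
#' @aliases SyntenyMap-class
#' @exportClass SyntenyMap
setClass("SyntenyMap",
    representation(
        focal  = "character",
        target = "character",
        blocks = "data.frame"
    )
)

setValidity("SyntenyMap", function(object) {
    msg <- character()
    need <- c("qseqid", "qstart", "qend", "tseqid", "tstart", "tend",
              "score", "strand")
    if (!all(need %in% names(object@blocks)))
        msg <- c(msg, paste("blocks must have columns:",
                            paste(need, collapse = ", ")))
    else {
        b <- object@blocks
        if (nrow(b)) {
            if (any(b$qstart > b$qend) || any(b$tstart > b$tend))
                msg <- c(msg, "block intervals must be non-empty")
            if (!all(b$strand %in% c("+", "-")))
                msg <- c(msg, "strand must be '+' or '-'")
            if (any(b$score < 0))
                msg <- c(msg, "scores must be non-negative")
            o <- order(b$qseqid, b$qstart)
            if (!identical(o, seq_len(nrow(b))))
                msg <- c(msg, "blocks must be sorted by (qseqid, qstart)")
        }
    }
    if (length(msg)) msg else TRUE
})

#' SpeciesTreePath: a rooted species tree viewed from the focal species
#'
#' Stores the rooted tree plus the derived quantities the origin stage needs:
#' the ancestor path p_0..p_K from the parent of the focal leaf to the root,
#' and the cousin sets t_0..t_K, where t_i holds the leaves descending from
#' p_i but not from p_(i-1) (t_0 = siblings of the focal species).  Cousin
#' sets are pairwise disjoint and together contain every non-focal leaf.
#'
#' @slot tree an \link[ape]{ape} \code{phylo} object (rooted; multifurcations
#'   allowed).
#' @slot focal focal leaf label.
#' @slot ancestors character vector of ancestor node names p_0..p_K
#'   (node labels when present, otherwise "p0", "p1", ...).
#' @slot cousinSets named list of character vectors, one per ancestor.
#'
#' @aliases SpeciesTreePath-class
#' @exportClass SpeciesTreePath
setClass("SpeciesTreePath",
    representation(
        tree       = "ANY",
        focal      = "character",
        ancestors  = "character",
        cousinSets = "list"
    )
)

setValidity("SpeciesTreePath", function(object) {
    msg <- character()
    if (!inherits(object@tree, "phylo"))
        msg <- c(msg, "tree must be a phylo object")
    else {
        tips <- object@tree$tip.label
        if (!(object@focal %in% tips))
            msg <- c(msg, "focal must be a tip label of the tree")
        sets <- object@cousinSets
        if (length(sets) != length(object@ancestors))
            msg <- c(msg, "one cousin set per ancestor required")
        all_leaves <- unlist(sets, use.names = FALSE)
        if (anyDuplicated(all_leaves))
            msg <- c(msg, "cousin sets must be pairwise disjoint")
        if (!setequal(all_leaves, setdiff(tips, object@focal)))
            msg <- c(msg, "cousin sets must partition the non-focal leaves")
        if (any(lengths(sets) == 0L))
            msg <- c(msg, "cousin sets must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' DerivedSequences: transcripts, CDS and proteins derived from gene models
#'
#' @slot speciesId species label.
#' @slot transcripts spliced transcript sequences
#'   (\link[Biostrings]{DNAStringSet}, named by tx_id).
#' @slot cdsSeqs spliced CDS sequences (DNAStringSet, named by tx_id).
#' @slot proteins translated proteins without the terminal stop
#'   (\link[Biostrings]{AAStringSet}, named by tx_id); transcripts whose CDS
#'   failed validation are absent here.
#' @slot cdsInTx \link[IRanges]{IRanges} named by tx_id: the CDS footprint in
#'   spliced-transcript coordinates (used to separate the annotated CDS from
#'   other ORFs on the same transcript).
#' @slot flags \link[S4Vectors]{DataFrame} with one row per transcript:
#'   tx_id, gene_id, valid, internal_stop, missing_start, not_mult3,
#'   out_of_bounds.
#'
#' @aliases DerivedSequences-class
#' @exportClass DerivedSequences
setClass("DerivedSequences",
    representation(
        speciesId   = "character",
        transcripts = "DNAStringSet",
        cdsSeqs     = "DNAStringSet",
        proteins    = "AAStringSet",
        cdsInTx     = "IRanges",
        flags       = "DataFrame"
    )
)

setGeneric("speciesId", function(x) standardGeneric("speciesId"))
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))
setGeneric("nRuns", function(x) standardGeneric("nRuns"))
setGeneric("blocks", function(x) standardGeneric("blocks"))
setGeneric("cousinSets", function(x) standardGeneric("cousinSets"))
setGeneric("ancestorPath", function(x) standardGeneric("ancestorPath"))
setGeneric("focalSpecies", function(x) standardGeneric("focalSpecies"))

#' @describeIn GenomeAssembly species label
#' @param x object
#' @export
setMethod("speciesId", "GenomeAssembly", function(x) x@speciesId)

#' @describeIn GeneModels species label
#' @export
setMethod("speciesId", "GeneModels", function(x) x@speciesId)

#' @describeIn DerivedSequences species label
#' @export
setMethod("speciesId", "DerivedSequences", function(x) x@speciesId)

#' @describeIn GenomeAssembly named integer vector of scaffold lengths
#' @export
setMethod("scaffoldLengths", "GenomeAssembly", function(x) {
    stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
})

#' @describeIn GenomeAssembly per-scaffold IRangesList of maximal N runs
#' @export
setMethod("nRuns", "GenomeAssembly", function(x) x@nRuns)

#' @describeIn SyntenyMap the block table
#' @export
setMethod("blocks", "SyntenyMap", function(x) x@blocks)

#' @describeIn SpeciesTreePath named list of cousin leaf sets t_0..t_K
#' @export
setMethod("cousinSets", "SpeciesTreePath", function(x) x@cousinSets)

#' @describeIn SpeciesTreePath ancestor node names p_0..p_K
#' @export
setMethod("ancestorPath", "SpeciesTreePath", function(x) x@ancestors)

#' @describeIn SpeciesTreePath focal leaf label
#' @export
setMethod("focalSpecies", "SpeciesTreePath", function(x) x@focal)

setMethod("show", "GenomeAssembly", function(object) {
    cat("GenomeAssembly:", object@speciesId, "\n")
    cat(" ", length(object@sequences), "scaffold(s),",
        sum(as.numeric(Biostrings::width(object@sequences))), "nt,",
        sum(lengths(object@nRuns)), "N run(s)\n")
})

setMethod("show", "GeneModels", function(object) {
    cat("GeneModels:", object@speciesId, "\n")
    cat(" ", length(object@genes), "gene(s),",
        length(object@transcripts), "transcript(s),",
        nrow(object@invalid), "flagged invalid\n")
})

setMethod("show", "SyntenyMap", function(object) {
    cat("SyntenyMap:", object@focal, "->", object@target, "\n")
    cat(" ", nrow(object@blocks), "block(s)\n")
})

setMethod("show", "SpeciesTreePath", function(object) {
    cat("SpeciesTreePath: focal =", object@focal,
        "| K =", length(object@ancestors) - 1L, "\n")
    for (i in seq_along(object@cousinSets))
        cat("  t_", i - 1L, " (", object@ancestors[i], "): ",
            paste(object@cousinSets[[i]], collapse = ", "), "\n", sep = "")
})

setMethod("show", "DerivedSequences", function(object) {
    cat("DerivedSequences:", object@speciesId, "\n")
    cat(" ", length(object@transcripts), "transcript(s),",
        length(object@proteins), "valid protein(s),",
        sum(!object@flags$valid), "flagged\n")
})
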