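## Homology-class decision tree.
##
## Thirteen classes in three groups:
##   AAic    A_gen, A_trn, A_orf      amino-acid-level homology
##   NTic    N_cds, N_exo, N_rna, N_dna   nucleotide-only homology
##   Unknown U_una, U_nst, U_tec, U_ind, U_scr, U_nm   no homology found,
##           with the inferred reason (assembly edge / N gap / interval too
##           long to search / indel / scrambled synteny / no match)
## Evaluation is first-affirmative: the first predicate that holds wins.
## Within Unknown, technical causes (missing assembly, N gaps, skipped
## oversize intervals) are tested before biological inferences (indel,
## scramble), so assembly artifacts pre-empt biological claims; U_nm is the
## mandatory fallback.  The node order is configurable.

HOMOLOGY_LABELS <- c("A_gen", "A_trn", "A_orf",
                     "N_cds", "N_exo", "N_rna", "N_dna",
                     "U_una", "U_nst", "U_tec", "U_ind", "U_scr", "U_nm")

#' Group of a homology label
#' @param label character vector of homology class labels.
#' @return "AAic", "NTic" or "Unknown" for each label.
#' @export
homologyGroup <- function(label) {
    stopifnot(all(label %in% HOMOLOGY_LABELS))
    c(A = "AAic", N = "NTic", U = "Unknown")[substr(label, 1, 1)]
}

## Predicate registry: each maps (evidence flags, diagnostics row) -> logical
.PREDICATES <- list(
    A_gen = function(ev, diag) isTRUE(ev$aa_gen),
    A_trn = function(ev, diag) isTRUE(ev$aa_trn),
    A_orf = function(ev, diag) isTRUE(ev$aa_orf),
    N_cds = function(ev, diag) isTRUE(ev$nt_cds),
    N_exo = function(ev, diag) isTRUE(ev$nt_exo),
    N_rna = function(ev, diag) isTRUE(ev$nt_rna),
    N_dna = function(ev, diag) isTRUE(ev$nt_dna),
    U_una = function(ev, diag) isTRUE(diag$unmapped) || isTRUE(diag$at_edge),
    U_nst = function(ev, diag) isTRUE(diag$contains_n_run),
    U_tec = function(ev, diag) isTRUE(diag$oversize),
    U_ind = function(ev, diag) !is.na(diag$length_ratio) &&
        diag$length_ratio < diag$indel_ratio,
    U_scr = function(ev, diag) isTRUE(diag$scrambled),
    U_nm  = function(ev, diag) TRUE
)

#' The default decision tree
#'
#' An ordered vector of homology-class labels; each label names a predicate,
#' and classification takes the first predicate that returns TRUE.  The
#' final fallback (U_nm) is mandatory.  Pass a reordered subset (always
#' ending in U_nm) as \code{cfg$decision_tree} to customize.
#'
#' @return character vector of labels in evaluation order.
#' @export
defaultDecisionTree <- function() HOMOLOGY_LABELS

.checkTree <- function(tree) {
    if (!all(tree %in% HOMOLOGY_LABELS))
        stop("unknown decision-tree node(s): ",
             paste(setdiff(tree, HOMOLOGY_LABELS), collapse = ", "))
    if (tree[length(tree)] != "U_nm")
        stop("decision tree must end with the fallback node U_nm")
    tree
}

#' Classify one query x target evidence bundle
#'
#' Total function: exactly one of the thirteen labels is returned for any
#' input, by first-affirmative evaluation of the decision tree.
#'
#' @param evidence evidence flags from \code{\link{searchIntervalEvidence}}.
#' @param diagnostics one-row diagnostics from
#'   \code{\link{intervalDiagnostics}}.
#' @param tree ordered label vector (default \code{\link{defaultDecisionTree}}).
#' @param cfg run configuration (supplies \code{indel_ratio}).
#' @return a single homology-class label.
#' @export
classify <- function(evidence, diagnostics, tree = defaultDecisionTree(),
                     cfg = defaultRunConfig()) {
    tree <- .checkTree(tree)
    diagnostics$indel_ratio <- cfg$indel_ratio
    for (label in tree) {
        if (.PREDICATES[[label]](evidence, diagnostics))
            return(label)
    }
    "U_nm"  # unreachable: U_nm is a mandatory tree node
}

#' Classify all query genes against all targets
#'
#' Runs search-interval inference, evidence collection and decision-tree
#' classification for every (query gene, target species) pair, returning a
#' dense table with one row per pair.
#'
#' @param focalModels focal \linkS4class{GeneModels}.
#' @param focalAssembly focal \linkS4class{GenomeAssembly}.
#' @param focalDerived focal \linkS4class{DerivedSequences}.
#' @param targets named list (by target species id), each element a list
#'   with components \code{assembly}, \code{models}, \code{derived},
#'   \code{synmap}.
#' @param cfg run configuration.
#' @param queryIds character vector of focal gene ids to classify (default:
#'   all genes with models).
#' @return data.frame with columns query_gene_id, target_species, label,
#'   group, best_hit_id, p_adjusted and the diagnostics columns.
#' @export
classifyAll <- function(focalModels, focalAssembly, focalDerived, targets,
                        cfg = defaultRunConfig(), queryIds = NULL) {
    if (is.null(queryIds))
        queryIds <- as.character(focalModels@genes$gene_id)
    if (length(queryIds) == 0L)
        return(data.frame(query_gene_id = character(),
                          target_species = character(),
                          label = character(), group = character(),
                          best_hit_id = character(),
                          p_adjusted = numeric(),
                          stringsAsFactors = FALSE))
    missing_q <- setdiff(queryIds, focalModels@genes$gene_id)
    if (length(missing_q))
        stop("query gene(s) not in focal gene models: ",
             paste(missing_q, collapse = ", "))
    for (tn in names(targets)) {
        t <- targets[[tn]]
        if (is.null(t$assembly) || is.null(t$models) ||
            is.null(t$derived) || is.null(t$synmap))
            stop("target '", tn, "' is missing assembly, models, derived ",
                 "sequences or a synteny map")
    }
    tree <- if (is.null(cfg$decision_tree)) defaultDecisionTree()
            else .checkTree(cfg$decision_tree)
    reps <- representativeProteins(focalDerived)
    genes <- focalModels@genes
    nullCache <- new.env(parent = emptyenv())
    rows <- list()
    for (tn in names(targets)) {
        t <- targets[[tn]]
        si_all <- inferSearchIntervals(focalModels, t$synmap, t$assembly,
                                       cfg, queryIds = queryIds)
        for (gid in queryIds) {
            gi <- which(genes$gene_id == gid)
            glen <- IRanges::width(genes)[gi]
            gseq <- Biostrings::subseq(
                focalAssembly@sequences[[
                    as.character(GenomicRanges::seqnames(genes))[gi]]],
                IRanges::start(genes)[gi], IRanges::end(genes)[gi])
            if (as.character(GenomicRanges::strand(genes))[gi] == "-")
                gseq <- Biostrings::reverseComplement(gseq)
            prot <- if (gid %in% names(reps)) reps[[gid]] else NULL
            si <- si_all[si_all$query_gene_id == gid, , drop = FALSE]
            diag <- intervalDiagnostics(si, glen, t$assembly, cfg)
            ev <- suppressWarnings(searchIntervalEvidence(
                gid, prot, gseq, si, t$assembly, t$models, t$derived,
                cfg, nullCache))
            label <- classify(ev, diag, tree, cfg)
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(query_gene_id = gid, target_species = tn,
                           label = label,
                           group = unname(homologyGroup(label)),
                           best_hit_id = ev$best_hit,
                           p_adjusted = ev$best_p,
                           stringsAsFactors = FALSE),
                diag[, setdiff(names(diag), "query_gene_id"), drop = FALSE])
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
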