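## Collapsing per-species homology classes across the species tree.
##
## For each ancestor p_i on the focal lineage, the cousin set t_i is
## collapsed to one of {A, N, U} under a single-birth model:
##   A if any leaf in t_i is AAic;
##   N if all leaves in t_i are NTic;
##   U otherwise (any Unknown leaf leaves open the possibility of a hidden
##     AAic match, so mixed N/U collapses to U).
## The resulting UNA vector s_0..s_K yields a synteny-based phylostratum:
## the deepest i with s_i = A; a vector with no A is split into
## focal_specific (s_0 = N: positive evidence that the nearest relatives
## carry only non-coding homologs, the supported de novo pattern) versus
## unknown (s_0 = U: no positive evidence anywhere).

#' Collapse one cousin set's leaf groups to a single label
#'
#' @param leafGroups character vector of homology groups
#'   ("AAic", "NTic", "Unknown"), one per leaf of the cousin set; leaves
#'   with no data must be passed as "Unknown".
#' @return "A", "N" or "U".
#' @export
collapseSubtree <- function(leafGroups) {
    if (length(leafGroups) == 0L)
        stop("empty cousin set: species tree is malformed")
    stopifnot(all(leafGroups %in% c("AAic", "NTic", "Unknown")))
    if (any(leafGroups == "AAic")) return("A")
    if (all(leafGroups == "NTic")) return("N")
    "U"
}

#' Build the UNA vector for one query gene
#'
#' Maps each target species' homology class to a group and collapses each
#' cousin set.  In \code{default} mode every AAic class (A_gen, A_trn,
#' A_orf) counts as amino-acid-level support; in \code{strict} mode only
#' matches to annotated target genes (A_gen) count, and A_trn/A_orf are
#' demoted to Unknown, which emulates annotation-based phylostratigraphy
#' restricted to syntenic regions.  Tree leaves with no class (missing
#' genomes) are treated as Unknown.
#'
#' @param classes named character vector: homology-class label per target
#'   species.
#' @param tree a \linkS4class{SpeciesTreePath}.
#' @param mode "default" or "strict".
#' @return character vector s_0..s_K over {A,N,U}, named by ancestor.
#' @export
buildUna <- function(classes, tree, mode = c("default", "strict")) {
    mode <- match.arg(mode)
    known_leaves <- setdiff(tree@tree$tip.label, tree@focal)
    extra <- setdiff(names(classes), known_leaves)
    if (length(extra))
        stop("classes given for species not in the tree: ",
             paste(extra, collapse = ", "))
    leafGroup <- function(sp) {
        if (!(sp %in% names(classes)) || is.na(classes[[sp]]))
            return("Unknown")
        lab <- classes[[sp]]
        if (mode == "strict" && lab %in% c("A_trn", "A_orf"))
            return("Unknown")
        unname(homologyGroup(lab))
    }
    sets <- cousinSets(tree)
    s <- vapply(sets, function(leaves)
        collapseSubtree(vapply(leaves, leafGroup, character(1))),
        character(1))
    names(s) <- ancestorPath(tree)
    s
}

#' Assign a synteny-based phylostratum from a UNA vector
#'
#' The stratum is the ancestor p_m with m = max{i : s_i = A} (the deepest
#' cousin set with amino-acid-level support).  Vectors without any A are
#' split on s_0: N means the closest relatives carry non-coding homologs
#' (\code{focal_specific}; the supported de novo orphan pattern), U means
#' no positive evidence at all (\code{unknown}).
#'
#' @param una character vector from \code{\link{buildUna}}.
#' @param tree a \linkS4class{SpeciesTreePath}.
#' @return list with \code{stratum} (ancestor name, "focal_specific" or
#'   "unknown") and \code{depth} (0-based index of the stratum ancestor, or
#'   NA).
#' @export
assignPhylostratum <- function(una, tree) {
    stopifnot(all(una %in% c("A", "N", "U")))
    a <- which(una == "A")
    if (length(a)) {
        m <- max(a)
        return(list(stratum = ancestorPath(tree)[m], depth = m - 1L))
    }
    if (una[1] == "N")
        return(list(stratum = "focal_specific", depth = NA_integer_))
    list(stratum = "unknown", depth = NA_integer_)
}

#' UNA vectors and phylostrata for a whole classification table
#'
#' @param classTable output of \code{\link{classifyAll}}.
#' @param tree a \linkS4class{SpeciesTreePath}.
#' @param mode "default" or "strict".
#' @return data.frame: query_gene_id, una (collapsed label string such as
#'   "AUU"), stratum, depth, mode.
#' @export
unaTable <- function(classTable, tree, mode = c("default", "strict")) {
    mode <- match.arg(mode)
    genes <- unique(classTable$query_gene_id)
    rows <- lapply(genes, function(g) {
        sub <- classTable[classTable$query_gene_id == g, , drop = FALSE]
        classes <- stats::setNames(sub$label, sub$target_species)
        una <- buildUna(classes, tree, mode)
        ps <- assignPhylostratum(una, tree)
        data.frame(query_gene_id = g,
                   una = paste(una, collapse = ""),
                   stratum = ps$stratum,
                   depth = ps$depth,
                   mode = mode,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Compare default and strict phylostratum calls
#'
#' Joins per-gene strata under both modes (plus an optional user-supplied
#' standard-phylostratigraphy table) and counts agreements and
#' disagreements per stratum.  Standard phylostrata are an external input;
#' they are never computed here.
#'
#' @param defaultCalls,strictCalls outputs of \code{\link{unaTable}} for the
#'   two modes.
#' @param standardStrata optional data.frame with columns
#'   \code{query_gene_id} and \code{stratum}.
#' @return list with \code{per_gene} (one row per gene with the stratum
#'   under each mode) and \code{summary} (counts per stratum combination).
#' @export
compareModes <- function(defaultCalls, strictCalls, standardStrata = NULL) {
    if (!setequal(defaultCalls$query_gene_id, strictCalls$query_gene_id))
        stop("query sets differ between modes: ",
             paste(union(setdiff(defaultCalls$query_gene_id,
                                 strictCalls$query_gene_id),
                         setdiff(strictCalls$query_gene_id,
                                 defaultCalls$query_gene_id)),
                   collapse = ", "))
    per <- merge(
        defaultCalls[, c("query_gene_id", "una", "stratum")],
        strictCalls[, c("query_gene_id", "una", "stratum")],
        by = "query_gene_id", suffixes = c("_default", "_strict"))
    if (!is.null(standardStrata)) {
        if (!setequal(standardStrata$query_gene_id, per$query_gene_id))
            stop("query sets differ between modes and standard strata: ",
                 paste(union(setdiff(standardStrata$query_gene_id,
                                     per$query_gene_id),
                             setdiff(per$query_gene_id,
                                     standardStrata$query_gene_id)),
                       collapse = ", "))
        names(standardStrata)[names(standardStrata) == "stratum"] <-
            "stratum_standard"
        per <- merge(per, standardStrata[, c("query_gene_id",
                                             "stratum_standard")],
                     by = "query_gene_id")
    }
    per <- per[order(per$query_gene_id), , drop = FALSE]
    rownames(per) <- NULL
    agree <- per$stratum_default == per$stratum_strict
    summ <- as.data.frame(table(stratum_default = per$stratum_default,
                                stratum_strict = per$stratum_strict),
                          stringsAsFactors = FALSE)
    summ <- summ[summ$Freq > 0L, , drop = FALSE]
    names(summ)[names(summ) == "Freq"] <- "n_genes"
    rownames(summ) <- NULL
    list(per_gene = per, summary = summ,
         n_agree = sum(agree), n_disagree = sum(!agree))
}
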