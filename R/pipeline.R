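## Pipeline orchestration: stage 1 (load + derive + search intervals),
## stage 2 (evidence + decision tree), stage 3 (UNA vectors, phylostrata,
## default-vs-strict comparison), plus the run manifest and summaries.

.loadSpecies <- function(id, genome_path, gff_path) {
    assembly <- readGenome(genome_path, speciesId = id)
    models <- readGeneModels(gff_path, assembly)
    models@speciesId <- id
    derived <- deriveSequences(assembly, models)
    list(assembly = assembly, models = models, derived = derived)
}

#' Summarize a classification table
#'
#' Per-target homology-class counts; the counts partition the input rows
#' exactly.
#'
#' @param classTable output of \code{\link{classifyAll}}.
#' @return data.frame target_species x label with counts (all thirteen
#'   labels listed, zeros included).
#' @export
summarizeClasses <- function(classTable) {
    tab <- table(target_species = classTable$target_species,
                 label = factor(classTable$label,
                                levels = HOMOLOGY_LABELS))
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out)[names(out) == "Freq"] <- "n_genes"
    out$group <- unname(homologyGroup(out$label))
    out <- out[order(out$target_species,
                     match(out$label, HOMOLOGY_LABELS)), ,
               drop = FALSE]
    rownames(out) <- NULL
    out[, c("target_species", "label", "group", "n_genes")]
}

#' Summarize a UNA table
#'
#' Counts of UNA label strings by phylostratum (ordered by stratum depth,
#' deepest first).
#'
#' @param una output of \code{\link{unaTable}}.
#' @return data.frame with columns una, stratum, mode, n_genes.
#' @export
summarizeUna <- function(una) {
    agg <- stats::aggregate(list(n_genes = una$query_gene_id),
                            by = list(una = una$una,
                                      stratum = una$stratum,
                                      mode = una$mode),
                            FUN = length)
    depth <- vapply(seq_len(nrow(agg)), function(i) {
        d <- una$depth[una$una == agg$una[i] &
                       una$stratum == agg$stratum[i]][1]
        if (is.na(d)) -1L else as.integer(d)
    }, integer(1))
    agg <- agg[order(-depth, agg$stratum, agg$una), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

#' Run the full pipeline from a configuration
#'
#' Loads and validates all inputs, infers syntenic search intervals,
#' classifies every query gene against every target, collapses classes into
#' UNA vectors (default and strict modes) and phylostrata, and writes all
#' tabular outputs plus a run manifest into the output directory.  Any
#' validation failure aborts before any class table is written.  Reruns
#' with an identical configuration and seed produce byte-identical tables.
#'
#' Outputs written to \code{outdir}: \code{classes.tsv} (one row per query x
#' target with label and diagnostics), \code{una_default.tsv} /
#' \code{una_strict.tsv}, \code{strata_comparison.tsv},
#' \code{class_summary.tsv} (per-target label counts),
#' \code{una_summary.tsv} (UNA-by-phylostratum counts) and
#' \code{manifest.yaml}.
#'
#' @param config a configuration list (see \code{\link{defaultRunConfig}})
#'   or the path to a YAML configuration file.
#' @param outdir output directory; overrides \code{config$outdir}.
#' @param seed overrides \code{config$seed}.
#' @return invisible list with the in-memory tables (\code{classes},
#'   \code{una_default}, \code{una_strict}, \code{comparison},
#'   \code{class_summary}, \code{una_summary}) and \code{outdir}.
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL) {
    cfg <- if (is.character(config)) readRunConfig(config)
           else validateRunConfig(utils::modifyList(defaultRunConfig(),
                                                    config))
    if (!is.null(outdir)) cfg$outdir <- outdir
    if (!is.null(seed)) cfg$seed <- seed
    if (is.null(cfg$focal) || is.null(cfg$tree) || !length(cfg$targets))
        stop("configuration must name a focal species, a tree and at ",
             "least one target")
    for (p in c(cfg$focal$genome, cfg$focal$gff, cfg$tree))
        if (!file.exists(p)) stop("input file not found: ", p)
    for (t in cfg$targets)
        for (p in c(t$genome, t$gff, t$synteny))
            if (!file.exists(p)) stop("input file not found: ", p)

    old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old_seed))
            assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(cfg$seed)

    focal <- .loadSpecies(cfg$focal$id, cfg$focal$genome, cfg$focal$gff)
    tree <- readSpeciesTree(cfg$tree, cfg$focal$id)
    targets <- list()
    for (t in cfg$targets) {
        if (!(t$id %in% tree@tree$tip.label))
            stop("target '", t$id, "' is not a leaf of the species tree")
        sp <- .loadSpecies(t$id, t$genome, t$gff)
        sp$synmap <- readSyntenyMap(t$synteny, focal = cfg$focal$id,
                                    target = t$id)
        targets[[t$id]] <- sp
    }
    queryIds <- if (is.null(cfg$queries))
        as.character(focal$models@genes$gene_id)
    else
        readLines(cfg$queries, warn = FALSE)

    if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)

    ## manifest first: a run is identifiable before any result lands
    inputs <- c(cfg$focal$genome, cfg$focal$gff, cfg$tree,
                unlist(lapply(cfg$targets,
                              function(t) c(t$genome, t$gff, t$synteny))))
    manifest <- list(
        config = cfg[setdiff(names(cfg), c("focal", "targets", "tree",
                                           "queries", "outdir"))],
        inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                         basename(inputs))),
        n_queries = length(queryIds),
        n_targets = length(targets),
        focal_invalid_models = nrow(focal$models@invalid))
    yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))

    classes <- classifyAll(focal$models, focal$assembly, focal$derived,
                           targets, cfg, queryIds = queryIds)
    una_def <- unaTable(classes, tree, "default")
    una_str <- unaTable(classes, tree, "strict")
    comparison <- compareModes(una_def, una_str)
    class_summary <- summarizeClasses(classes)
    una_summary <- summarizeUna(rbind(una_def, una_str))

    writeTsv(classes, file.path(cfg$outdir, "classes.tsv"))
    writeTsv(una_def, file.path(cfg$outdir, "una_default.tsv"))
    writeTsv(una_str, file.path(cfg$outdir, "una_strict.tsv"))
    writeTsv(comparison$per_gene,
             file.path(cfg$outdir, "strata_comparison.tsv"))
    writeTsv(class_summary, file.path(cfg$outdir, "class_summary.tsv"))
    writeTsv(una_summary, file.path(cfg$outdir, "una_summary.tsv"))

    invisible(list(classes = classes, una_default = una_def,
                   una_strict = una_str, comparison = comparison,
                   class_summary = class_summary,
                   una_summary = una_summary, outdir = cfg$outdir))
}
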