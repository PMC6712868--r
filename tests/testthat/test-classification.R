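evFlags <- function(...) {
    ev <- list(aa_gen = FALSE, aa_trn = FALSE, aa_orf = FALSE,
               nt_cds = FALSE, nt_exo = FALSE, nt_rna = FALSE,
               nt_dna = FALSE)
    utils::modifyList(ev, list(...))
}

diagRow <- function(...) {
    d <- data.frame(query_gene_id = "g", n_intervals = 1L,
                    total_length = 500L, length_ratio = 1.0,
                    contains_n_run = FALSE, oversize = FALSE,
                    at_edge = FALSE, scrambled = FALSE, unmapped = FALSE,
                    stringsAsFactors = FALSE)
    utils::modifyList(d, list(...))
}

test_that("first-affirmative evaluation follows the default node order", {
    ## an annotated-protein match wins regardless of other evidence
    expect_equal(classify(evFlags(aa_gen = TRUE, nt_cds = TRUE,
                                  nt_dna = TRUE),
                          diagRow(scrambled = TRUE)), "A_gen")
    expect_equal(classify(evFlags(aa_trn = TRUE, nt_dna = TRUE),
                          diagRow()), "A_trn")
    expect_equal(classify(evFlags(aa_orf = TRUE, nt_exo = TRUE),
                          diagRow()), "A_orf")
    ## nucleotide-only evidence, most to least genic
    expect_equal(classify(evFlags(nt_cds = TRUE, nt_dna = TRUE),
                          diagRow()), "N_cds")
    expect_equal(classify(evFlags(nt_dna = TRUE), diagRow()), "N_dna")
    ## unknowns: technical before biological, U_nm as fallback
    expect_equal(classify(evFlags(), diagRow(unmapped = TRUE)), "U_una")
    expect_equal(classify(evFlags(), diagRow(at_edge = TRUE,
                                             scrambled = TRUE)), "U_una")
    expect_equal(classify(evFlags(), diagRow(contains_n_run = TRUE,
                                             length_ratio = 0.1)), "U_nst")
    expect_equal(classify(evFlags(), diagRow(oversize = TRUE)), "U_tec")
    expect_equal(classify(evFlags(), diagRow(length_ratio = 0.1)), "U_ind")
    expect_equal(classify(evFlags(), diagRow(scrambled = TRUE)), "U_scr")
    expect_equal(classify(evFlags(), diagRow()), "U_nm")
})

test_that("classification is total and exclusive over random inputs", {
    set.seed(51)
    for (i in 1:200) {
        ev <- evFlags()
        for (k in names(ev)) ev[[k]] <- sample(c(TRUE, FALSE), 1)
        d <- diagRow(unmapped = sample(c(TRUE, FALSE), 1),
                     at_edge = sample(c(TRUE, FALSE), 1),
                     contains_n_run = sample(c(TRUE, FALSE), 1),
                     oversize = sample(c(TRUE, FALSE), 1),
                     scrambled = sample(c(TRUE, FALSE), 1),
                     length_ratio = stats::runif(1, 0, 2))
        lab <- classify(ev, d)
        expect_length(lab, 1L)
        expect_true(lab %in% HOMOLOGY_LABELS)
        ## priority: any earlier true predicate forbids later labels
        if (ev$aa_gen) expect_equal(lab, "A_gen")
        else if (ev$aa_trn) expect_equal(lab, "A_trn")
        else if (ev$aa_orf) expect_equal(lab, "A_orf")
        else if (ev$nt_cds) expect_equal(lab, "N_cds")
    }
})

test_that("the tree is user-configurable but must end in the fallback", {
    ## swapped N order: exon-level before CDS-level matches
    tree <- c("A_gen", "A_trn", "A_orf", "N_exo", "N_cds", "N_rna",
              "N_dna", "U_una", "U_nst", "U_tec", "U_ind", "U_scr", "U_nm")
    expect_equal(classify(evFlags(nt_cds = TRUE, nt_exo = TRUE),
                          diagRow(), tree = tree), "N_exo")
    expect_error(classify(evFlags(), diagRow(), tree = c("A_gen")),
                 "U_nm")
    expect_error(classify(evFlags(), diagRow(),
                          tree = c("A_gen", "X_bad", "U_nm")), "unknown")
})

test_that("homologyGroup maps labels to their groups", {
    expect_equal(unname(homologyGroup(c("A_gen", "N_dna", "U_scr"))),
                 c("AAic", "NTic", "Unknown"))
    expect_error(homologyGroup("Z_zz"))
})

test_that("an empty query list yields an empty table", {
    fx <- generateFixture(file.path(tempdir(), "fx-cls"), seed = 61,
                          nTargets = 1L)
    foc <- loadFixtureSpecies(fx$dir, "focal")
    tgt <- loadFixtureSpecies(fx$dir, "target1")
    tgt$synmap <- readSyntenyMap(file.path(fx$dir, "focal_vs_target1.tsv"),
                                 "focal", "target1")
    out <- classifyAll(foc$models, foc$assembly, foc$derived,
                       list(target1 = tgt), queryIds = character(0))
    expect_equal(nrow(out), 0L)

    ## missing target data is a hard error before classification
    expect_error(classifyAll(foc$models, foc$assembly, foc$derived,
                             list(target1 = tgt[c("assembly", "models")]),
                             queryIds = "g_no_match"),
                 "missing")
})

test_that("self-comparison classifies every annotated query as A_gen", {
    fx <- generateFixture(file.path(tempdir(), "fx-self"), seed = 62,
                          nTargets = 1L)
    foc <- loadFixtureSpecies(fx$dir, "focal")
    ## identity synteny map: every focal scaffold maps onto itself
    lens <- scaffoldLengths(foc$assembly)
    idm <- do.call(rbind, lapply(names(lens), function(nm)
        synRow(nm, 1, lens[[nm]], nm, 1, lens[[nm]])))
    self <- list(assembly = foc$assembly, models = foc$models,
                 derived = foc$derived,
                 synmap = readSyntenyMap(writeTempSynteny(idm),
                                         "focal", "focal"))
    set.seed(62)
    out <- classifyAll(foc$models, foc$assembly, foc$derived,
                       list(focal_copy = self))
    expect_equal(nrow(out), 9L)
    expect_true(all(out$label == "A_gen"))
})
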