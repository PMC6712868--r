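# synphylo

Synteny-based phylostratigraphy and fine-grained classification of young
genes, for comparative genomicists asking whether a lineage-specific gene
is a genuine *de novo* birth, a rapidly diverged ortholog, or an artifact
of an incomplete assembly or annotation.

Standard phylostratigraphy dates a gene by the oldest clade with a
detectable protein homolog and so rests on negative evidence: no hit may
mean "young gene" or just "bad data".  synphylo instead projects each
query gene of a focal species through a whole-genome synteny map onto each
target genome and searches only that syntenic interval.  Every query x
target pair receives one of thirteen homology classes in three groups:

* **AAic** — amino-acid-level homolog in the interval: to an annotated
  protein (`A_gen`), to a non-CDS ORF on an annotated mRNA (`A_trn`), or
  to an unannotated genomic ORF (`A_orf`);
* **NTic** — a nucleotide-level trace only, located against the target
  annotation (`N_cds`, `N_exo`, `N_rna`, `N_dna`) — positive evidence of a
  non-coding homolog, the de novo signature;
* **Unknown** — nothing found, with the inferred reason: scaffold
  edge/unmapped (`U_una`), assembly N gap (`U_nst`), interval too long to
  search (`U_tec`), interval much smaller than the query, i.e. an indel
  (`U_ind`), scrambled local synteny (`U_scr`), or a plain no-match
  (`U_nm`).

Per-target classes are then collapsed over a rooted species tree: for each
ancestor p_i of the focal species, the cousin set t_i becomes **A** if any
leaf is AAic, **N** if all leaves are NTic, and **U** otherwise.  The
resulting UNA vector s_0..s_K gives the synteny-based phylostratum: the
deepest ancestor with an A, or `focal_specific` (s_0 = N: supported de
novo orphan) / `unknown` (s_0 = U) when no A exists.  A *strict* mode
counts only `A_gen` as protein-level support, emulating annotation-based
phylostratigraphy restricted to syntenic genes.

Evidence comes from affine-gap Smith-Waterman alignment with
shuffled-sequence Gumbel significance (BH-adjusted, alpha = 0.05) plus an
identity-coverage requirement; see the vignette
(`vignettes/synteny-phylostratigraphy.Rmd`) for the model, the
search-interval contract, and every default.

## Worked example

synphylo ships a seeded generator of miniature genome bundles with planted
evolutionary scenarios, so the whole pipeline runs offline in seconds:

```r
library(synphylo)
fx  <- generateFixture("fx", seed = 42)   # focal + 2 targets + map + tree
res <- runPipeline(fx$config)

head(res$classes[, c("query_gene_id","target_species","label","group","length_ratio")], 8)
#>            query_gene_id target_species label   group length_ratio
#> 1  g_conserved_annotated        target1 A_gen    AAic    1.0000000
#> 2      g_utr_orf_homolog        target1 A_trn    AAic    1.5378788
#> 3 g_unannotated_ortholog        target1 A_orf    AAic    1.0000000
#> 4    g_de_novo_precursor        target1 N_dna    NTic    0.9848485
#> 5           g_indel_loss        target1 U_ind Unknown    0.0000000
#> 6     g_scrambled_region        target1 U_scr Unknown    6.0606061
#> 7   g_scaffold_truncated        target1 U_una Unknown    0.0000000
#> 8                g_n_gap        target1 U_nst Unknown    1.2525253
```

Each planted scenario lands in its intended class: the conserved ortholog
is `A_gen`; the frameshift-disrupted copy keeps ~98% of the locus at the
nucleotide level but no qualifying ORF, hence `N_dna`; the deleted locus
leaves an interval 0% the size of the query (`U_ind`); the truncated
scaffold gives `U_una`.  Collapsing over the tree:

```r
res$una_default[, c("query_gene_id", "una", "stratum")]
#>            query_gene_id una        stratum
#> 1  g_conserved_annotated  AA             p1
#> 2      g_utr_orf_homolog  AA             p1
#> 3 g_unannotated_ortholog  AA             p1
#> 4    g_de_novo_precursor  NN focal_specific
#> 5           g_indel_loss  UU        unknown
#> ...

res$comparison$summary
#>   stratum_default stratum_strict n_genes
#> 1  focal_specific focal_specific       1
#> 2              p1             p1       1
#> 3              p1        unknown       2
#> 4         unknown        unknown       5
```

`AA` at the root ancestor `p1` means both cousin sets carry protein-level
support; `NN` with no A is the supported de novo pattern.  The comparison
table shows the default/strict disagreement exactly where it should be:
the two genes whose only protein evidence is an unannotated ORF (`A_orf`)
or a UTR ORF (`A_trn`) are old under the default mode and `unknown` under
strict.

Real data use the same entry point with a YAML configuration naming the
focal/target FASTA + GFF3 files, one synteny map per target (8-column
block TSV: `qseqid qstart qend tseqid tstart tend score strand`, 1-based
inclusive), and a rooted Newick tree; `runPipeline("config.yaml")` writes
`classes.tsv`, `una_default.tsv`, `una_strict.tsv`,
`strata_comparison.tsv`, the two count summaries, and a manifest with the
config snapshot and input checksums.  A thin CLI wrapper lives at
`inst/scripts/synphylo.R` (`run` / `fixture` / `summarize`).

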