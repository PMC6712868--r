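---
title: "Synteny-based phylostratigraphy with synphylo"
author: "synphylo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-based phylostratigraphy with synphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synphylo)
```

## The problem

Standard phylostratigraphy dates a gene by the oldest clade in which a
protein-level homolog can be detected.  Its central weakness is that it
rests on negative evidence: failing to find an annotated homolog in a
relative may mean the gene is genuinely young, but it may equally mean the
relative's assembly is incomplete, its annotation missed the gene, or the
gene diverged beyond recognition.  For candidate *de novo* genes - genes
born from previously non-coding sequence - the decisive observation is
positive: the orthologous *locus* in a close relative exists and is
non-coding.  Finding that locus requires synteny.

synphylo classifies each query gene of a focal species against each target
genome by searching only the syntenically mapped portion of that genome,
then distinguishes three situations: an amino-acid-level homolog exists
(**AAic**), only a nucleotide-level trace exists (**NTic** - the de novo
signature), or nothing is found (**Unknown**), in which case the syntenic
context is mined for the probable reason.  Collapsing the per-target
classes over a rooted species tree yields a per-gene **UNA vector** and a
synteny-based phylostratum.

## Pipeline structure

**Stage 1 - input derivation.**  Genomes (FASTA), gene models (GFF3), a
pairwise focal-to-target synteny map per target (8-column block TSV from a
whole-genome aligner; synphylo consumes maps, it never computes them), and
a rooted Newick tree are validated and indexed.  From models and genomes we
derive spliced transcripts, CDS, proteins (terminal stop removed;
minus-strand models reverse-complemented before splicing), and open
reading frames on transcripts and genome intervals.  Models failing
structural checks - CDS length not a multiple of three, missing ATG,
internal stop, coordinates beyond the scaffold - are flagged and excluded
from protein search but retain their genomic footprint for overlap tests,
so invalid input stays visible instead of silently vanishing.

**Stage 2 - search intervals and evidence.**  Each query gene is projected
through the synteny map onto each target (next section), and the resulting
intervals are searched with affine-gap Smith-Waterman alignment: the query
protein against annotated target proteins overlapping the interval,
against non-CDS ORFs of those annotated mRNAs (for example a reading frame
in a 3' UTR), and against ORFs of the interval DNA that overlap no
annotated mRNA; then the query's full nucleotide sequence against the
interval DNA on both strands, with each nucleotide hit located against the
annotation as CDS, exon, intron or intergenic.  A first-affirmative
decision tree turns the evidence flags and interval diagnostics into one
of thirteen classes:

| group | classes | meaning |
|---|---|---|
| AAic | `A_gen`, `A_trn`, `A_orf` | protein match to an annotated gene / to a non-CDS ORF on an annotated mRNA / to an unannotated genomic ORF |
| NTic | `N_cds`, `N_exo`, `N_rna`, `N_dna` | nucleotide-only match overlapping a CDS / exon / intron / intergenic DNA |
| Unknown | `U_una`, `U_nst`, `U_tec`, `U_ind`, `U_scr`, `U_nm` | unmapped or at a scaffold edge / N gap in the interval / interval too long to search / interval much smaller than the query (indel) / scrambled anchors / no match |

Technical Unknown causes are tested before biological ones so that
assembly artifacts pre-empt biological inference; `U_nm` is the mandatory
fallback.  The node order is configurable (`decision_tree` in the run
configuration), reflecting that the tree is a policy, not a fact.

**Stage 3 - origins.**  For ancestors p_0..p_K of the focal species (parent
to root) and cousin sets t_0..t_K (leaves under p_i but not p_{i-1}), each
cousin set collapses to a single label under a single-birth model: **A** if
any leaf is AAic, **N** if all leaves are NTic, otherwise **U** (a mixed
N/U set stays U because the Unknown leaf *could* hide an AAic match - the
rule deliberately overstates uncertainty).  The phylostratum is the deepest
ancestor with an A; vectors with no A split on s_0: `focal_specific` when
s_0 = N (the nearest relatives carry non-coding homologs - the supported
de novo pattern) and `unknown` when s_0 = U.  *Default* mode counts every
AAic class as protein-level support; *strict* mode counts only `A_gen`,
emulating annotation-based phylostratigraphy restricted to syntenic genes.
Strict calls are therefore never deeper than default calls, a property the
test suite checks over randomized class tables.

## The search-interval contract

The upstream literature delegates interval inference to a dedicated
syntenic-search tool without fixing the algorithm, so synphylo defines a
self-contained, oracle-testable contract over contiguous anchors:

* **(a) overlap** - every block overlapping the query gene contributes the
  linear interpolation of the overlapped stretch, extended by the query
  overhangs; minus-strand blocks swap left and right target sides.
* **(b) gap** - for every inter-anchor gap the gene reaches into, if the
  two bracketing anchors lie on one target scaffold in consistent
  orientation, the target-side gap between them is emitted (possibly
  empty - a clean deletion); discordant anchors instead each project the
  gene beyond their gene-side edge and raise the scramble score.
* **(c) tail** - a gene extending beyond the outermost anchor projects
  from that anchor's target edge to the scaffold end, with the unanchored
  side's bounded flag cleared.
* **(d) unmapped** - a query scaffold with no blocks yields an explicit
  unmapped record (classified `U_una` downstream).

The rules are applied as a union rather than as exclusive cases: a gene
straddling a block edge keeps both its overlap projection and the gap it
reaches into.  This choice is what makes interval inference *monotone* -
enlarging a query gene can only grow its search space - which the suite
verifies on randomized layouts; exclusive per-case rules break monotonicity
exactly at the block-boundary transition.

The scramble score is the fraction of discordant adjacent anchor pairs
(different target scaffold, different strand, or target order contradicting
query order) within a window of `scramble_window` (default 5) anchors on
each side of the gene; `scramble_score > scramble_threshold` (default 0.5)
marks the context scrambled.

## Alignment significance

Raw Smith-Waterman scores (BLOSUM62, gap open 10 / extend 1 for amino
acids; +2/-3 with gap open 5 / extend 2 for nucleotides; a gap of length L
costs open + L x extend) are calibrated per length stratum against a
Gumbel (type-I extreme-value) null fitted by the method of moments to
`null_shuffles` (default 100) alignments of shuffled copies of the two
sequences.  p-values are Benjamini-Hochberg adjusted within each (query x
target species x evidence kind) group, and a hit is *significant* when the
adjusted p falls below `alpha` (default 0.05).  A degenerate null (zero
score variance, e.g. an all-N interval) forces p = 1: unalignable content
can never support homology.  Ambiguity codes, N in particular, score as
mismatches against everything, including themselves.

An evidence *flag* - what the decision tree actually consumes - requires
one further property: identity coverage, the fraction of query positions
matched identically in the local alignment, of at least
`min_query_coverage` (default 0.25).  The rationale is statistical: a
marginally significant local alignment between unrelated sequences occurs
at roughly the rate alpha per comparison, which would make a per-gene,
per-target label a coin flip at the 5% level; but random local alignments
cannot match a quarter of the query identically, because accumulating that
many identities drives the alignment score negative long before the
identity count is reached.  Any homolog with at least 25% identity across
the query - far into the twilight zone - still passes.  The hit table
itself keeps the pure significance call (`significant` is exactly
`p_adjusted < alpha`), so the calibration of the p-values remains
inspectable and is itself under test.

## The fixture generator

`generateFixture()` writes a complete miniature input bundle - focal
genome and GFF3, per-target genome/GFF3/synteny map, Newick tree, YAML
configuration - with one planted scenario per query gene, and a ground
truth table of expected labels, UNA vectors and strata.  The nine
scenarios map one-to-one onto the decision tree's distinguishable
outcomes: a conserved annotated ortholog (`A_gen`), homology moved into a
3' UTR ORF of an otherwise unrelated annotated gene (`A_trn`), an ortholog
whose annotation was dropped (`A_orf`), a frameshift-disrupted copy that
preserves nucleotide identity but no ORF of 30 or more codons (`N_dna`), a
clean whole-locus deletion between abutting anchors (`U_ind`), a locally
order-reversed anchor neighbourhood with the locus removed (`U_scr`), a
scaffold truncated before the locus (`U_una`), the locus replaced by a run
of Ns (`U_nst`), and the locus replaced by random sequence (`U_nm`).

Default dimensions: per scenario one focal scaffold of about 3.6 kb - four
400-nt anchor segments per flank around a 396-nt single-exon gene (131-aa
protein) - and two target species on a caterpillar tree, both receiving
the same edit for a given gene so the expected UNA vector is the
scenario's collapsed label repeated.  These sizes keep a full pipeline run
on one fixture around ten seconds while leaving the null model enough
sequence to fit; the per-site substitution rate for ortholog scenarios is
0.05, high enough to be realistic for congeneric comparisons and low
enough that planted homologies remain unambiguous.  Mutation is
substitution-only; all structural change (deletion, frameshift,
truncation, scrambling) is scenario-level, which is what keeps the
expected labels provable.  Gene strands alternate so reverse-complement
handling is exercised throughout.

Each scenario's defining property is asserted at generation time by
independent brute-force checks (a plain codon-loop ORF scan, gap
arithmetic), never by the pipeline under test.  For the de novo precursor,
substitution noise (2%) plus a 1-nt deletion every 60 nt usually destroys
all long ORFs, but chance ATG runs across the new frame joints survive
often enough to matter; the generator therefore breaks any surviving ORF
of 30 or more codons by planting a stop codon at a jittered in-frame
position and re-scans, erroring out if disruption fails.  A subtlety
motivates the jitter: a planted forward stop can overwrite a reverse-strand
stop (the complement of TAA reads TTA), so deterministic plant positions
can cycle between strands.

What the fixtures do *not* emulate: multi-exon target orthologs, codon
-model or rate-heterogeneous evolution, real indel processes inside
conserved loci, transposition, segmental duplication, or annotation noise.
A green suite therefore demonstrates that the classification machinery is
correct under its own model assumptions, not that those assumptions
describe any particular genome pair.

## Numerical and policy choices

* **Coordinates** are 1-based closed (`IRanges`) everywhere inside the
  package; GFF3 and the synteny TSV load without conversion, and only the
  BED exporter converts (to BED's 0-based half-open).  An empty target
  interval - a clean deletion - is encoded as `tend == tstart - 1`.
* **ORF definition**: ATG-initiated, stop-terminated, longest-per-stop
  (nested ATGs sharing a stop do not spawn extra ORFs), at least
  `min_orf_codons` (default 30) amino acids, stop codon excluded from the
  interval and the translation; codons containing ambiguity characters are
  never starts or stops.  A stop-to-stop mode is available
  (`orf_require_atg: false`) since conventions differ across tools.
  Genomic ORFs are single-exon by construction.
* **Representative query protein**: the longest valid CDS among a gene's
  transcripts; target-side, all transcripts' proteins are searched.  This
  keeps one query per gene while maximizing target-side sensitivity.
* **Nucleotide hit location**: the hit's target-side footprint is
  classified per base with priority CDS > exon > intron > intergenic and
  then by majority, ties toward the more genic category.
* **Unknown-cause order** (`U_una`, `U_nst`, `U_tec` before `U_ind`,
  `U_scr`): a scaffold edge, an N gap or a skipped oversize interval makes
  any biological reading of the same interval unsafe.
* **Missing leaves** (species in the tree without data) enter the collapse
  as Unknown, never silently dropped.
* **No-A UNA vectors** split on s_0 only: N at s_0 is positive non-coding
  evidence in the closest relatives (`focal_specific`); U at s_0 leaves
  the origin `unknown`.  Deeper N values with s_0 = U do not promote the
  call, which errs toward uncertainty; the output records the mode and the
  full vector so users can re-cut this boundary.
* **Thresholds** `indel_ratio = 0.25` (interval/query length below which an
  indel is inferred), `n_run_min = 10` nt, `max_interval_nt = 1e6` are
  explicit defaults echoed into every run manifest; the qualitative terms
  they operationalize ("much smaller", "a string of Ns", "too long to
  search") have no canonical values.
* **Determinism**: the configuration seed drives all randomness (null
  shuffles, fixture generation); reruns with identical configuration and
  seed reproduce every output table byte for byte, and the manifest
  (config snapshot plus input checksums) is written before any result.

## Problem sizes under test

The suite checks planted-scenario recovery on fixtures for twenty seeds
(360 query-target pairs), the aligner against an independent O(nm) Gotoh
oracle on 400 random short pairs, the ORF finder against a naive six-frame
scan on fifty 10-kb sequences, subtree collapse exhaustively for all label
multisets up to size four, significance calibration on 500 shuffled-null
alignments, interval inference against a per-base mapping oracle on
randomized layouts, strict-mode dominance and monotone degradation on a
thousand random class tables, and byte-level determinism of end-to-end
reruns.  `scripts/acceptance.R` recomputes the headline quantities from
scratch against the installed package.

## Known limitations

Search intervals come from a deliberately simple contiguous-anchor
contract, not from a full syntenic-search tool; duplicated or k-best
interval semantics are out of scope.  Smith-Waterman is exact but
quadratic, so very long intervals are skipped (surfacing as `U_tec`)
rather than searched heuristically.  Translated (frameshift-aware)
alignment is not implemented, which makes the NTic/AAic boundary sharp
under frameshift: a single-frame disruption with conserved amino-acid
stretches shorter than the ORF cutoff reads as NTic.  Only the standard
genetic code is supported.  The strict/default comparison consumes an
externally supplied standard-phylostratigraphy table when one is given; it
never computes one.
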