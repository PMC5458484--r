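---
title: "Screening putative lncRNAs: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening putative lncRNAs: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscreenr)
library(dplyr)
```

## The screening problem

Long non-coding RNAs (lncRNAs) are transcripts of at least 200 nt with no
protein-coding capacity.  Deep RNA-seq assemblies contain hundreds of
thousands of transfrags, most of which are fragments of known genes,
alternative starts of coding genes, or small RNAs.  `lncscreenr` implements
a two-phase computational screen over such an assembly:

* **Phase I — filtration.**  Each assembled transfrag is classified against
  a reference annotation by its structural relation (intron-chain match
  `=`, shared splice junction `j`, same-strand exonic overlap `o`,
  antisense overlap `x`, intronic `i`, intergenic `u`).  Only categories
  that cannot be fragments of annotated same-strand genes are kept
  (default `i`, `u`, `x`).  Annotated lncRNAs from the reference are added
  back, transcripts are merged into gene loci by their merger-assigned
  gene id, and loci are removed if they (a) touch an extended transcription
  start site (TSS) of any protein-coding transcript on the same strand,
  (b) overlap annotated small RNAs (miRNA, snRNA, srpRNA, tRNA, scRNA,
  antigen-receptor loci) exonically on the same strand, or (c) fall below
  the 200 nt lncRNA length definition.  A coding-probability gate (an
  externally computed CPAT-style score) then removes likely coding loci.
* **Phase II — classification.**  Gene-level FPKM is computed from raw
  counts; per group, samples below an FPKM cutoff are excluded before
  averaging.  Histone-mark peaks are assigned to each locus's extended TSS
  region, and group-enriched **lncRNAs** (expressed + H3K4me3) and
  **enhancer-RNAs** (expressed + H3K4me1 + H3K27ac, no H3K4me3) are
  called per group.  Results are summarised as a pie matrix (per-group
  mark-category counts and pairwise group overlaps), a supervised ordering
  for heatmaps, and a comprehensive per-lncRNA feature report with
  optional segment (CNV/SNP), differential-expression and Hi-C
  annotations.

Every step feeds a filtration ledger (step, counting unit, input,
retained, excluded/added), so the impact of each criterion is auditable.

## Coordinates and overlap semantics

All internal coordinates are 0-based half-open; GTF (1-based closed) is
converted at the boundary and BED-family formats pass through unchanged.
One convention internally eliminates a whole class of off-by-one bugs, and
every boundary case is pinned by tests (touching intervals do not overlap;
a 199 nt locus is excluded while a 200 nt locus survives).

"Overlap" means at least one shared base unless stated otherwise — the
screen is deliberately conservative, since a single shared base with a
protein-coding TSS window is already grounds for suspicion.  Strandedness
matters wherever biology dictates: TSS exclusion, small-RNA exclusion and
annotation-source labels are same-strand; histone-mark peaks, CNV/SNP
segments, TAD intervals and Hi-C anchors are unstranded and match both
strands.

The TSS is a single base (leftmost on `+`, rightmost on `-`); the extended
region covers `2 * flank + 1` bases, including the TSS base itself, and is
clamped at coordinate 0.  This is the simplest faithful reading of "extend
by 1.5 kb upstream and downstream".

## Class codes

The classifier assigns exactly one code by fixed precedence
(`=`, `j`, `o`, `x`, `i`, `u`):

1. `=` — identical intron chain with a same-strand reference transcript
   (single-exon transfrags match by exonic overlap with a single-exon
   same-strand reference transcript);
2. `j` — at least one intron shared exactly (donor and acceptor) with a
   same-strand reference transcript;
3. `o` — same-strand exonic overlap;
4. `x` — antisense exonic overlap, or an intron overlapping a reference
   intron on the opposite strand;
5. `i` — the full genomic span inside a single reference intron (either
   strand: an intronic transfrag is suspicious regardless of orientation);
6. `u` — intergenic.

Only the codes the downstream filter consumes are distinguished; the finer
categories of transfrag-comparison tools collapse into the nearest of
these, which provably cannot change what the `i`/`u`/`x` filter keeps.
Same-strand evidence is ranked above antisense evidence where both exist;
this tie-break is a declared convention of this implementation.  The
classifier is validated against a brute-force base-level oracle on
thousands of random geometries, and planted fixtures confirm 100% recovery
of each constructed code.

## Quantification

FPKM(g, s) = counts(g, s) x 1e9 / (length(g) x library(s)).  Gene length
is the spliced exon-union length of the merged locus, matching gene-level
counting; the library size defaults to the column sum of the supplied
count table, which should span the putative assembly and the reference
annotation together.  Group means are **cutoff-aware**: samples at or
below the FPKM cutoff are excluded before averaging ("above" is strict
`>`, so a tie at the cutoff is excluded — the natural reading of
"below the cutoff are excluded" applied to the boundary), and a gene with
no sample above the cutoff reports mean 0 with `n_above = 0` rather than
`NA`, keeping the report rectangular.  The mean divides by the number of
retained samples, the literal reading of excluding samples *before*
computing the average.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `keep_codes` | `i, u, x` | transfrag classes retained by the class filter |
| `tss_flank` | 1500 nt | extension of protein-coding and lncRNA TSSs |
| `min_length` | 200 nt | lncRNA length definition (spliced, gene level) |
| `fpkm_cutoff` | 0.5 FPKM | expression cutoff for group means and calls |
| `coding_cutoff` | 0.364 | coding-probability exclusion boundary (published optimum for human); `>= cutoff` is excluded |
| `min_fold` | 0 | fold-enrichment floor for peak assignment |

The lncRNA rule (H3K4me3 required) and eRNA rule (H3K4me1 + H3K27ac
required, H3K4me3 forbidden) are configurable via `group_call_rules()`;
rule pairs that could hold simultaneously are rejected at construction, so
the two calls are disjoint by design.  The eRNA expression cutoff defaults
to the lncRNA cutoff but is separately configurable.

## Design choices where the design was open

* **The 200 nt filter applies to the merged gene locus** (exon-union
  length), because filtration operates on the gene-level merge; a
  transcript-level reading would re-admit fragments of multi-isoform loci.
  Users who need the transcript-level reading can filter before merging.
* **TSS exclusion uses every protein-coding transcript**, not one TSS per
  gene, to capture alternative starts.
* **Add-back happens before the gene-level merge**, so annotated lncRNAs
  merge under their own gene ids and pass through the same exclusions.
* **Small-RNA exclusion is exonic, not span-based**: an intron-hosted
  miRNA on the same strand does not disqualify its host locus, consistent
  with every other exon-based overlap in the screen.
* **Coding gate at gene level**: when probabilities are supplied per
  transcript, a gene is gated on the maximum member-transcript
  probability (the conservative aggregation).  Genes without a supplied
  probability are retained with a flag rather than silently dropped.
* **ORF convention**: the longest ATG-to-stop span over the three forward
  frames of the oriented spliced sequence, stop codon included; ORFs with
  no in-sequence stop are ignored.  The coding decision itself always
  comes from the supplied probability, never from the ORF length.
* **"Same TAD"** means the lncRNA and the mRNA each overlap (>= 1 base)
  one common TAD interval; a boundary-straddling gene may qualify through
  either of its TADs.  Hi-C anchors match locus spans, not exons, because
  interaction bins are far coarser than exon structure.  No minimum
  interaction score is imposed; scores are carried into the report for the
  user to threshold.
* **Pie-matrix off-diagonal cells** count genes called in both groups of a
  pair *in the same mark category* (totals are reported alongside); this
  makes the matrix symmetric and makes the self-overlap equal the
  diagonal, which the tests assert as invariants.
* **Supervised ordering** within a group is by descending group mean FPKM
  with ties broken by gene id — a deterministic convention where only
  "the order discovered in each group" is prescribed.
* **Ledger units**: the gene-level merge changes the counting unit from
  transcripts to loci, so the ledger carries a `unit` column; conservation
  (input = retained + excluded) and chaining are enforced within each
  unit, and the merge and add-back rows are the two documented exemptions.

## The synthetic fixture generator

`generate_fixtures()` is first-class, tested code: it plants a toy genome,
reference annotation, assembly, counts, peaks, small-RNA sets, annotation
sources, coding probabilities, CNV/SNP segments and TAD-constrained Hi-C
pairs with a known fate for every gene, and emits truth tables that the
test suite uses as its oracle.  The defaults describe a small multi-group
study: 4 groups x 3 samples, 140 background protein-coding genes, 28
novel planted survivors with classes cycled over `u`/`i`/`x`, 8 annotated
lncRNA add-backs, and decoys for every exclusion reason (class-filter
decoys `=`/`j`/`o`; a 199 nt short decoy; a same-strand TSS-window decoy;
a tRNA-overlapping decoy; a coding-probability decoy at 0.9) — roughly
210 genes in total.  Expression is planted by computing the exact raw
count that yields FPKM 10 at a fixed 1e6-read library — twenty times the
call cutoff, so no call is ever decided at a boundary — and every file is
byte-reproducible from the seed.

What the fixtures deliberately do **not** emulate: read-level noise,
ambiguous class geometries (each planted transfrag satisfies exactly one
survival or exclusion path by construction), biological sequence
composition, and overlapping gene models on the same strand.  Passing the
planted-truth tests therefore demonstrates that the *logic* of the cascade
is exact, not that the screen is robust to assembler artifacts — on real
data the class filter inherits whatever fragmentation the assembler
produces.

Test problem sizes are chosen to keep the full suite comfortably
reproducible on a laptop: ~1,000 random classifier instances, >10,000
interval-algebra cases, 1,000 random ORF sequences up to 2 kb, and 100
randomized fixture sweeps for the ledger invariants.

## Known limitations

* Coding probabilities are consumed, not computed; without them the gate
  is a no-op (flagged per gene).
* DESeq2-style differential expression, peak calling, Hi-C matrix
  processing and genome-browser snapshot rendering are out of scope; their
  outputs are consumed as tables.
* Unstranded assemblies cannot be classified: class codes and TSS logic
  require strand.
* The HTML report is a static sortable table; the TSV is the canonical
  artifact.
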