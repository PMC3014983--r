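---
title: "Post-assembly methods: graph clustering, selection screens and sex-specific calling"
author: "ContigGraphKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-assembly methods: graph clustering, selection screens and sex-specific calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ContigGraphKit)
```

# The problem

Pooled, normalized cDNA libraries from a non-model organism, pyrosequenced
as one female and one male pool and assembled *de novo*, leave three
post-assembly questions that no single standard tool answers:

1. **Which contigs belong together?** Divergent alleles, duplicated genes
   and alternatively spliced isoforms all fragment into separate contigs
   because reads from variable regions misalign. An assembler that splits
   reads at variation boundaries leaves a usable trace: each split read
   ties two contigs together.
2. **Which genes look like they are under diversifying selection?**
   Per-contig transition/transversion and nonsynonymous/synonymous
   polymorphism counts, variant density and their intersection form a
   cheap, assembly-scale screen.
3. **Which genes are present in only one sex's transcriptome?** With
   normalized libraries the signal is presence/absence of sex-of-origin
   read classes, not expression level.

ContigGraphKit implements the three analyses plus the homology-side
utilities they need (homology clustering, unique-homologue counting,
chimera detection, singleton rescue), and a synthetic-data generator that
emulates the assembler's outputs with a full ground-truth ledger so every
stage is testable without any external data.

# The contig graph and its components

Contigs are nodes; an edge joins two contigs when at least one read was
split between them (`buildGraph()`, weight = number of supporting split
reads, `minEdgeSupport` default 1 — the evidence the assembler gives is a
single split read, but the threshold is exposed because one read is weak
evidence under noise). Connected components of this graph are
*graph-clusters* (`findClusters()`).

Within a cluster, relationships between contigs are decided by sequence
identity bands over a semi-global *overlap alignment* (match +1, mismatch
-1, gap -2, end gaps free; identity = matches / aligned columns, gap
columns counted in the denominator; pairs whose best alignment spans fewer
than `minOverlap = 40` columns have *undefined* identity):

* identity >= 0.95 — divergent **alleles** of one gene,
* 0.80 <= identity < 0.95 — the diverged regions of a **duplicated** gene
  pair,
* lower or undefined — an alternative-**splicing** relationship (distinct
  exons).

Both thresholds are closed on the left: an identity of exactly 0.95 is an
allele, exactly 0.80 a duplicate. Real-valued identity lands on a boundary
with probability zero; fixing the convention makes runs reproducible.

One design point deserves emphasis. The two allele contigs of a gene are
usually *not* joined by a split read — no read overlaps both alleles;
each allele contig is instead linked to the gene's shared contig. Allele
and duplicate relations are therefore evaluated over **all unordered
contig pairs within a cluster**, not only along split-read edges; the
split-read edges that remain after those relations are set aside are the
splice structure. (In network drawings of such clusters these are the
dotted homology links versus the solid split-read edges.)

`mergeAlleles()` contracts every connected subgraph of allele-band pairs
into one super-node. The consensus is built progressively in lexicographic
id order; at each aligned column agreement is kept, a two-row disagreement
is a tie and becomes the IUPAC ambiguity code of the union (preserving
information and keeping the operation deterministic), and gap columns keep
the present base so the consensus spans the union. Labelling and
contraction are iterated with the consensus sequences until no allele pair
remains. `callComponents()` then emits one `duplicate_pair` component per
duplicate-band pair and one `alt_splice` component per residual connected
splice subgraph of two or more nodes; a splice component that shares a
node with a duplicate pair is flagged `unresolved`.

Note what this decomposition implies for counting: a cluster built from
one allele pair plus its shared contig yields a `merged_alleles` component
*and* a residual splice component (the shared contig linked to the merged
super-node). Component counts are therefore not gene counts; the
ground-truth comparison in `evaluateRecovery()` scores whether each
*expected* component (the allele pair, the duplicate pair, the exon set)
is recovered with the right type and exact member set.

`blastCategory()` summarizes each component's homology pattern into the
five-way scheme (none / some-different / some-same / all-different /
all-same subject) against one database at one e-value cut-off.

# Variant statistics

`filterVariants()` keeps a call iff coverage is in `[5, 100]` and
probability >= 0.9 — all boundaries inclusive, following the strict
inequalities of the filtering rule it implements — and additionally drops
any insertion/deletion inside or immediately adjacent to a homopolymer
run. "Homopolymer" means a run of >= 3 identical bases (`homopolymerLen`,
configurable): 3 is the conventional trouble threshold for pyrosequencing
indel artefacts; "adjacent" means the run intersects `[pos - 1, pos + 1]`.
The filter is idempotent.

Per contig, `summarizeContigs()` reports transitions (A<->G, C<->T) and
transversions with the smoothed ratio `(TS + 1) / (TV + 1)`, and — for
contigs with a predicted ORF — nonsynonymous and synonymous SNP counts
with `(Ka + 1) / (Ks + 1)`. These are raw polymorphism counts with +1
smoothing, not per-site rates and not a codon-model dN/dS; the +1 keeps
ratios defined when either count is zero. When several ORFs exist only the
longest is used. A SNP whose codon carries a second SNP is evaluated
one-at-a-time against the reference codon: the data model has no haplotype
phase, so joint evaluation would be invented information. Stops count as
amino-acid states.

`flagHighlyVariable()` flags contigs at or above the 0.99 nearest-rank
quantile of variants-per-bp, computed over contigs with at least one
variant. The rank used is `min(n, floor(q * n) + 1)`: with 100 distinct
densities exactly the maximum is flagged, and exact ties at the threshold
are all flagged. `selectionCandidates()` intersects the three screens
(Ka/Ks > 1, TS/TV < 1, highly variable). `regressVariantsOnLength()` is an
ordinary least-squares fit of variant count on contig length over contigs
with variants (degenerate input — all lengths equal — is an error, not a
silent NaN).

`findLongestOrf()` scans all six frames for complete ATG...stop spans (the
stop codon counts toward the length) of at least 30 bp; ties prefer the +
strand, then the lowest frame index, then the smallest start.

# Sex classification and sex-specific genes

`classifySequences()` assigns each contig FC (all reads female), MC (all
male) or BC (both); a split read contributes its sex to both linked
contigs; singletons carry their read's sex.

`callSexSpecific()` works per subject accession in one reference database.
A gene is *female-specific* iff some female sequence (FC contig or F
singleton) hits it at `evalue <= 1e-50` **and** no male or both-sexes
sequence hits it at `evalue <= 1e-5`; symmetrically for male. The two
cut-offs implement the conservative reading of "no homology down the
e-value ladder": the focal evidence must be strong, the disqualifying
evidence may be weak. Both are exposed (`strictCutoff`, `screenCutoff`).
BC contigs contain reads of both sexes, so any BC hit disqualifies
specificity and makes the gene `shared`. Genes whose evidence clears
neither rule are `insufficient` rather than silently dropped.

Enrichment between the female- and male-specific sets uses one Fisher
exact test per GO term present in either set, two-sided by the
point-probability rule (all tables with fixed margins whose point
probability does not exceed the observed one, within relative tolerance
1e-12, are summed), with Benjamini-Hochberg correction across terms.
Two-sided is the default because the comparison is symmetric in the two
sets; a one-sided variant is available by flag.

# Homology utilities

`clusterByHomolog()` groups sequences by shared subject accession at a
cut-off; sequences join every cluster they hit and multi-membership is
reported separately. `uniqueHomologCounts()` counts distinct accessions
per database over the ladder 1e-5 / 1e-10 / 1e-20 / 1e-50.
`presenceVenn()` computes per-sequence database presence sets.

`detectChimeras()` formalizes the visual signature of a misjoined contig:
two hits with `evalue < 1e-20` to different subjects whose query intervals
overlap by at most 20% of the shorter interval and whose midpoints fall in
opposite halves of the query. Both knobs are flags; a subject-pair
whitelist suppresses known co-transcribed neighbours (the mitochondrial
case) instead of a manual exception.

`mapSingletons()` rescues singletons that align to a contig at >= 95%
identity (gap columns count against identity) with fewer than 10 bases
unaligned at each end, via a local alignment under the same scoring as the
overlap aligner. Candidate contigs are pre-screened by exact shared
16-mers, so unrelated pairs are never aligned; a singleton placed entirely
within one contig always shares such a seed far below the 95% identity
floor, so the screen does not cost recall at the thresholds used.

# The synthetic-data generator

`simulateStudy()` emulates what the assembler hands downstream, not the
sequencer. Gene categories: unique genes (one segment), allele pairs
(shared segment + two divergent copies of a variable segment), duplicate
pairs (shared segment + two paralogous diverged regions), alternatively
spliced genes (codon-aligned exons, isoform paths sharing at least one
exon), and chimera-source genes whose halves form planted chimera contigs.

Emulation rules: segment copies at identity >= `assemblerMergeIdentity`
(default 0.97) collapse into one contig and their differences surface as
SNP calls; copies below it become separate contigs; a read spanning a
segment boundary is split into two placements. The merge default sits
strictly above the 0.95 allele band so that alleles diverged 3-4.5% yield
*unmerged* contig pairs the classifier must re-merge — the non-trivial
test band — while a configurable fraction of allele pairs
(`alleleMergedFrac`) is drawn nearly identical and collapses at assembly,
exercising the variant path instead. A pair whose realized identity lands
exactly on the merge threshold collapses (closed boundary, same convention
as the classification bands).

Defaults describe the study conditions the package is tested under, chosen
once: 200 genes (140 unique / 20 allele-pair / 10 duplicate-pair / 20
alt-splice / 10 chimera-source), 10 female-only and 10 male-only genes,
segment lengths 300-600 bp (codon multiples), reads 250 +/- 30 bp at 100
reads per gene (about 20,000 reads per run — a size chosen so the full
pipeline and its repeated-run determinism check stay light), 41% of
unbiased reads female (the sex ratio of the motivating study's read
totals), 7.5% singletons and 5.7% discarded reads (ditto), true SNPs at
0.003/bp with transition:transversion odds 2:1, variant probabilities
Beta(20, 1) for true calls and Beta(2, 2) for injected false calls (placing
most true calls above the 0.9 filter and most false ones below), half of
the false calls homopolymer-adjacent INDELs, and 30% of genes with no
homologue in any database (quickly evolving or taxon-specific genes).

`mutateSequence()` plants **exactly** `round(divergence * L)` substituted
sites rather than sampling per-site: realized identity then sits inside
the requested band instead of blurring across the 0.80/0.95 thresholds
with binomial noise, which keeps the classification bands meaningful as
test conditions. Transitions are drawn with odds `tsTvWeight : 1`.

Segment sequences are complete reading frames (ATG-opened, stop-closed,
stop-free in between, lengths codon multiples), so every contig carries a
predictable ORF and the Ka/Ks stage is exercised end-to-end; exon codon
alignment keeps isoform skipping in frame.

What the generator does **not** emulate — and hence what green tests do
not show about real data: no per-base sequencing error or homopolymer
miscalls on reads (noise enters only via injected false variant calls and
the singleton/discard rates); no quantitative expression levels
(normalized libraries are presence/absence by design, and an optional
`leakageRate` exists only as a robustness knob); no partial homology,
domain sharing or database misannotation in the simulated hits; one split
per spanning read (reads never exceed the shortest segment, so a read
crosses at most one boundary — an idealization of the assembler's
behaviour); strand is always `+`. Recovery results on this generator
bound what the algorithms can do under clean evidence; they do not
calibrate error rates for real 454 assemblies.

# Numerical and reporting choices

* Alignment traceback tie order is fixed (diagonal, then gap-in-second,
  then gap-in-first; end ties to the smallest coordinates), and
  `overlapIdentity()` canonicalizes argument order, so identity is exactly
  symmetric.
* Fisher's test sums hypergeometric point probabilities computed by
  `dhyper`; the `1 + 1e-12` relative tolerance guards against ties lost to
  floating point.
* Coordinates are 1-based inclusive in the read-status, variant and blast
  tables (alignment-tool convention) and 0-based half-open in ORF records
  (BED convention); every written file states its convention in a header
  comment.
* The run report is serialized to JSON without wall-clock timings (those
  go to the text log), so repeated runs with one seed are byte-identical —
  determinism is a tested property, and timestamps would break it.
* Degenerate inputs error loudly: contigs with no placed reads cannot be
  sex-classified, an all-zero Fisher table has no test, a regression on
  equal lengths has no slope.

# Problem sizes used by the tests

The test suite simulates studies of 20-500 genes: oracle-equivalence
checks run on 200 random sequence pairs up to 60 bp, 500 random 2x2
tables, and a 500-node random graph; component recovery uses 60 allele
pairs (identity 0.955-0.97), 40 duplicate pairs (0.82-0.93) and 60
alternatively spliced genes; sex recovery uses 10 + 10 sex-restricted
genes among 180 shared ones with subsampling at 50/25/10%; chimera
recovery plants 20 chimeras among 500 contigs; the determinism check runs
the default 200-gene, ~20k-read pipeline twice. These sizes are the
package's chosen test conditions; all complete in well under two minutes
each on one CPU.

# Known limitations

* Isoform structure is reported as components and edge lists, not as
  enumerated transcript paths: the split-read graph constrains but does
  not determine the set of expressed isoforms, and enumerating paths would
  overstate what the evidence supports.
* Duplicate pairs are called from identity-band pairs without a
  reciprocal-best requirement; in dense paralog families one contig can
  participate in several pairs (such components are flagged).
* The sex-specific screen is per accession in one database; a gene whose
  opposite-sex evidence hits a *different* accession of the same gene
  family is not disqualified. Screening at the family level would need
  grouped accessions as input.
* Ka/Ks on raw counts with +1 smoothing is a screen, not an estimator: it
  is biased toward 1 for contigs with few coding SNPs and is not
  comparable across very different ORF lengths.
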