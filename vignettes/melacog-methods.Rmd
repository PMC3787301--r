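---
title: "Methods: ortholog clustering, taxonomic voting and genome assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog clustering, taxonomic voting and genome assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the models and procedures the package implements,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely open.

## The comparative setting

The package targets the situation where a few (canonically four) closely
related genomes have been reconstructed from metagenomes and must be
characterized without cultivation: which genes form one-per-genome
orthologous clusters, which phylum each cluster most resembles, what
functions the clusters carry, how complete each genome bin is, and where
the organisms occur in 16S rRNA surveys.

## Similarity search

All comparisons run through a bundled Smith–Waterman aligner (C++ core)
with affine gaps: a gap of length $L$ costs $o + Le$ with the standard
protein defaults $o = 11$, $e = 1$ over BLOSUM62. Raw scores $S$ are
converted with the Karlin–Altschul gapped parameters for that matrix and
penalty combination, $\lambda = 0.267$ and $K = 0.041$:

$$\text{bits} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = K\,m\,n\,e^{-\lambda S},$$

where $m$ is the query length and $n$ the summed length of the subject set
of the call. These constants are the conventional uncorrected values — no
edge-effect or composition-based correction is applied — so e-values are on
the familiar scale but not identical to a production search engine's.
Both are overridable through `scoring_scheme()`.

Alignment length counts gapped columns, so percent identity is computed
over the gapped length; this keeps the product
$\text{length} \times \text{pident}/100$ equal to the number of identical
columns, the quantity the voting rule consumes, and matches the convention
of imported 12-column hit tables.

Traceback ties are broken in fixed operator order (diagonal, then up, then
left) for determinism. Search output is sorted by bitscore, then e-value,
then subject id. There is no heuristic seeding: every pair is aligned
exactly, which is practical at the package's intended scale (hundreds of
proteins per genome) and is why hit tables from external engines can be
substituted for large inputs.

## Ortholog clustering

For each ordered genome pair, each query's best hit is its top-bitscore
hit (ties: lower e-value, then lexicographic subject id). An edge joins
$a$ and $b$ when each is the other's best hit; the edge carries the mean of
the two supporting bitscores. Within the resulting graph, every
one-per-genome subset of size $G$ is a candidate cluster, and is valid when
at least two members have induced degree $G-1$ and all members have degree
at least $G-2$. For $G = 4$ this is exactly: two members connected to all
three others, the rest connected to at least two.

Candidates can overlap (a component may admit several valid quads sharing
members). The package resolves conflicts greedily — most induced edges
first, then highest summed edge bitscore, then lexicographic member ids —
and enforces disjoint clusters. Disjointness is an assumption, not a
theorem: nothing in the connectivity rule itself forbids a protein from
sitting in two quads, but one-protein-one-cluster is the natural reading of
a partitioned COG table and makes downstream counts well defined.

Self-comparisons are never computed, and the degree rule generalizes to
$G \neq 4$ genomes as stated above (it reduces to the quoted rule at
$G = 4$).

## Taxonomic voting

Per gene: hits with $E \le 10^{-5}$ are ranked by bitscore; with none the
gene is "No hit"; with one, that hit's phylum (a single unambiguous hit is
treated as stronger evidence than none, although only the two-hit
comparison is defined by the margin rule). With two or more, the top two
are compared by identical positions
$IP = \text{length} \times \text{pident}/100$: the top hit wins iff
$IP_1 \ge 1.05 \, IP_2$. The boundary is inclusive — exactly 5% more is a
win. Otherwise "Multiple"; optionally (`collapse_same_phylum`, default
off) two non-separable top hits from the same phylum yield that phylum.

Per cluster: all members "No hit" → "No hit"; at least
`multiple_threshold` (default 2) members "Multiple" → "Multiple";
otherwise plurality over phylum labels, ties → "Multiple". The threshold
default of 2 is the minimal reading of "several" votes out of four, and is
exposed as a parameter precisely because it is an interpretation.

Raising the margin is monotone: it can only move genes from a phylum call
toward "Multiple", never the reverse. This is verified property-style in
the tests.

## KEGG categories

The cluster representative is the member from the first genome in the
configured order. Its best surviving hit's KO is mapped through the KO →
pathway → category tables: no pathway → "Undecided"; pathways from more
than one category → "Multiple"; otherwise the common category; no hit at
all → "unknown". In summaries, "no functional assignment" aggregates
"unknown" and "Undecided" (they are also reported separately, since the
aggregate is a presentation convention, not a semantic identity).

## Genome assessment

The bundled marker set is the 16 ribosomal proteins rpL2, 3, 4, 5, 6, 14,
15, 16, 18, 22, 24 and rpS3, 8, 10, 17, 19. Curated representative
sequences cannot be shipped, so the default representatives are
deterministic synthetic sequences (`synthetic_marker_set()`, fixed internal
seed) — the same sequences the simulator plants — and real analyses should
supply a curated FASTA. Detection is similarity-based: each proteome
protein is assigned to the marker of its best hit (E ≤ 10⁻⁵), each protein
counted at most once, so the inventory is a copy-number vector.

Grading: *Complete* requires every marker present and linkage established
between all scaffolds; *Near Complete* requires every marker and "almost
all" scaffolds linked, quantified as largest-linkage-component fraction
≥ 0.9 (no published number exists for "almost all"; the knob is
`near_complete_linkage`); anything else is *Partial*. N50 is the largest
scaffold length $L$ such that scaffolds of length ≥ $L$ cover half the
assembly; %GC is computed over unambiguous A/C/G/T only.

## Marker scans

The RnpB locus is found by exact search for GAGGAAAGTCC (U ≡ T) on both
strands, coordinates always reported on the forward strand, with a
±500 nt flank for inspection of the intergenic region. A one-mismatch
option exists but defaults off: the motif is described as highly conserved,
and exact search keeps the false-positive model trivial (a chance 11-mer
occurs once per ~2 Mb per strand).

The TLR5 region is extracted from a global alignment of a flagellin to a
reference flagellin (BLOSUM62, 11/1): the query columns aligned to
reference residues 88–103 are returned, flagged `gapped` when any
reference position in the span aligns to a gap. No recognized/unrecognized
call is computed — that judgment was always a visual one, and inventing a
classifier for it would overstate what the method can do. Display ordering
of regions uses average-linkage clustering on pairwise region identity
(itself a stand-in for an unspecified "organized by similarity"), made
input-order-invariant by sorting ids first.

## 16S survey

Hits are retained at ≥ 97% identity (inclusive), one assignment per read
by top bitscore. Per-sample relative abundance is
$100 \cdot \text{target}/\text{total}$ percent, displayed as $\log_{10}$
of percent (so 0.1% ↦ −1). Samples with zero target reads are removed,
then sample types whose *summed* target reads fall below 5 — the type-level
sum is an interpretation (the motivating example is a whole sample type
with a handful of reads), and `min_type_reads` is exposed. Two-group
comparison defaults to the pooled-variance Student t test, the unadorned
"t-test" convention; Welch is a flag. Read-to-sample linkage follows the
QIIME-style id convention `sampleID_serial`.

## The synthetic-data generator

The generator is the package's study design, not a test fixture. Defaults:
4 genomes, 200 ortholog families, ancestral lengths
$\mathcal N(250, 50^2)$ floored at 50, residues drawn from the
Robinson–Robinson background frequencies, no duplication or loss, and
pairwise divergence 0.05 between any two genome copies. "Divergence" is
defined as *expected pairwise* divergence: the per-copy mutation rate is
solved from it accounting for the chance a background redraw reproduces
the original residue, so observed mean pairwise identity matches
$100(1-d)$ by construction rather than approximately.

Each family may carry a planted nearest phylum (defaults: Firmicutes 0.30,
Cyanobacteria 0.15, Proteobacteria 0.20, Bacteroidetes 0.20; the remaining
0.15 of families have no reference counterpart and should come back
"No hit"). The reference database contains, per such family, one close
homolog of the ancestor under the planted label (mutation rate 0.10) and
one decoy per other phylum at rate 0.35 — far enough apart that the margin
rule should separate them at the default divergence, close enough that all
decoys still align significantly. Every reference gene carries a KO;
"unknown" arises only from families with no reference counterpart, while
pathway-less and cross-category KOs in the planted catalog exercise
"Undecided" and "Multiple".

Scaffolds are built by uniform-codon back-translation of the proteins,
joined with random spacers (mean 150 nt), packed gene-by-gene into about
10 scaffolds per genome (no gene is ever split). Chance occurrences of the
RnpB motif are disrupted before 3 copies per genome are planted at
recorded positions and strands, so recovered-equals-planted is exact. The
linkage table chains the first `linkage_completeness` fraction of
scaffolds (default 1, so default genomes grade *Complete*).

The survey simulates six sample types with log-normal percent abundances
(foregut-fermenter feces highest among feces at median 0.5%, hindgut
0.12%, human 0.05%, soil 0.02%, water 0.8%, and a near-absent "air" type
that exercises the below-5-reads removal rule); 5,000–20,000 total reads
per sample; target counts are binomial draws; 10% extra decoy reads are
emitted below the 97% identity threshold and must be removed by the
filter.

What the generator does *not* emulate: realistic evolutionary models (no
rate matrices, no indels within families — alignment lengths are therefore
near-full-length and gap handling is exercised only by the unit tests),
database composition bias, paralog families in the reference, chimeric
bins, or read-level amplicon error. Passing recovery tests therefore shows
the decision rules are implemented correctly and separate planted signal
at realistic identity levels — not that the pipeline is robust to every
pathology of real metagenomic data.

Reproducibility: one master seed feeds fixed per-module substreams, so
individual simulators can be re-run independently and whole-pipeline
outputs are byte-identical under a fixed seed.

## Problem sizes in the test suite

The default study (4 × 200 families, divergence 0.05) is run once per test
session and shared by the recovery checks; the zero-divergence limit uses
60 families, and the byte-reproducibility check runs the full pipeline
twice at 30 families — the properties checked there (exact recovery,
determinism) do not depend on family count. Aligner-versus-oracle checks
use 500 random pairs of length ≤ 6 against a plain-R dynamic program plus
spot checks against an independent aligner at lengths 30–80.

## Known limitations

* Exhaustive all-vs-all alignment scales quadratically; beyond a few
  thousand proteins per genome, import external hit tables instead.
* E-values use uncorrected Karlin–Altschul statistics; absolute values
  near the 10⁻⁵ cutoff can differ from edge-corrected engines, which can
  move borderline hits in or out.
* The marker detector is similarity-based against single representatives;
  profile-based detection (HMMs) would be more sensitive for divergent
  genomes and can be plugged in by supplying a different marker FASTA and
  threshold.
* Cluster disjointness and the greedy conflict resolution are reasonable
  but unverifiable conventions; alternative tilings of a tangled component
  are possible.
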