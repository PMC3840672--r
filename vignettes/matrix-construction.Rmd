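---
title: "Constructing phylogenomic supermatrices with mfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing phylogenomic supermatrices with mfx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfx)
```

## The problem

Most of the work in a phylogenomic study is matrix construction, not
tree inference: raw transcriptome reads must be filtered, screened for
ribosomal RNA and vector contamination, reduced to one exemplar
transcript per gene, grouped into homologous clusters across species,
aligned, purged of paralogs, and concatenated into a partitioned
supermatrix that inference software can consume. mfx implements this
chain as composable R functions with a thin command-line front end,
with every stochastic step seeded and every stage's sequence count
recorded, so a complete run is reproducible and auditable.

The heavy external steps that surround matrix construction — de novo
assembly, read mapping, expression quantification, translation-aware
multiple alignment, and maximum-likelihood tree inference — are
consumed through files (FASTA, SAM template lengths, expression TSVs,
aligned FASTA, Newick), not reimplemented. What mfx owns is the
decision logic between them.

## Read sanitization

A read pair is discarded whole (never trimmed) when either mate fails
any of three tests, applied in the fixed order quality, adapter,
composition:

* **quality** — mean Phred score below `mean_quality_min`
  (default 28; a stricter `assembly_quality_min`, default 33, is the
  conventional pre-assembly setting). The thresholds are knobs because
  acceptable quality depends on the library and the assembler.
* **adapter** — exact substring match of any configured adapter (a
  small bundled set of common Illumina adapter stems by default).
  Exact matching is deliberate: at these lengths (34+ nt) a verbatim
  hit is unambiguous, and fuzzy matching belongs in dedicated trimmers.
* **composition** — any of A, C, G, T at a frequency strictly below
  5% or strictly above 60% of the non-N bases. Such skew is
  characteristic of synthesis artifacts and low-complexity junk.
  All-N reads are degenerate and count as skewed.

Surviving pairs are re-emitted in a seeded random order with mates kept
in lockstep. Downstream subsetting then reduces to taking prefixes
(`subset_reads`), which makes read subsets nested by construction. The
permutation is a pure function of the configured seed, recorded in the
stats object, so two runs over the same input are byte-identical.

## Screening

Screening decisions (is this read rRNA-derived? does this transcript
contain vector?) are made by **canonical k-mer containment**
(`kmer_matcher`): a query matches when at least `min_shared_fraction`
(default 0.5, compared with `>=`) of its k-mers, canonicalized so a
k-mer and its reverse complement are identified, occur in the
reference set. The default `k = 25` is long enough that a shared k-mer
is effectively diagnostic (random collisions at 4^25 are negligible)
and short enough to tolerate a few percent divergence from the
reference. The matcher is deterministic, needs no external binary, and
sits behind a small interface so a mapping-based screener can replace
it without touching callers. Transcripts are only ever *flagged*
(`is_rrna`, `is_vector`); deletion decisions are left to exemplar
selection.

The fraction of read pairs removed as rRNA is reported
(`remove_rrna_reads`), since it is direct feedback on library
preparation quality.

Insert sizes are estimated (`estimate_insert_size`) as the arithmetic
mean and unbiased sample variance of positive template lengths, read
from the TLEN field of a paired mapping (`read_template_lengths`);
variance is defined as 0 for a single observation rather than NA so the
estimate is always usable downstream.

## ORFs and exemplars

`find_longest_orf` scans all six frames for the longest **stop-to-stop
codon run** — a start codon is *not* required, because transcriptome
fragments are frequently 5'-truncated, and requiring ATG would
systematically clip real coding sequence. Partial terminal codons are
ignored (each frame scans ⌊L/3⌋ codons). Ties are broken by frame
order +1, +2, +3, −1, −2, −3, then by smaller forward-strand start;
all coordinates are reported 0-based half-open on the forward strand.
"Likely coding" is thus judged by length alone; protein-database
support is a deliberate non-goal.

`select_exemplars` keeps one transcript per gene: the unflagged isoform
with the highest expression (missing expression counts as 0), ties
broken by length and then by sequence id so the choice is total and
deterministic. Expression values are consumed from an external
quantifier, in whatever units it produced — only their order matters.

## Homology: graph + Markov Clustering

An all-by-all similarity search (run externally; tblastx-style
12-column tabular output) is reduced to a weighted undirected graph:
an edge joins two distinct sequences when at least one directional hit
passes **both** a stringent e-value ceiling (default 1e-20) and a
minimum alignment length (default 50 nt); the weight is the maximum
bit score over passing hits in either direction. Bit score is used
rather than −log e-value because it is independent of database size,
so graphs built from different search runs are comparable.

The graph is clustered with a from-scratch **MCL** implementation
(`mcl_cluster`): self-loops are added (loop weight = maximum incident
edge weight, 1 for isolated nodes — the standard regularization that
keeps attractors stable), columns are normalized to stochastic, and the
iteration alternates expansion (matrix power, default 2) with inflation
(elementwise power, default 2.0, then renormalization), pruning entries
below 1e-5, until the maximum column change drops below 1e-6 or 100
iterations elapse (non-convergence returns the current clustering with
a warning — it has not been observed on test graph families). A column
whose entries are all pruned is restarted on itself. Clusters are read
off the limit matrix as weakly connected groups of its nonzero
entries, which assigns every node to exactly one cluster. Each
connected component is iterated independently — the result is
identical because the stochastic matrix never mixes components, and
the dense per-component iteration stays cheap at desk scale. Plain
connected components (`connected_components`) are available both as an
alternative clustering mode and as an outer bound: every MCL cluster
lies within one component, a property the test suite checks on random
graph families.

## Cluster refinement

`filter_clusters` removes sequences shorter than `min_seq_len`
(default 60 nt) first, then drops clusters spanning fewer than
`min_taxa` (default 4) distinct taxa or exceeding `max_seqs` (default
100) members. The values are conventions, not doctrine, and are
exposed on the command line; drop reasons are logged per cluster.

`trim_ends` removes sequence ends with no similarity support inside
the cluster: for each member, the union of its query-side hit spans
against *other* members defines an envelope `[min_start, max_end]`,
and the sequence is cut to it. Only the ends are cut — interior
low-similarity stretches are kept, since cutting them would fabricate
chimeric junctions of its own. A member with no qualifying intra-
cluster hits is removed outright; a sequence none of its cluster
supports anywhere is the signature of a chimeric or misassigned
transcript. ORF coordinates are shifted into the trimmed frame and
dropped when the ORF falls entirely outside it.

The multiple aligner is an external interface: clusters go out as
unaligned FASTA (`write_cluster_fasta`) and come back aligned
(`read_alignment_fasta`). A built-in `pad_align` exists for
self-contained runs on the package's indel-free synthetic data, where
rows are columnwise homologous by construction, and `align_mafft`
wraps a mafft binary when one is on the PATH. `clean_alignment` is an
explicitly simplified gap-block filter — columns above a gap fraction
(default 0.5) go, then surviving runs shorter than `min_block_len`
(default 10) go — not a reimplementation of any published cleaner;
externally cleaned alignments can be supplied instead.
`translate_alignment` applies the standard genetic code codon-wise,
mapping all-gap codons to `-` and partial-gap, ambiguous, or stop
codons to `X` (stops with a warning, since internal stops usually mean
frame damage).

## Ortholog decomposition (treeprune)

Gene trees over clusters that contain paralogs are split into
**maximally inclusive subtrees with at most one sequence per taxon**
(`prune_orthologs`). The tree is treated as unrooted — ML gene trees
are unrooted, and rooting guesses would bias which paralog copy
survives — so the candidate leaf sets are the two sides of the
bipartition induced by deleting each branch, plus the whole leaf set.
Among taxon-unique candidates the largest is extracted greedily (ties:
most distinct taxa, then lexicographically smallest sorted label list
— a convention chosen to make extraction order reproducible), its
leaves are deleted with degree-2 nodes suppressed, and the process
repeats on the residual until no leaves remain. The output sets are
disjoint, cover every leaf, and each is taxon-unique by construction;
the test suite verifies first-extraction maximality against brute-force
enumeration over an exhaustive family of small trees. A rooted mode
(clade candidates only) exists behind a flag for comparison.
Singleton sets are emitted rather than suppressed; the downstream
`min_taxa` filter disposes of them, keeping each stage's contract
simple.

Trees are filtered beforehand by **mean bootstrap support**
(`filter_trees_by_support`), averaging only over internal nodes that
carry a numeric value; a tree with no supports at all is excluded with
a warning rather than silently kept, because "no evidence of signal"
should not pass a signal filter by default.

## Supermatrix

`concatenate` joins per-ortholog alignments in lexicographic gene
order (reproducibility; any explicit order can be given), keying rows
by taxon. Missing taxon-by-gene blocks are filled with `?`, which is
deliberately distinct from the alignment gap `-`: absent data and
inferred indels are different statements, though `occupancy` counts
both as missing. Partitions are recorded 1-based inclusive and written
as RAxML-style lines `DNA, g1 = 1-825` (`write_supermatrix`, which
also emits FASTA and relaxed PHYLIP); a model token such as `WAG` can
replace the datatype for protein matrices. The writer/reader pair
round-trips exactly, and per-partition column extraction reproduces
the source alignment rows — both identities are under test.

## The synthetic-data generator

`simulate_gene_families` draws one random species tree, then evolves
each family root sequence along it with i.i.d. per-site substitutions
(probability `substitution_rate`, default 0.02, per branch, uniform
over the three alternative bases — Jukes–Cantor-like, **no indels**).
Duplicated families plant one duplication on a random internal branch:
the clade below carries a second, independently evolving copy. The
truth table maps every sequence to its (family, copy), and everything
is a pure function of the seed. `simulate_hit_table` stands in for the
external all-by-all search by emitting hits from true pairwise
identity (threshold 0.7 over the shorter length), and `sim_gene_tree`
constructs duplication gene trees directly. `simulate_reads` draws
fragments with truncated-normal insert lengths (defaults 266 ± 40 bp,
echoing a typical RNA-seq library) and injects defect classes — full
adapter verbatim, homopolymer composition, uniformly low quality,
rRNA-reference fragments — each built to be detectable by exactly one
filter; clean fragments that would trip a filter by chance are redrawn
so the manifest partition is exact. Default library scale is 25,000
100-bp pairs; 5 taxa with 50 single-copy and 10 duplicated families is
the default family preset.

What the generator does **not** emulate, and what passing tests
therefore do not show: indel evolution (so alignment correctness on
real data is untested — the built-in pad aligner is only valid because
of this), position-dependent quality curves, sequencing error within
reads, rate heterogeneity across sites and lineages, incomplete lineage
sorting, isoform structure beyond whole-sequence duplicate copies, and
realistic rRNA secondary-structure conservation. Results on this
substrate validate the decision logic, not the upstream biology.

## Numerical and design choices

* All randomness routes through an internal seeded-RNG wrapper that
  restores the caller's RNG state; identical inputs and seeds give
  byte-identical outputs everywhere.
* Internal coordinates are 0-based half-open; external formats (hit
  tables, partitions) keep their native 1-based inclusive conventions,
  converted only at the I/O boundary.
* Sequence ids are namespaced `taxon@seq` internally so tree leaves
  are unambiguous; `@` is reserved and rejected in user ids.
* MCL: pruning at 1e-5 and convergence at 1e-6 are the classic
  defaults; the limit-matrix cluster reading (weak connectivity of
  nonzero entries) is robust to the rare overlapping-attractor case.
* Degenerate inputs are decided, not left undefined: all-N reads are
  skewed; an empty read stream makes the rRNA fraction an error rather
  than NaN; a fully pruned MCL column restarts on itself; trimming
  that empties a member removes the member; cleaning that empties an
  alignment warns and returns an empty alignment.
* Test problem sizes (chosen to exercise each property thoroughly at
  desk scale): exhaustive tree topologies to 6 leaves over up to 4
  taxa plus 200 seeded 7–8-leaf trees for the decomposition oracle;
  200 seeded random graphs (≤ 8 nodes) for the MCL oracle; 1,000
  seeded 300-mers for the ORF oracle; a 10,000-pair library for
  sanitize exactness; a 2,000-pair pool for rRNA recovery; and the
  default family preset for the end-to-end run.

## Known limitations

The built-in cleaner is far cruder than GBLOCKS-class tools; the NJ
gene trees used by the self-contained pipeline carry no bootstrap
supports, so the support filter is only meaningful with externally
inferred trees; the k-mer screen will miss references more than a few
percent diverged from the query at `k = 25`; MCL is iterated densely
per component, which is fine for thousands of sequences but not
millions; and the greedy decomposition is maximal per extraction, not
globally optimal across the whole sequence of extractions (the
classical formulation shares this property).
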