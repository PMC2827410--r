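---
title: "Dissecting protein superfamilies into subfamilies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting protein superfamilies into subfamilies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subfam)
```

## The problem

Large enzyme superfamilies — the alpha/beta hydrolases housing proline
iminopeptidases (PepI), prolinases (PepR), leucyl peptidases (PepL) and
esterases (EstA) are the motivating example — diverge so far in sequence
that a full-length multiple alignment is unreliable: members differ by
large insertions and deletions, and a structurally variable "cap" domain
covers the substrate-binding site while the catalytic domain stays
conserved. `subfam` implements the comparative strategy built around that
observation: anchor the alignment on the structurally conserved core,
build a distance tree from the concatenated core alignment, and split the
tree into orthologous groups (subfamilies) by duplication/speciation
labelling. A companion component turns pangenome comparative genome
hybridization (CGH) scores into presence/absence calls per strain.

## Pipeline stages and their models

### Homolog collection and redundancy removal

Queries are compared against every proteome sequence by exhaustive local
dynamic programming (Smith-Waterman with affine gaps, BLOSUM62, gap open
11 / extend 1 — a gap of length $L$ costs $11 + L$). A sequence is
recruited when its best hit reaches both a raw score threshold (default
60) and an identity threshold (default 0.25); no E-value model is used,
because thresholds on score and identity are transparent and the panels
involved are small enough for exhaustive search. Identity is always the
fraction of identical residues over mutually non-gap columns of an
alignment. Near-duplicates are removed by a greedy scan in input order: a
sequence is dropped when its global identity to an already-kept sequence
is *strictly* greater than 0.90, so a pair at exactly 90% survives. The
greedy, order-dependent rule is deliberate: it makes the kept set
deterministic without claiming which of two redundant records is the
"right" one.

### Structure superposition and core detection

Structures enter as Calpha traces. Rigid-body superposition is the Kabsch
algorithm (SVD of the cross-covariance matrix with the reflection guard),
which is exact for the least-squares rotation+translation problem.
Residue equivalences between two structures come from a global alignment
of their structure-derived sequences; equivalences across more than two
structures are chained through the first structure, the reference — a
deliberate simplification that is adequate for the handful of template
structures these analyses use.

The structurally conserved core is found iteratively: superpose everything
onto the reference over the current core set, re-score *every* initially
aligned position by its maximum pairwise Calpha deviation under the
current fit, and keep positions below the cutoff (default 3.0 Å). Two
numerical details matter. First, early fits can be dominated by spuriously
matched cap positions; while the thresholded set would shed more than a
quarter of the current core, only the worst quartile is trimmed, which
lets the fit improve gradually instead of collapsing. Second, because all
candidates are re-scored each round, a position trimmed under a
contaminated fit can return once the fit is clean; the loop stops at a
stable set or after `max_iter` (default 20) rounds, and a final strict
filter guarantees every reported position sits below the cutoff. Kept
positions are split into maximal runs of consecutive reference residues;
runs of at least `min_segment_length` (default 4) become core segments,
shorter runs are reported as diagnostics. The deviation cutoff and
minimum segment length are declared defaults, not published values — the
original core definition was visual — so the segment count on real
templates depends on them; they are exposed in the configuration and swept
in the tests.

### Core alignment

Each core segment is projected from the reference sequence onto every
family member through a global pairwise alignment; a segment whose
template positions align to more than 50% gaps in the target is flagged
missing rather than silently empty. Segment blocks are aligned with a
simple deterministic progressive aligner: pairwise distances (1 −
identity), a UPGMA guide tree, and profile-profile dynamic programming
under the same BLOSUM62/affine-gap scoring. Columns below 0.5 occupancy
are removed — an automated, reproducible stand-in for manual curation of
ambiguously aligned regions, which cannot be encoded — and the curated
blocks are concatenated, with all-gap spans for missing segments. The
aligner makes no claim of parity with MUSCLE or ClustalW; recovery of
planted subfamily structure on synthetic data, not aligner equivalence,
is the validation surface.

### Trees, orthology, triads

Distances are p-distances over mutually non-gap columns (Poisson
correction $-\ln(1-p)$ optional; the default stays uncorrected because
the divergences involved sit well below saturation and the published
pipeline's correction is unstated). Trees are Saitou-Nei neighbor
joining with deterministic tie-breaking (lexicographically smallest pair
of cluster keys) and negative branch lengths clamped to zero with the
deficit recorded; NJ is exact on additive matrices, which is the primary
oracle in the tests. Bootstrap supports resample alignment columns with
replacement (the full-scale convention is 1000 replicates) and count, per
internal edge, the fraction of replicate trees containing the same leaf
bipartition.

For orthology the unrooted NJ tree is midpoint-rooted. Internal nodes are
labelled by species overlap: a node whose child subtrees share at least
one species is a duplication, otherwise a speciation. No species tree or
reconciliation is needed. Orthologous groups are the maximal
duplication-free regions after cutting every edge below a duplication;
hierarchical ids gain one dot level per duplication passed (`1`, `1.1`,
`1.2`, ...). Groups can change under re-rooting; the midpoint choice is a
declared convention, and the simulation design below shows why a distant
outgroup makes it stable. "Major" subfamilies are operationalized as
groups with at least three members, the rest reported as intermediate
genes.

The catalytic-triad diagnostic reads three alignment columns — designated
by mapping the reference structure's known nucleophile/base/acid residue
numbers through the core alignment — and classifies each row as `SHD`
(the classic Ser-His-Asp triad), `SHE` (the Asp→Glu substitution
diagnostic of the PepR subfamily), or `other`, with gaps flagged.

### CGH presence/absence

Probe scores are collapsed per gene by maximum (mean available) and
thresholded at 5.5 with a *strict* greater-than: a score of exactly 5.5
is absent. An optional symmetric ambiguity band around the cutoff yields
`ambiguous` calls, rendered `0?` in the exported strain-by-gene table;
the band defaults to zero because no numeric band is published, only the
annotation. Genes constant across all strains are excluded from the
variable-gene table, and co-inherited (e.g. plasmid-borne) genes are
found by single-linkage clustering on the Jaccard similarity of
present-strain sets at a declared threshold of 0.9.

## The simulators and what they do (not) show

All pipeline inputs can be generated with known truth.

**Families.** A uniform random root sequence evolves along a species tree
with Poisson-distributed substitutions per branch (uniform replacement
over the other 19 residues — deliberately not WAG/LG, since the aim is
controlled divergence, not realism). Duplications are planted halfway
along the branch entering randomly chosen internal nodes, so the copy
split has a positive stem and is identifiable; a duplication placed
exactly at a speciation node would create a zero-length internal branch
that no method could resolve. True groups are the leaf sets sharing a
duplication-copy path, with tags qualified by the duplication node so
independent duplications in disjoint clades stay distinct.

**Study conditions.** The reference study tree
(`example_species_tree()`) has six ingroup species plus a distant
outgroup `O`; branch lengths give ingroup divergences around 30%, and
sequences default to 300 residues, a typical single-domain enzyme length.
The outgroup anchors midpoint rooting the way reference proteins from
other phyla do in real superfamily trees: without it, a duplication near
the ingroup root yields two copy clades as deep as the true root and
rooting — hence orthology — becomes unstable regardless of
implementation quality. Under these conditions the end-to-end pipeline
(homolog collection → redundancy filter → alignment → NJ → midpoint
rooting → species-overlap orthology) recovers the planted partition
exactly in ≥95 of 100 seeds; the residual failures are short duplication
stems drawn close to the identifiability limit, which is the expected
behaviour, not a defect.

**Structures.** The shared core backbone is a self-avoiding random walk
with 3.8 Å steps (the Calpha virtual bond). Members are rigid transforms
of the noisy core with member-specific random-walk cap insertions at the
inter-segment junctions; core residues share one amino-acid sequence so
that sequence alignment can pair them, caps are random. This emulates a
conserved catalytic domain with variable caps but none of the real
correlations between sequence and structural divergence.

**CGH.** Presence is Bernoulli per cell; probe scores are class-conditional
normals (present: N(12, 2), absent: N(2, 1.5), three probes per gene),
declared inventions calibrated so the conventional 5.5 cutoff separates
the classes; optional plasmid blocks share one truth vector. Passing
tests therefore demonstrate the calling and clustering logic, not
robustness to real array artefacts (normalization, spatial effects,
cross-hybridization are out of scope).

## Reproducibility and problem sizes

One master seed governs every stochastic stage; each stage derives its
own stream via a string-hash mix (`derive_seed()`), and each pipeline run
writes its resolved configuration next to its outputs. The packaged
checks use problem sizes chosen to exercise the statistics without waste:
100 random additive 6-taxon matrices for NJ exactness, 100 random rigid
transforms for superposition recovery, 4-member structure sets with
10-40-residue caps at 0.3 Å noise for core recovery, 100 simulated
families for the orthology study, and 10,000 CGH cells for calling
accuracy. Bootstrap replicate counts in examples and tests are reduced
from the full-scale 1000 to keep runs brief; supports are
seed-reproducible at any count.

## Replicating the published template analysis

The checks that depend on the four published template structures (PDB
1MTZ, 1AZW, 1WM1, 2UZ0) and on full proteome panels — four discontinuous
core segments in the catalytic domain, five major PepD subfamilies, four
PepI/R/L+EstA subclusters, single-copy PepP — are encoded in
`replication_manifest()` and run through `run_replication()` once the
user supplies the coordinate files locally. The segment count is
threshold-dependent (the original definition was visual); the manifest
records the expected values and comparison mode rather than claiming
them as package outputs. When counting segments for comparison, the
reference's catalytic-domain residue range should be supplied so the
structurally variable cap region is excluded.

## Known limitations

* Correspondences are chained through the reference structure, not a full
  multiple structure alignment; with many or very divergent templates a
  joint superposition would be preferable.
* The progressive aligner has no iterative refinement; badly gapped
  segment blocks rely on the occupancy filter.
* Species-overlap orthology can over-merge under extensive gene loss, and
  groups depend on the rooting; both are documented behaviours of the
  method class, not implementation artefacts.
* The CGH component starts from hybridization scores; array normalization
  and probe design are out of scope.
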