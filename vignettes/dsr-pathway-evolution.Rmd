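---
title: "Reconstructing the evolution of the dissimilatory sulfite reduction pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the evolution of the dissimilatory sulfite reduction pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrevo)
```

## The scientific problem

Dissimilatory sulfite reduction is among the oldest energy-conserving
metabolisms.  Its core is the sulfite reductase DsrAB, which together with
the sulfur-carrier DsrC and the DsrMK(JOP) membrane complex forms the
minimal protein set -- DsrABCMK -- required to process sulfite in either
direction.  Sulfate reducers add the sulfate-activation arm (Sat, AprAB,
QmoABC); sulfur oxidizers run the cascade in reverse and recruit DsrEFH and
DsrL while losing DsrD and DsrT.  Reconstructing how this modular pathway
was assembled requires, for each protein family: detecting homologs in
annotated genomes while rejecting look-alike families (NarGHI-, HdrA-like),
reducing redundancy, building and rooting phylogenies, reading gene
neighborhoods, and classifying genome repertoires.

`dsrevo` implements that workflow as a reusable, fully testable pipeline.
Because the original genome corpus is far too large to re-screen on a
desktop, every stage is validated against a bundled synthetic-genome
simulator with known evolutionary ground truth: a species tree, per-family
gene trees, planted gene-cluster layouts, decoy families, genome
incompleteness, and planted lateral gene transfer (LGT) events.

## Pipeline stages and their parameters

| Stage | Operation | Key parameters (defaults) |
|---|---|---|
| assignment | best local alignment against family references, decoy-aware | min identity 25%, max E-value 1e-10, BLOSUM62, gaps 10/0.5 |
| redundancy | all-vs-all global identity, MCL, longest per genus | edges strictly > 90% identity, inflation 2.0 |
| alignment | k-mer/UPGMA-guided progressive profile alignment | gaps 15/2 (see below) |
| trimming | per-column gap filter | keep columns with >= 95% residues |
| tree | corrected-distance neighbor joining + column bootstrap | 1000 replicates |
| rooting | minimal ancestor deviation (MAD) + optional outgroup | -- |
| synteny | max-gap clustering of hits along contigs | <= 4 intervening genes |
| genotyping | presence/absence against the DsrABCMK minimal set | -- |

Identity conventions follow the EMBOSS tools this workflow is modelled on:
the denominator of percent identity is the full alignment length, gap
columns included; a gap run of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{extend}$; terminal gaps are penalized in
global mode.  Pairwise traceback ties resolve deterministically (diagonal,
then up, then left), so every run is reproducible byte for byte.

Because no database search engine is embedded, the E-value filter uses the
Karlin–Altschul surrogate $E = K m n e^{-\lambda S}$ with the gapped
BLOSUM62 constants ($K = 0.041$, $\lambda = 0.267$); E-values from
externally supplied hit tables take precedence when provided.

### Why the multiple aligner uses stiffer gap penalties

The progressive aligner scores profile columns by the average substitution
score over residue pairs.  At the divergence typical of deep protein
families (40–60% identity), the pairwise-scan penalties (open 10, extend
0.5) are too permissive for multiple alignment: a gap run of length five
costs only 12.5, well within the score fluctuation of a few dozen columns
of diverged homologs, so even sequences that differ by substitutions alone
acquire spurious gaps.  Under open 15 / extend 2 the same run costs 25 and
stops paying for itself.  The aligner therefore defaults to 15/2 — the
test suite asserts that simulated (indel-free) families align gap-free
under these defaults — while genuine indels remain affordable.

### MCL details

The identity graph keeps edges strictly above the 90% threshold.
Self-loops are weighted by each node's maximum incident edge rather than 1:
with edge weights in the 90–100 range a unit loop is negligible, and
2-cliques -- the dominant case for near-duplicate sequences -- are
bipartite, so expansion oscillates with period 2 and the cluster splits.
Max-weight loops (the MCL tool's own convention) damp that oscillation.
Convergence uses elementwise tolerance 1e-6, pruning below 1e-5, and at
most 100 iterations; overlapping attractions resolve to the attractor
system with the largest value, ties to the lowest cluster id.

### Tree inference: a distance stand-in plus an engine adapter

Maximum-likelihood inference is deliberately not re-implemented.  The
self-contained path is neighbour joining on model-corrected distances,
with supports from a Felsenstein column bootstrap; `external_tree_adapter()`
accepts a command template (`{in}`/`{out}` placeholders) so a real ML
engine can replace the stand-in without touching anything downstream.
Distances use the uniform 20-state correction
$d = -\tfrac{19}{20}\,\ln(1 - \tfrac{20}{19}\,p)$, which exactly inverts
the simulator's substitution model, giving parameter-recovery tests a
closed-form oracle.  Saturated pairs ($p \ge 0.95$) are capped at $d = 10$
with a warning; negative NJ branch lengths are clamped to zero.  NJ itself
is delegated to `ape::nj` (canonical algorithm, exact on additive
matrices); equal-Q tie-breaking follows ape's deterministic implementation
rather than the lexicographic rule we use elsewhere.

### MAD rooting

For every branch, every leaf pair $(b,c)$ receives a putative ancestor --
the candidate root point for pairs straddling the branch, their induced
ancestor node otherwise -- and deviates from a strict clock by
$r_{bc} = |2\,d(\rho,b)/d(b,c) - 1|$.  The branch score is the RMS of
$r_{bc}$ over all pairs; the optimal relative root position $\rho$ has a
closed form (the objective is quadratic), clamped to the branch.  Zero
branch lengths are replaced by $10^{-9}$ (the ratio statistic is undefined
at zero), tied branch scores resolve to the lexicographically smallest
side, and the ratio of the second-best to best deviation is reported so
near-ties are visible.  On ultrametric trees the minimum deviation is
exactly 0 at the true root.

### Genotype classification

`has_minimal_set` is true iff DsrA, DsrB, DsrC, DsrM, DsrK are all
present.  Classes are assigned with precedence chimeric > oxidative >
sulfate-capable > sulfite-minimal > partial > none: *chimeric* requires the
minimal set plus both a reductive-type marker (DsrD/DsrT) and an
oxidative-type marker (DsrEFH/DsrL); *oxidative* the minimal set plus
DsrEFH (all three) or DsrL without DsrD; *sulfate-capable* the minimal set
plus Sat, AprA, AprB and QmoA or QmoB; *partial* at least one but not all
of the minimal set.  The precedence order is a design decision -- the
narrative definitions never state one -- and chimeric is conditioned on the
minimal set so that stray accessory genes alone cannot produce a pathway
call.

### Synteny

Gene positions are 0-based ranks in gene order, not nucleotide
coordinates: the distance unit of the neighborhood analysis is "genes".
Consecutive family hits separated by at most four other genes join one
cluster (equivalently, rank difference <= 5); the alternative reading of
"distance of four genes" as a rank offset is available via
`gap = "offset"`.  Clusters never span contigs; strands are recorded but
ignored for clustering, since the gene clusters of interest span operons
on both strands.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` draws a birth–death species tree (`ape::rphylo`,
defaults birth 1, death 0) conditioned on the number of genomes, rescaled
to unit root-to-tip height and relabelled `g01..gNN`.  Genome classes
(archaeal-minimal, bacterial-reductive, oxidative, chimeric) are assigned
to contiguous blocks of ladderized tips, emulating cladewise pathway
types; genera cover pairs of adjacent tips.  Each family evolves along the
species tree restricted to its carrier classes under a uniform 20-state
model: per site, events arrive as Poisson with mean
$\text{rate}\times\text{branch}\times\text{site rate}$ and replace the
residue with one of the 19 alternatives uniformly.  This model was chosen
over an empirical matrix precisely because it admits the closed-form
distance inversion above; pipeline logic, not substitution realism, is
what the tests must exercise.  Site-rate heterogeneity is available via a
gamma multiplier (mean 1).

Defaults describe the study conditions used throughout the tests: 20
genomes, 300-residue proteins (500 in the tree-recovery studies), 0.5
expected substitutions per site root-to-tip -- giving cross-class
identities around 45–55%, comparable to real deep Dsr-family divergence --
8 unrelated cargo genes per genome, and no incompleteness.  The planted
cluster layout follows the canonical consecutive *dsrABDNCTMKJOP* order
(with per-class subsets), a *sat-aprBA-qmoABC* block in sulfate reducers,
and a *dsrEFH* block plus scattered *dsrL* in oxidizers.  Decoy families
(NarG-like, HdrA-like) evolve from independent random roots that share a
30-residue motif with their target family (DsrB, QmoA), so decoy rejection
is non-trivial.  Genome incompleteness is i.i.d. gene deletion with
re-ranking of the survivors.

LGT is implemented as xenologous replacement: the recipient's copy is
dropped and re-attached halfway along the donor's terminal branch in the
family's gene tree, mirroring the replacement of an archaeal DsrAB by a
bacterial reductive-type version while the rest of the pathway stays
vertical.  The evaluation flags a family tree as discordant for an event
when the recipient's nearest leaf by patristic distance belongs to the
donor's class rather than its own.

Not emulated: indels (alignment inference is exercised with
substitution-only truth, so tests say nothing about gap placement on real
data), nucleotide-level structure, codon models, rate variation across
branches, assembly chimerism, or contamination.  Passing tests demonstrate
that the pipeline's logic recovers planted signal under a known model --
not that any particular biological conclusion about real genomes is
reproduced.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed through named per-stage
  substreams, so any stage can be re-run in isolation and whole runs are
  byte-identical (reports omit filesystem paths for this reason).
* Alignment of empty sequences, trees with fewer than 3 leaves, all-gap
  trimming results, non-consecutive gene ranks, unknown strand symbols,
  and outgroups equal to the full leaf set are rejected with informative
  errors naming the offending file, line, or pair.
* Families with fewer than 2 assigned or fewer than `min_family_size`
  (default 3) retained sequences skip tree building with a logged reason;
  the pipeline continues.
* Bootstrap replicates whose resampled alignment makes a pair share zero
  columns are dropped from the support denominator.

## Problem sizes used by the test-suite studies

Unit tests run on 5–10 genome simulations with 200-residue proteins.  The
pipeline-level studies use 20 genomes at 500 residues: five to ten
replicates for end-to-end recovery, 100 twelve-leaf clock simulations for
root recovery, and 100 planted-partition graphs (3 groups of 8) for MCL.
These sizes were chosen so the complete study battery runs on a single
CPU in minutes while keeping Monte-Carlo bands tight enough for the
properties being checked.

## Known limitations

* Neighbour joining on corrected distances is noisier than
  likelihood-based inference; internal branches carrying roughly one
  expected substitution across the alignment are at the edge of what 500
  sites can resolve, and birth–death trees routinely contain such
  branches.  End-to-end topology-recovery rates should be read against
  that information limit, which the adapter to an external ML engine does
  not remove.
* MAD root recovery on noisy trees degrades gracefully but near-ties
  between adjacent candidate branches are common; the reported ambiguity
  ratio should be consulted before trusting a root.
* The E-value surrogate calibrates to gapped BLOSUM62 statistics only; it
  is a filter, not a replacement for a real search engine's statistics.
* The progressive aligner is quadratic per profile pair and intended for
  family-sized inputs (hundreds of sequences), not proteome-scale MSA.
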