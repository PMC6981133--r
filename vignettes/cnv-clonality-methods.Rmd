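---
title: "Reconstructing intra-tumor CNV clonality trees: methods and design"
author: "cnvClonality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing intra-tumor CNV clonality trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvClonality)
```

# The problem

Single-cell RNA-seq permits inference of copy-number variation (CNV) per
cell, and in tumors such as uveal melanoma the CNV composition of the cell
population carries the clonal history: canonical events (monosomy 3, 8q
gain, 6p gain) arise early and subclonal events accumulate on top of them.
CNV-inference tools emit, per inferred subcluster of cells, a set of
genomic regions with a six-state copy-number code (1–2 loss, 3 neutral,
4–6 gain). This package turns those region calls into an interpretable
clonal architecture: arm-level events, a nested evolutionary tree scaled
by the percentage of cells, driver mutations placed onto branches, and a
deterministic SVG rendering.

The package deliberately starts *after* CNV inference: the upstream HMM,
its Bayesian filtering, and the subclustering of cells are consumed as an
interface (a region table plus a cell-groupings table), not re-implemented.

# Arm-level conversion

Each region call is mapped onto the p and/or q arm of its chromosome using
a cytoband table. The arm boundary is defined as the start of the first
q band; the two "acen" bands flank the centromere, so this boundary sits
at the centromere's proximal edge. Cytoband files use 0-based half-open
coordinates and region tables 1-based closed ones; all interval arithmetic
is done after converting both to 0-based half-open form, and a region is
clipped to its chromosome before overlap is computed. A region wholly on
one arm yields one arm event; a centromere-spanning region yields events
on both arms. States below 3 produce losses, above 3 gains, and neutral
regions nothing. Mitochondrial regions are excluded from arm calling
(the mitochondrial genome has no arms, and mitochondrial CNV signal in
scRNA-based inference is dominated by expression artifacts).

Two choices here were genuinely open:

* **Minimum arm overlap.** By default any positive overlap triggers the
  arm event (`minArmOverlap = 0`): the conversion is a simplification of
  location, not a coverage test. A stricter fraction-of-arm threshold is
  exposed for users who want to ignore focal events.
* **Conflicting directions.** If one subclone accumulates both gain and
  loss calls on the same arm, the direction with the greater total
  overlapped length wins; exact ties keep both events and emit a warning.
  Length-majority is the least surprising deterministic rule.

# Tree reconstruction

Subclones with set-equal arm-event sets are collapsed (cells unioned).
The tree is then built greedily by containment: subclones are ordered by
event-set size, and each is attached to the deepest existing node whose
cumulative event set is a strict subset of the subclone's set. Ties among
equally deep candidates are broken lexicographically on the node id (the
"+"-joined cumulative event set), which makes the algorithm a
deterministic function of the input set regardless of input order. Added
events on a branch are the set difference from the parent. The same event
arising on two incomparable branches is permitted — reported as a
homoplasy warning — rather than triggering invention of latent internal
nodes; the transparent behavior was preferred over hidden inference.

Percentages are *inclusive*: a node's percentage is the percentage of all
tumor cells sitting at the node or any of its descendants, with the
denominator covering every cell that entered the CNV analysis, including
CNV-free cells (which sit at the root). This makes the root exactly 100%
and matches the natural reading of a nested architecture — in the worked
example below, a 6% clone with loss of both 3p and 3q arises *within* a
23% clone defined by 3q loss alone.

**Noise pruning.** Real per-cell call sets contain dropouts and spurious
calls, each of which mints a tiny "subclone" with a unique event set. The
tree builder therefore takes a `minFraction` argument (default 0, i.e.
spec-pure behavior): subclones holding fewer than `minFraction` of all
cells do not become nodes, and their cells are counted at the deepest
surviving node whose cumulative set they contain. In the package's own
robustness analyses a pruning threshold of 5% is used against 2%
per-cell per-event false-negative noise with true clones of at least 10%,
where it removes essentially all noise nodes while true clones are never
near the threshold.

# Mutation correction and attribution

Bulk targeted sequencing gives raw variant allele frequencies (VAFs)
depressed by normal-cell contamination. Because Gα mutations (GNAQ or
GNA11) are truncal and heterozygous in uveal melanoma, the anchor's true
VAF is 50%; all VAFs are rescaled by $0.5 / \mathrm{VAF}_{\text{anchor}}$,
so the anchor lands at exactly 50% and the rescaling is invariant to any
common purity factor. Values above 1 after rescaling are clamped with a
warning.

Under a heterozygous-diploid assumption a corrected VAF $v$ implies a
clone percentage of $\min(100, 200v)$. A mutation is attributed to the
non-root node whose inclusive percentage is *nearest* to this expectation,
provided the distance is within a tolerance (default 5 percentage points)
and the nearest node is unique; otherwise it is starred and listed at the
root, meaning bulk sequencing shows it to be subclonal but no specific
branch can be named. The nearest-node form (rather than "any node within
tolerance, unique or bust") was chosen because it behaves monotonically:
shrinking the tolerance can only star more mutations, never rescue a
starred one, which makes sensitivity analyses over the tolerance
interpretable. Truncal expectations (within tolerance of 100%) attach to
the first node above the root when the tree has a single trunk, else they
are starred.

The default 5-point tolerance quantifies "clones of like percentage" in
the absence of a stated rule; it is configurable, and analyses in the
test-suite that probe recovery at a 15-point clone separation use a
10-point tolerance matched to that separation. At depth 500, binomial
noise on a mid-sized clone's VAF propagates to roughly 3–5 percentage
points of standard error on the expected percentage, so tolerances much
below that reject genuine matches.

A caveat is logged when an attributed driver lies on an arm lost in its
clone (e.g. BAP1 on 3p under monosomy 3): copy-number-aware conversion of
VAF to cell fraction is out of scope, and the diploid formula
underestimates such clones.

# SVG rendering

The layout implements a single stated geometric rule: the Euclidean
length of every edge is

$$\text{scale} \times \text{inclusive percentage} + \text{circle diameter}
+ 5 \text{ px},$$

i.e. branch length proportional to the percentage of cells plus a spacer
of one circle diameter plus 5 pixels (defaults: 2 px per point, 10 px
circles). Everything else is fixed for determinism and legibility: the
root sits top-center with the trunk drawn straight down; children are
ordered by descending percentage (ties by label); the first child
continues its parent's direction and later siblings fan out at +40°,
−40°, +65°, −65°, +90°, … relative to it; the canvas is padded by 20 px;
coordinates are written with fixed 9-decimal formatting so identical
trees produce byte-identical files. Branches can be tinted by
gene-expression-profile class (class 1 blue, class 2 red).

# Upstream cell filters

The QC and reference-selection stage operates on a gene-by-cell count
matrix (10x-style MatrixMarket input is supported):

* cells are retained when UMIs $> 400$ (strict), detected genes lie in
  $[100, 8000]$ (inclusive), and mitochondrial fraction $< 10\%$
  (strict), mitochondrial genes being identified by the "MT-" symbol
  prefix;
* normal reference cells are those whose log-normalized CD3E expression
  (counts per 10,000, log1p — mean and SD taken over QC-passing cells)
  exceeds the mean by more than 2 SD, with zero raw counts of PRAME and
  HTR2B. Whether the 2-SD rule should use raw or normalized expression
  was open; normalized was chosen as it matches the surrounding
  pipeline's stated normalization;
* tumor cells entering CNV inference additionally require UMIs
  $> 3000$ (strict).

# The synthetic-data generator

Every stage is testable without external data. `simulateCellCNVCalls()`
takes a ground-truth tree (node, parent, added events, exclusive cell
fraction), apportions cells by largest-remainder rounding — so fractions
that are multiples of $1/n$ are hit exactly and percentage recovery can
be asserted to equality — shuffles barcodes under the seed, drops each
true event per cell with probability `fnRate`, adds spurious arm calls
with probability `fpRate` per free arm, and writes full-arm region calls
(loss state 2, gain state 5) in the exact file formats the readers
consume, one group per realized event set. `simulateMutationVAFs()` draws
observed VAFs as Binomial(depth, purity × 0.5 × inclusive fraction).
`simulateExpressionMatrix()` builds a sparse matrix with tumor and T-cell
populations plus deterministic boundary cells straddling each QC
threshold. `simulateCytoband()` provides a deterministic banded toy
genome. The default worked scenario is the sequential-LOH3 composition:
1000 cells of which 770 are CNV-free, 170 carry 3q loss only and 60 carry
both 3q and 3p loss, reconstructing the 23% → 6% chain.

What the generator does *not* emulate: per-gene expression smoothing and
the HMM's segmentation behavior (regions are clean full arms), correlated
dropout between events, doublets, or subclone-specific expression
programs. Tests passing on simulator output therefore validate the
post-processing logic — conversion, collapsing, tree building, VAF
arithmetic, geometry — not the upstream CNV inference.

Random ground-truth trees used in the recovery analyses draw each node's
added events from arms unused elsewhere in the tree. That keeps the
ground truth free of homoplasy, so ancestry is identified by set
containment and exact recovery is a well-posed target; trees with
repeated events are exercised separately for the warning path.

# Problem sizes and numerical choices

The packaged analyses run at desk scale: 300–1000 simulated cells per
replicate, 50 noiseless random trees (up to 6 nodes), 100 noisy
replicates for topology recovery, 100 replicates of depth-500 mutation
attribution, and a 1000-region brute-force oracle comparison on a
tiny-coordinate genome, all single-threaded in about two minutes.
Percentage comparisons in the noiseless setting are exact by
construction; geometric checks use a $10^{-6}$ px tolerance against
re-measured SVG coordinates; tie detection in mutation attribution uses a
$10^{-9}$ slack so floating-point midpoints count as ties.

# Known limitations

* Arm events are binary gain/loss; amplitude (states 1 vs 2, 4 vs 6) is
  discarded, as is sub-arm resolution.
* The containment-greedy tree is one concrete reading of "restructuring"
  a subclone hierarchy; when two incomparable subclones share events the
  true history is ambiguous and only a warning is possible.
* Mutation attribution assumes heterozygous diploid loci and matches on
  percentage alone; it cannot separate two genuine clones of similar
  size, and copy-number-aware cell-fraction inference is out of scope.
* The denominator of every percentage is the set of cells that entered
  CNV inference; selection biases upstream of that (the 3000-UMI filter
  retains high-quality, often larger cells) propagate into the
  percentages.
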