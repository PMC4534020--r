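---
title: "Methods: WGP physical-map construction and RH-map integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WGP physical-map construction and RH-map integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgpmap)
```

This vignette describes the models, the tunable parameters, and the design
choices behind `wgpmap`.  It states no empirical result that the package's
tests and acceptance script do not themselves compute.

## 1. The problem

A BAC-based physical map of a large, repeat-rich plant chromosome is built
in four stages: (i) fingerprint every clone of an arm-sorted BAC library
and assemble overlapping clones into contigs; (ii) remove clones that
entered the library from other chromosomes during flow sorting; (iii) order
PCR markers by co-retention on a panel of irradiated lines (a radiation
hybrid map) and on terminal-deletion stocks; (iv) anchor the contigs to the
marker map, orient them, and read off the virtual gene order for
comparative analysis against sequenced grass relatives.  `wgpmap`
implements all four stages plus a ground-truthed simulator of their inputs.

## 2. Fingerprint assembly

### Tags and the overlap score

In whole-genome profiling a fingerprint is a set of short sequence tags
generated at restriction sites.  The package represents tags as integer
identifiers of fixed genomic sites; any exact-match dictionary maps real
sequence tags onto this abstraction, which keeps the assembly logic
independent of sequence handling.  Matching is exact (`tolerance = 0`);
gel-type fingerprints with a nonzero match window are out of scope.

Overlap significance between two fingerprints with `nL <= nH` tags sharing
`m` of them, given `G` possible tags (the "gel length"), is the Sulston
score: each of the smaller clone's tags independently matches the larger
clone with probability `q = 1 - (1 - 1/G)^nH`, so the score is the binomial
upper tail `P(X >= m)`, `X ~ Binomial(nL, q)`.  The assumption of
independent uniform tags is the classical one; the test suite checks the
implementation against an exact combinatorial sum and against a Monte-Carlo
simulation of that sampling model.  Scores are computed in log10 space
(`sulstonLog10()`), since meaningful cut-offs (1e-75) lie far below
double-precision underflow for products, and clustering compares exponents
only.

### Filtering

Clones with fewer than 30 % or more than 2.5 times the mean tag count are
removed before assembly (`filterBacsByTagCount()`); at a mean of 20.6
tags/BAC the keep window is 7..51 tags.  The window is recomputed per
dataset, with an explicit override, because the printed thresholds of any
one study follow from its own mean.

### Stepwise assembly

The initial assembly is single-linkage clustering at 1e-75.  Each later
round relaxes the cut-off by five orders of magnitude (the published
schedule; `stepExp` is configurable) and allows only single-to-end and
end-to-end merges: a merge must be supported by a clone pair in which each
clone is a singleton or lies within `fromEnd` (default 12, half the mean
tag count) consensus-band units of its contig's end.  After every round a
DQer pass re-assembles contigs carrying more than `dqFraction = 10 %`
Questionable clones at a cut-off `dqStep = 3` rounds more stringent.

FPC's internal Questionable-clone rule is not published; the package
defines a member as Questionable when fewer than half of its tags fall
inside its median-centred placement window (width = its tag count plus a
slack of `max(2, 10 %)`).  This reproduces the role of the rule — flagging
clones whose tags scatter across the consensus — with a testable
definition.

### CB coordinates

Within a contig, consensus-band coordinates come from a greedy seriation:
the clone with the most tags seeds the consensus, and remaining clones are
added in order of maximal tag overlap with the placed set (ties broken by
clone id), novel tags extending the consensus on the nearer end.  On clean
simulated tilings this reproduces clone order and spacing well; it is an
approximation, not FPC's CB algorithm.  Contig size is
`uniqueTags x cbUnit`, with `cbUnit` the mean genomic distance between
adjacent tags (about 5-6 kb; in the simulator, insert length divided by
mean tags per clone).

### Final cut-off and MTP

`selectFinalCutoff()` makes the published "balance" criterion concrete: it
returns the round minimising the Q-contig count among rounds whose
cumulative size lies within a tolerance band (default 15 %) of the
coverage target, ties broken toward the more stringent cut-off.  The
minimal tiling path is the greedy furthest-reach interval cover over member
CB intervals with at least one tag unit of overlap between consecutive
clones; for interval inputs greedy is minimal, and tests verify equality
with an exhaustive cover up to 12 members.

## 3. Contamination screen

Tag-origin tables (in reality produced by a homology search of tag
sequences against survey assemblies at 95 %/95 % thresholds) are a plug-in
input.  The rules are exact: a clone is foreign when the best other
chromosome group out-votes the target group by strictly more than
`margin = 4` tags; a contig is eliminated when strictly more than 66 % of
its members are foreign.  Clones whose tags are all unassigned are
indeterminate — they are never called foreign, but they stay in the
denominator of the 66 % rule, the simplest defensible reading.  Small
contigs (< 3 members) are eliminated when at least 80 % of their tags occur
in one larger retained contig; the containment threshold and member cut are
package defaults, since the source procedure only names "depth" without
numbers.

## 4. RH mapping

### Model

Calls are presence/absence of a marker in a line.  The package uses an
equal-retention haploid model: a line retains the first locus with
probability `r`; between adjacent loci the chain keeps its state with
probability `1 - theta_i`, otherwise the state is re-drawn (retained with
probability `r`).  Two-point cell probabilities follow as
`P(11) = r(1-theta) + r^2 theta`, `P(10) = P(01) = r theta (1-r)`,
`P(00) = (1-r)(1-theta) + (1-r)^2 theta`.  A single global `r` is the
simplest identifiable choice; real panels show position-dependent
retention, which this model ignores.  Distances are
`d = -100 ln(1 - theta)` centirays.  Total map lengths are therefore
comparable between runs of this package but are not expected to equal
values produced by other mapping engines with different internals.

Two-point estimation is closed-form in `r` (margin frequency) with a 1-D
likelihood maximisation in `theta`; the LOD compares against independence
(`theta = 1`) with retention re-fitted.  Linkage groups are connected
components under `LOD >= 4` AND `d <= 100 cR`; the AND reading of the two
published thresholds is this package's contract.  Markers agreeing on every
co-observed line (with at least one shared informative line) collapse into
one locus before ordering.

### Ordering

With complete calls and no observation error the chain likelihood
decomposes over adjacent pairs, so candidate orders are scored through
precomputed pairwise terms; with missing calls the decomposition (on
pairwise-complete lines) is the search surrogate, while reported
likelihoods always come from the exact forward algorithm
(`multipointLoglik()`, which marginalises missing calls and supports a
genotyping-error rate `epsilon`, default 0).  The search is greedy chaining
from the strongest two-point pair, best-position insertion, then full
2-opt and a window-5 ripple to convergence.  Orientation is canonical
(lexicographically smaller terminal locus first); remaining ties are broken
by locus id.  Tests verify that the search attains the factorial-search
optimum for up to six loci and recovers the true order of well-spaced
40-locus frameworks from 355-line panels in at least 90 % of seeds;
near-coincident loci are genuinely unidentifiable and collapse or tie
instead.

### Breaks and bins

Obligate breaks are adjacent 1/0 transitions per line after dropping
missing calls, summed over lines; bin-scoped counts restrict to the loci
between a bin's distal and proximal markers.  Deletion bins are runs of
identical presence patterns across the terminal-deletion lines along the
map; 18 distinct breakpoints yield 19 pattern blocks, and supplying the
short/long-arm boundary splits the spanning block, giving the published
20-bin structure.  Bins are named by the line flipping at their proximal
boundary.  Resolution summaries (`mapSummaries()`) report cR/locus, kb/cR
and Mb/break, with zero-break scopes reported as undefined (`NA`), never
infinity.

## 5. Integration

Contigs are placed at the median locus of their anchored markers (an even
split breaks toward the more distal locus, logged); orientation is the sign
of the Spearman correlation between marker CB coordinates and centiray
positions and requires two distinct loci — contigs with two markers at one
locus stay unoriented.  A contig is chimeric when its marker positions form
two clusters more than `gapCR = 50` centirays apart (a package default; the
source gives none); the split point is the largest CB gap between the
marker-bearing members of the two clusters.  Median rather than mean
placement is deliberate: it is robust to a single mis-anchored marker.
Within a shared locus, contigs carrying syntenic genes are ranked by the
median ortholog position on the reference chromosome; unlinked contigs
keep a stable rank after them.

## 6. Comparative analysis

Gene markers are de-duplicated by greedy clustering at 98 % identity
(longest representative, ties by id).  Genes annotated on sequence contigs
transfer to BAC contigs through tags that hit exactly one sequence contig;
a sequence contig hit by tags of distant BAC contigs is discarded whole.
Rearrangement detection segments the reference positions of syntenic
genes, in map order, into maximal monotone runs: runs share their turning
points, one interrupting gene per ten may be skipped when the run resumes
(real ortholog tables are noisy), and a reference jump larger than the
translocation offset (default 5 Mb) always ends a run so that displaced
blocks form their own runs.  The expected colinear orientation is
ascending; descending runs of at least `minBlockSize = 3` genes are
inversions, runs displaced by more than the offset from a resistant
(Theil-Sen) colinear fit on the remaining genes are translocations, and
both at once is a translocation (inversion).  When the whole order is
reversed and no internal blocks exist, a single whole-span inversion is
reported — so a globally reversed chromosome is one inversion, while
reversing the input of a map that contains one inversion returns that same
inversion.

## 7. The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* a chromosome with arms and an optional NOR-like interval; gene positions
  drawn with intensity `1 + g·d(x)` where `d` is per-arm distance from the
  centromere (a positive `g` reproduces telomere-increasing gene density);
* a BAC library with Gaussian insert lengths (default mean 130 kb, sd
  13 kb), clone count `coverage x length / insertMean`, and contaminants at
  rate `1 - purity` (sorting purities of 85-92 % are typical);
* WGP tags as site identifiers spaced `insertMean / meanTagsPerBac` apart
  (default mean 20.6 tags/BAC), with independent per-tag dropout;
  contaminant clones draw from a disjoint site universe per foreign
  chromosome except for 2 % shared-repeat collisions, which make the
  contamination screen non-trivial;
* an RH panel (default 355 lines) with Poisson break counts and uniform
  break positions, each fragment retained independently.  The break-count
  distribution of real gamma-irradiated panels is not standardised; Poisson
  is a modelling choice exposed in the configuration.  The default mean of
  3.6 breaks/line is the published break total divided by the panel size;
  the default retention of 0.7 reflects seed-derived wheat panels, where
  most of the chromosome survives irradiation;
* terminal-deletion lines as single-breakpoint truncations;
* ortholog tables with colinear reference positions (scaled by 0.1,
  roughly the wheat-to-rice size ratio), explicit inversion/translocation
  blocks, and a nonsyntenic fraction defaulting to 477/2015.

What the simulator does **not** emulate: sequencing error inside tags,
correlated (repeat-driven) tag dropout, position-dependent RH retention,
segregation distortion, or assembly collapse over tandem repeats such as
the NOR core.  Passing tests therefore demonstrate correctness of the
algorithms under the stated models, not robustness to every artefact of
real libraries.

Randomness uses one master seed with fixed per-component child seeds
(`(seed mod 2000003) * 1000 + component offset`), so each component is
independently reproducible and all child seeds stay below 2^31.

## 8. Numerical choices and problem sizes

Scores and likelihoods are computed in log space; optimisations in `theta`
use `stats::optimize()` on `[1e-9, 1 - 1e-9]` with boundary checks; `r`
estimates are clamped away from 0 and 1.  Degenerate inputs follow the
principle "undefined, not infinite": zero informative lines is an error,
zero breaks gives `NA` resolution, indeterminate clones are never foreign.

Tests and the acceptance script run simulations sized for a desktop
machine: arms of 3-10 Mb at 6-10x coverage for assembly (hundreds to a few
thousand clones), 355-line panels with 25-150 markers for RH mapping,
20-seed replication for order recovery, and a 100-contig chromosome for
placement accuracy.  These sizes were chosen so that every stochastic
check has comfortable statistical margin while the whole suite stays
fast; the algorithms scale to full-chromosome inputs (tens of thousands of
clones) through the sparse pair-counting step, which only enumerates clone
pairs that share tags.

## 9. Known limitations

* The CB consensus is a seriation heuristic; heavily duplicated regions
  can interleave clone coordinates, which the Q-clone rule flags rather
  than repairs.
* The equal-retention RH model mis-states likelihoods when retention
  varies strongly along the chromosome (e.g. near centromeres).
* Chimera detection needs two anchored markers per fragment; chimeras
  joining an unanchored fragment are invisible.
* Rearrangement classification attributes every displacement to the
  wheat lineage's reference comparison; resolving which lineage moved
  requires multiple references, which the package treats as independent
  link tables.
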