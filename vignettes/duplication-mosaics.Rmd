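---
title: "Dissecting segmental duplication mosaics: methods and design"
author: "SDmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting segmental duplication mosaics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SDmosaic)
library(GenomicRanges)
```

## The problem

Clusters of segmental duplications (SDs, also called low copy repeats)
such as the LCR22 blocks on human 22q11.2 are mosaics: the same
stretches of sequence occur at many positions, pasted together in
different orders by successive duplication events. Pairwise SD
records - two intervals, an orientation, and a fraction of matching
bases, as in the UCSC genomicSuperDups track - describe this homology
one pair at a time, but not its atomic structure. SDmosaic decomposes
such a region into *duplication subunits*: the smallest contiguous
segments that have each participated in at least one duplication event
as a unit. Subunit boundaries are candidate rearrangement breakpoints;
subunits recurring at the ends of many duplications are candidate
drivers of disease-associated rearrangements mediated by non-allelic
homologous recombination (NAHR).

## Decomposition by breakpoint propagation

The decomposition operates at interval resolution. Because the two
sides of a pair are copies of one another, any breakpoint that falls
inside one side must have a counterpart at the corresponding position
of the other side. Starting from the set of all duplicon endpoints,
`propagateBreakpoints()` projects every breakpoint through every
pair's coordinate map - proportional and orientation-aware, since no
base-level alignment is retained by the input format - and repeats
until no projection lands farther than `mergeTolerance` (default
20 b) from an existing breakpoint. Positions within the tolerance are
clustered and represented by the cluster minimum, which makes the
output deterministic. Segments between consecutive breakpoints that
are covered by at least one duplicon become subunits
(`buildSubunits()`); slivers shorter than `minSubunitLength` (default
30 b, the smallest subunit such analyses report on real data) are
merged into the neighbouring segment with which they share the most
duplicon coverage, ties going left.

The tolerance default is deliberately conservative: two independent
interval-resolution decompositions of the same region have been
observed to drift by up to 200 b at shared boundaries, so 20 b merges
only near-coincident projections while preserving genuine short
subunits.

### The per-base oracle

`oracleDecompose()` is an exact, tolerance-free reference
implementation used in validation: every covered base is linked to its
partner base under each pair's map, the relation is closed by
union-find, and a boundary is placed between adjacent bases whose
paralog-position sets are not shift-consistent (sorted classes must
correspond elementwise at distance one, which handles inverted copies
whose neighbours run backwards). It refuses regions above 1 Mb of
covered sequence; it exists to check the fast path, not to replace it.

A known limitation, discovered while validating: when duplicon sides
*partially* overlap each other, the composition of their maps can send
a region onto itself with a small net shift or a reflection
(quasi-periodic or palindromic structure, as in tandem arrays). There
the per-base truth has sparse boundaries, while endpoint propagation
fragments the region down to the tolerance scale. Interval-resolution
decomposition over-cuts such structures by construction. The oracle
equivalence is therefore claimed - and tested - on *laminar*
instances, where any two duplicon sides are disjoint or nested; nested
sides still exercise transitive propagation across pair chains.

## Families, blocks, and the duplication map

Subunits are grouped into paralogous families
(`classifyFamilies()`): an edge connects two subunits when some pair
maps one onto the other with reciprocal overlap at least 0.8 and
identity at least 0.90 (the conventional SD identity floor), and
families are the connected components with two or more members.
Identity is inherited from the pair's `fracMatch` by default; a
sequence mode (pairwise alignment of subunit sequences) is available
when the reference is supplied, since the inputs alone cannot decide
which the original analysis used. Subunits whose component is a
singleton are reported unassigned rather than forced into a family.

`assignBlocks()` chains subunits whose gaps are strictly below 500 kb
into LCR-style blocks - the single-linkage rule that reproduces
block-scale structure while tolerating unique sequence embedded inside
blocks. `mergeLoci()` merges overlapping duplicons into duplication
loci; `groupLoci()` connects loci sharing a family; and
`alignToAnchor()` aligns every locus to its group's largest locus by
the longest common contiguous run of family labels, testing both
orientations. Matching label strings rather than bases keeps the map
robust to the absent base-level alignments and mirrors how such maps
are drawn. The map is hierarchical, not directional: which copy was
donor and which acceptor is generally not identifiable from identity
alone, so no direction is inferred. `breakpointFamilies()` tallies the
families at the two ends of every placed member locus; a family is
*recurrent* above five end-occurrences (strict), and its Alu adjacency
is assessed within ±10 b windows.

## Synteny calling

`callSynteny()` classifies each subunit in a related species using
unique-sequence landmarks, in fixed precedence order: **present** when
an alignment block covering at least half of the subunit falls between
the flanking anchors' target positions; **present (rescued)** when the
expected target window is at least half assembly gap (`N`) and the
subunit aligns on an unplaced/random contig - tolerating draft-genome
artefacts; **absent** when no such alignment exists and the target
inter-anchor distance has collapsed below half the human distance
(the duplication simply is not there); otherwise **ambiguous**. The
coverage and N-fraction cutoffs (both 0.5) are package choices - the
qualitative rules come from practice with draft primate assemblies,
which do not quantify them. "Present only in human" is reported
strictly: a subunit must be called absent in *every* queried species;
ambiguous calls never count toward human specificity.

## CNV calling and breakpoint annotation

`callCNVs()` applies the alignment-gap rule: an unaligned reference
stretch longer than 200 b between consecutive blocks of a clone is a
loss, an unaligned clone stretch a gain anchored at the reference
junction (strictly greater than 200; a 200 b gap is ignored). Size
classes are small (< 1 kb), intermediate (1-10 kb, bounds inclusive)
and large (> 10 kb); the inclusive bounds are fixed by the worked
catalog, where 1,467 b and 8,981 b records are intermediate.
`paralogFlanked()` reports CNVs whose two breakpoints fall in
subunits of one family - the configuration NAHR produces.

`annotateFlankFeatures()` assigns each breakpoint the repeat
overlapping it or within ±10 b (nearest wins; overlap beats proximity;
leftmost breaks ties), `microHomology()` calls homology when two
10-mers agree at strictly more than 80% of positions (at least 9/10),
and `classifyNAHR()` reduces a feature pair to a mechanism class. Two
choices matter and are fixed by reproducing the worked catalog's
classification: Alu subfamilies are mutually homologous (AluY-AluSx
counts as an Alu pair - Alu elements are alignable regardless of
subfamily), and simple/low-complexity repeats are never treated as
homologous pairs. `scanMotif()` counts degenerate IUPAC motif hits
(default the recombination hotspot 13-mer `CCNCCNTNNCCNC`) on both
strands, overlapping occurrences included; strand handling is
toggleable since conventions differ.

## Permutation enrichment

`permutePlacements()` builds the null by placing each query interval
uniformly at random, length-preserved, within the universe -
independently across queries, the simplest model consistent with
random placement; a collision-free variant was deliberately not made
the default since observed features do overlap. The universe is the
analysis region by default, not the whole genome, because the
comparisons are intra-region. `empiricalP()` uses the add-one
convention `p = (r + 1)/(n + 1)`, which never returns zero; with the
default 1,000 replicates the smallest attainable p is about 0.001.
Calibration is tested by drawing the observed statistic from the same
placement process with a fresh null per dataset, where the p-values
are uniform by construction.

## The simulator and what it does (not) show

`simulateGenome()` generates the study conditions: a random background
(48% GC, matching gene-rich duplication clusters), planted synthetic
Alu-like (300 b) and L1-like (2 kb) decoy consensi at 3 copies per
10 kb, and a scripted event history replayed oldest first. Between
events the whole genome accumulates substitutions at 0.0015 per base
per age unit per lineage, so a pair of copies created `a` units ago
diverges by about `2 x 0.0015 x a` - the 3%-per-10-units molecular
clock conventionally used to date primate SDs, with ages read as
millions of years. Default split ages (chimpanzee 6, orangutan 16,
macaque 25) bracket the default event ages (up to 20) so that derived
species show both shared and missing duplications. Species genomes
are the lineage state at the split plus split-age worth of independent
substitutions; clone haplotypes apply scripted indels (> 200 b), with
NAHR-style deletions validated to span two same-label planted repeats
and their emitted alignments placing the gap at the left-most
consistent position, reproducing the breakpoint ambiguity real
aligners show inside homology tracts.

Deliberate simplifications, and what they imply for the tests: the
background mutation process has substitutions only (no indels), so
truth boundaries stay exact and identity thresholds are still
exercised; there is no gene conversion, which in real data homogenises
paralogs and biases identity-based dating; decoy repeats are synthetic
strings, so only their labels and positions matter; destinations may
not fall inside a previously created copy (copy-of-copy nesting is
allowed, interruption is not), keeping every duplicon a contiguous
interval as the pairwise input format assumes. Passing recovery tests
on these genomes therefore validates the algorithms' logic, not their
robustness to conversion, assembly error, or alignment noise in real
genomes. Problem sizes used in the validation suite (100-200 kb
genomes, 3-10 events, 100 random toy instances for the oracle
comparison) were chosen to exercise every code path at desk scale.

## Numerical and degeneracy conventions

Coordinates are 1-based closed `GRanges` internally - the Bioconductor
convention - with conversion at the I/O boundary: BED files are
written and read 0-based half-open, and emitted report tables are
1-based as printed tables in this field are. Breakpoints live in cut
coordinates (a breakpoint at `c` separates base `c - 1` from base
`c`). Ties are broken deterministically throughout: cluster minima for
snapped breakpoints, leftmost for anchor selection among equal-length
loci, left neighbour for sliver merging, leftmost repeat for equal
breakpoint distances. Degenerate inputs return empty, typed results
(empty pair sets, empty universes, all-`N` windows) rather than
errors, except where the input is contradictory (colliding event
destinations, overlapping clone blocks), which aborts with the
offending record named.
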