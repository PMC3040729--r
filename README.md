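# SDmosaic

Decomposition and duplication-history analysis of segmental
duplication mosaics.

Regions rich in segmental duplications (SDs, low copy repeats) — the
human 22q11.2 LCR22 cluster being the canonical example — are mosaics
of sequence fragments pasted together by successive duplication
events. These regions mediate non-allelic homologous recombination
(NAHR) and the genomic disorders it causes, but pairwise SD records
(two intervals + orientation + fraction identity, as in the UCSC
`genomicSuperDups` track) describe the homology one pair at a time,
not its atomic structure. SDmosaic is for genome biologists who want
to turn such pairwise records into an explicit architecture:

- **Duplication subunits** — the smallest contiguous segments involved
  in at least one duplication event as a unit. Every duplicon endpoint
  is a breakpoint; because the two sides of a pair are copies, a
  breakpoint inside one side implies one at the mapped position of the
  other. `propagateBreakpoints()` iterates these projections to a
  fixpoint (interval-resolution A-Bruijn-style decomposition), and
  `buildSubunits()` / `classifyFamilies()` turn the boundary set into
  non-overlapping subunits and paralogous families (connected
  components under reciprocal-overlap ≥ 0.8 and identity ≥ 0.90).
- **Blocks and the duplication map** — `assignBlocks()` chains
  subunits separated by < 500 kb; `mergeLoci()`, `groupLoci()` and
  `alignToAnchor()` reconstruct the hierarchical map of putative
  events by aligning every duplication locus to its group's largest
  locus via family-label strings; `breakpointFamilies()` flags
  families recurring (> 5 times) at event ends and their Alu
  adjacency.
- **Cross-species synteny** — `callSynteny()` classifies each subunit
  in a related genome as present / rescued / absent / ambiguous using
  unique-sequence landmarks, an N-gap + unplaced-contig rescue rule,
  and a collapsed-window (target distance < 0.5 × human) absence rule.
- **CNV calling and breakpoint annotation** — `callCNVs()` applies the
  alignment-gap rule (> 200 bp) to clone-versus-reference alignments;
  `paralogFlanked()` finds CNVs whose two breakpoints fall in
  same-family subunits; `annotateFlankFeatures()`, `microHomology()`
  (> 80% of 10 bp), `classifyNAHR()` and `scanMotif()`
  (`CCNCCNTNNCCNC`, both strands) characterise breakpoints.
- **Permutation enrichment** — `permutePlacements()`, `empiricalP()`
  (add-one rule), `foldEnrichment()` and `baseFractionOverlap()` for
  length-preserving random-placement tests.
- **A ground-truthed simulator** — `simulateGenome()` replays scripted
  duplication histories under a molecular clock (pair divergence
  ≈ 2 × rate × age), plants Alu/L1-like decoy repeats, derives species
  genomes by replaying only events older than each split, and emits
  clone haplotypes with planted indels, so every stage is testable
  offline.

## Worked example

The bundled seven-pair fixture reproduces the classic five-locus
decomposition cartoon:

```r
library(SDmosaic)
p <- fig1Fixture()
p
#> SDPairSet with 7 duplicon pair(s)
#>   identity: 94.0%-98.0% | inverted: 0
#>   span: chr22:17100001-17143000

dec <- decomposeSDs(p)
subunitStats(dec$subunits)
#>    n mean_bp median_bp min_bp max_bp
#> 1 15    1000      1000   1000   1000

dec$families
#>   family_id n_members     member_ids
#> 1      F001         2      S001,S006
#> 2      F002         3 S002,S007,S013
#> 3      F003         2      S003,S008
#> 4      F004         3 S004,S009,S010
#> 5      F005         3 S005,S011,S014
#> 6      F006         2      S012,S015

map <- buildDuplicationMap(p, dec$subunits)
map
#> DuplicationMap: 5 duplication loci in 1 group(s)
#>   1 anchor(s); 4 member locus/loci placed on anchors
```

Seven duplicon pairs decompose into 15 subunits forming six paralogous
families; the duplicons merge into five duplication loci that share
families, so they form one group whose anchor (the largest, 5 kb
locus) is what the other four loci align to. The anchor accounts for a
third of the locus bases (`topLevelFraction()` returns 0.33): the rest
of the duplicated sequence is explainable as copies of it.

The same functions run on real data: read the UCSC track with
`readSDPairs(path, region = GRanges("chr22", IRanges(17000000,
24000000)))`, RepeatMasker annotations with `readRepeatMasker()`, and
chain everything with `runPipeline()`.

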