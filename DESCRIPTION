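Package: SDmosaic
Title: Decomposition and Duplication-History Analysis of Segmental Duplication Mosaics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the mosaic architecture of clustered
    segmental duplications (low copy repeats) such as the human 22q11.2
    LCR22 region. Pairwise duplication records are decomposed into
    fundamental duplication subunits by breakpoint propagation, subunits
    are classified into paralogous families and genomic blocks, and a
    hierarchical map of putative duplication events is reconstructed by
    merging duplicons into loci, grouping loci through shared families,
    and aligning each locus to its group anchor. Companion modules call
    subunit presence/absence in related species from pairwise alignment
    anchors, call copy-number variants from clone-versus-reference
    alignment gaps, annotate breakpoints with flanking repeats,
    micro-homology and a recombination hotspot motif, and test feature
    enrichment by random length-preserving placement. A simulator with
    scripted duplication histories, planted repeats, derived species
    genomes and clone haplotypes provides full ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: GenomicVariation, CopyNumberVariation, StructuralVariation,
    Alignment, Annotation, SequenceMatching
RoxygenNote: 7.3.3
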