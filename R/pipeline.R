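#' Run the full analysis pipeline
#'
#' Orchestrates the stages in dependency order on whatever inputs are
#' provided: decomposition into subunits and families, block
#' assignment, the hierarchical duplication map (plus recurrent
#' breakpoint families when repeats are given), per-species synteny
#' calls, and CNV calling with breakpoint annotation. Stages whose
#' inputs are absent are skipped; every run is deterministic for fixed
#' inputs.
#'
#' @param pairs An [SDPairSet-class] (or a path readable by
#'   [readSDPairs()]).
#' @param params Decomposition parameters ([decompositionParams()]).
#' @param maxGap Block chaining gap (default 500000).
#' @param repeats Optional repeat `GRanges` (or RepeatMasker `.out`
#'   path).
#' @param cloneBlocks Optional clone-versus-reference alignment blocks
#'   (data frame or path).
#' @param speciesAlignments Optional named list of alignment-block
#'   data frames (or paths), one per species.
#' @param region Optional `GRanges` defining the analysis region; by
#'   default the span of the input pairs. Unique intervals for the
#'   synteny landmark map are its complement of the duplicon union.
#' @param minGap CNV gap threshold (default 200).
#' @param W Breakpoint annotation window (default 10).
#' @param outdir Optional directory; when given, stage outputs are
#'   written as TSV/BED files.
#' @return A list with elements `subunits`, `families`, `blocks`,
#'   `block_summary`, `map` (a [DuplicationMap-class]),
#'   `breakpoint_families`, `top_level`, `synteny`,
#'   `synteny_summary`, `cnvs`, `size_classes`, and `stats`.
#' @export
runPipeline <- function(pairs, params = decompositionParams(),
                        maxGap = 500000, repeats = NULL,
                        cloneBlocks = NULL, speciesAlignments = list(),
                        region = NULL, minGap = 200, W = 10,
                        outdir = NULL) {
  if (is.character(pairs)) pairs <- readSDPairs(pairs)
  if (is.character(repeats)) repeats <- readRepeatMasker(repeats)
  if (is.character(cloneBlocks))
    cloneBlocks <- readAlignmentBlocks(cloneBlocks)
  speciesAlignments <- lapply(speciesAlignments, function(b)
    if (is.character(b)) readAlignmentBlocks(b) else b)
  if (!length(pairs)) stop("no SD pairs; nothing to analyse")

  dec <- decomposeSDs(pairs, params)
  bl <- assignBlocks(dec$subunits, maxGap)
  subunits <- bl$subunits
  map <- buildDuplicationMap(pairs, subunits)
  bpfam <- breakpointFamilies(map, repeats, W = W)
  top <- topLevelFraction(map, pairs)

  synteny <- NULL
  if (length(speciesAlignments)) {
    if (is.null(region)) {
      allr <- c(pairs@first, pairs@second)
      region <- GenomicRanges::GRanges(
        .one_chrom(allr),
        IRanges::IRanges(min(BiocGenerics::start(allr)),
                         max(BiocGenerics::end(allr))))
    }
    sd_union <- GenomicRanges::reduce(c(pairs@first, pairs@second),
                                      ignore.strand = TRUE)
    uniq <- GenomicRanges::setdiff(region, sd_union,
                                   ignore.strand = TRUE)
    synteny <- do.call(rbind, lapply(names(speciesAlignments),
      function(sp) {
        blk <- speciesAlignments[[sp]]
        lm <- buildLandmarkMap(uniq, blk)
        callSynteny(subunits, lm, blk, sp)
      }))
  }
  block_summary <- blockSummary(bl$blocks, subunits, synteny)

  cnvs <- NULL; size_cls <- NULL
  if (!is.null(cloneBlocks) && nrow(cloneBlocks)) {
    cnvs <- callCNVs(cloneBlocks, minGap)
    if (!is.null(repeats))
      cnvs <- annotateFlankFeatures(cnvs, repeats, W)
    size_cls <- sizeClasses(cnvs)
  }

  res <- list(subunits = subunits, families = dec$families,
              blocks = bl$blocks, block_summary = block_summary,
              map = map, breakpoint_families = bpfam,
              top_level = top,
              synteny = synteny,
              synteny_summary = if (!is.null(synteny))
                syntenySummary(synteny) else NULL,
              cnvs = cnvs, size_classes = size_cls,
              stats = subunitStats(subunits))

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    su_bed <- subunits
    su_bed$name <- ifelse(is.na(subunits$family_id), "unassigned",
                          subunits$family_id)
    writeBedFile(su_bed, file.path(outdir, "subunits.bed"))
    writeTsvFile(dec$families, file.path(outdir, "families.tsv"))
    writeTsvFile(block_summary, file.path(outdir, "block_summary.tsv"))
    writeTsvFile(placements(map), file.path(outdir, "placements.tsv"))
    writeTsvFile(bpfam$report,
                 file.path(outdir, "breakpoint_families.tsv"))
    if (!is.null(synteny))
      writeTsvFile(synteny, file.path(outdir, "synteny_calls.tsv"))
    if (!is.null(cnvs))
      writeTsvFile(cnvs, file.path(outdir, "cnv_calls.tsv"))
  }
  res
}
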