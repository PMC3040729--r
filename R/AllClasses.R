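#' SDPairSet: a set of pairwise segmental-duplication records
#'
#' Container for pairwise segmental duplication (SD) records of the
#' genomicSuperDups kind: each record links two genomic intervals
#' (duplicons) with an orientation and a fraction of matching bases.
#' No base-level alignment is retained; coordinate transfer between the
#' two sides of a pair uses an orientation-aware proportional map.
#'
#' @slot first A [GenomicRanges::GRanges] with one range per record
#'   (the "A" side of each duplicon pair).
#' @slot second A [GenomicRanges::GRanges], parallel to `first`
#'   (the "B" side).
#' @slot orientation Character vector, `"same"` or `"inverted"`, one per
#'   record.
#' @slot fracMatch Numeric vector in `[0, 1]`, one per record: the
#'   fraction of aligned bases identical between the two sides.
#'
#' @seealso [SDPairSet()] for construction, [readSDPairs()] to parse the
#'   tab dialect, [propagateBreakpoints()] for decomposition.
#' @exportClass SDPairSet
setClass("SDPairSet",
  representation(
    first = "GRanges",
    second = "GRanges",
    orientation = "character",
    fracMatch = "numeric"
  )
)

setValidity("SDPairSet", function(object) {
  n <- length(object@first)
  msg <- character()
  if (length(object@second) != n)
    msg <- c(msg, "'first' and 'second' must have equal length")
  if (length(object@orientation) != n)
    msg <- c(msg, "'orientation' must have one entry per pair")
  if (length(object@fracMatch) != n)
    msg <- c(msg, "'fracMatch' must have one entry per pair")
  if (n && !all(object@orientation %in% c("same", "inverted")))
    msg <- c(msg, "orientation values must be 'same' or 'inverted'")
  if (n && (anyNA(object@fracMatch) ||
            any(object@fracMatch < 0 | object@fracMatch > 1)))
    msg <- c(msg, "fracMatch values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an SDPairSet
#'
#' @param first,second `GRanges` of equal length holding the two sides
#'   of each duplicon pair.
#' @param orientation Character vector (`"same"`/`"inverted"`), recycled
#'   if of length 1.
#' @param fracMatch Numeric vector of per-pair identity fractions,
#'   recycled if of length 1.
#' @return An [SDPairSet-class] object.
#' @examples
#' gr1 <- GenomicRanges::GRanges("chr22", IRanges::IRanges(101, 200))
#' gr2 <- GenomicRanges::GRanges("chr22", IRanges::IRanges(501, 600))
#' SDPairSet(gr1, gr2, "same", 0.97)
#' @export
SDPairSet <- function(first, second, orientation = "same", fracMatch = 1) {
  n <- length(first)
  if (length(orientation) == 1L) orientation <- rep(orientation, n)
  if (length(fracMatch) == 1L) fracMatch <- rep(fracMatch, n)
  methods::new("SDPairSet",
    first = first, second = second,
    orientation = as.character(orientation),
    fracMatch = as.numeric(fracMatch)
  )
}

#' DuplicationMap: hierarchical map of putative duplication events
#'
#' Result container for the locus-level reconstruction: duplication loci
#' (maximal regions of overlapping duplicons), their grouping by shared
#' paralogous subunit families, and the alignment of every member locus
#' to its group's anchor (largest) locus.
#'
#' @slot loci A `GRanges` of duplication loci with metadata columns
#'   `locus_id` and `group_id`.
#' @slot placements A `data.frame` with one row per locus: columns
#'   `locus_id`, `group_id`, `is_anchor`, `anchor_id`, `anchor_offset`
#'   (0-based offset of the matched run in the anchor's subunit string),
#'   `orientation`, `n_matched`, `n_disrupted`.
#' @slot subunits The subunit `GRanges` (with `subunit_id`, `family_id`)
#'   the map was built from.
#' @exportClass DuplicationMap
setClass("DuplicationMap",
  representation(
    loci = "GRanges",
    placements = "data.frame",
    subunits = "GRanges"
  )
)

setValidity("DuplicationMap", function(object) {
  msg <- character()
  need <- c("locus_id", "group_id", "is_anchor", "anchor_id",
            "anchor_offset", "orientation", "n_matched", "n_disrupted")
  if (nrow(object@placements) && !all(need %in% names(object@placements)))
    msg <- c(msg, paste("placements must have columns:",
                        paste(need, collapse = ", ")))
  if (length(object@loci) &&
      is.null(object@loci$locus_id))
    msg <- c(msg, "loci must carry a 'locus_id' metadata column")
  if (length(msg)) msg else TRUE
})
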