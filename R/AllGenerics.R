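#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Accessors for SDPairSet
#'
#' `firstRanges()` and `secondRanges()` return the two sides of each
#' duplicon pair; `pairOrientation()` the per-pair orientation;
#' `fracMatch()` the per-pair identity fraction.
#'
#' @param x An [SDPairSet-class].
#' @return A `GRanges` (ranges accessors) or vector parallel to the
#'   pairs.
#' @name SDPairSet-accessors
#' @aliases firstRanges secondRanges pairOrientation fracMatch
NULL

#' @rdname SDPairSet-accessors
#' @export
setGeneric("firstRanges", function(x) standardGeneric("firstRanges"))
#' @rdname SDPairSet-accessors
#' @export
setGeneric("secondRanges", function(x) standardGeneric("secondRanges"))
#' @rdname SDPairSet-accessors
#' @export
setGeneric("pairOrientation", function(x) standardGeneric("pairOrientation"))
#' @rdname SDPairSet-accessors
#' @export
setGeneric("fracMatch", function(x) standardGeneric("fracMatch"))

#' Accessors for DuplicationMap
#'
#' @param x A [DuplicationMap-class].
#' @return `dupLoci()` returns the locus `GRanges`; `placements()` the
#'   per-locus anchor-alignment table; `mapSubunits()` the subunit
#'   `GRanges` the map was built from.
#' @name DuplicationMap-accessors
#' @aliases dupLoci placements mapSubunits
NULL

#' @rdname DuplicationMap-accessors
#' @export
setGeneric("dupLoci", function(x) standardGeneric("dupLoci"))
#' @rdname DuplicationMap-accessors
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))
#' @rdname DuplicationMap-accessors
#' @export
setGeneric("mapSubunits", function(x) standardGeneric("mapSubunits"))
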