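#' @rdname SDPairSet-accessors
#' @export
setMethod("firstRanges", "SDPairSet", function(x) x@first)

#' @rdname SDPairSet-accessors
#' @export
setMethod("secondRanges", "SDPairSet", function(x) x@second)

#' @rdname SDPairSet-accessors
#' @export
setMethod("pairOrientation", "SDPairSet", function(x) x@orientation)

#' @rdname SDPairSet-accessors
#' @export
setMethod("fracMatch", "SDPairSet", function(x) x@fracMatch)

#' @describeIn SDPairSet Number of duplicon pairs.
#' @param x An `SDPairSet`.
#' @export
setMethod("length", "SDPairSet", function(x) length(x@first))

#' @describeIn SDPairSet Subset pairs.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "SDPairSet", function(x, i, j, ..., drop = TRUE) {
  methods::initialize(x,
    first = x@first[i], second = x@second[i],
    orientation = x@orientation[i], fracMatch = x@fracMatch[i]
  )
})

setMethod("show", "SDPairSet", function(object) {
  n <- length(object)
  cat("SDPairSet with", n, "duplicon pair(s)\n")
  if (n) {
    cat(sprintf("  identity: %.1f%%-%.1f%% | inverted: %d\n",
                100 * min(object@fracMatch), 100 * max(object@fracMatch),
                sum(object@orientation == "inverted")))
    span <- range(c(BiocGenerics::start(object@first),
                    BiocGenerics::start(object@second),
                    BiocGenerics::end(object@first),
                    BiocGenerics::end(object@second)))
    cat(sprintf("  span: %s:%d-%d\n",
                as.character(GenomicRanges::seqnames(object@first))[1],
                span[1], span[2]))
  }
  invisible(NULL)
})

#' Combine SDPairSet objects
#' @param x,... `SDPairSet` objects to concatenate.
#' @return A single `SDPairSet`.
#' @export
setMethod("c", "SDPairSet", function(x, ...) {
  args <- c(list(x), list(...))
  methods::initialize(x,
    first = do.call(c, lapply(args, function(p) p@first)),
    second = do.call(c, lapply(args, function(p) p@second)),
    orientation = unlist(lapply(args, function(p) p@orientation)),
    fracMatch = unlist(lapply(args, function(p) p@fracMatch))
  )
})
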