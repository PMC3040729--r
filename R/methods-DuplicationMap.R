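#' @rdname DuplicationMap-accessors
#' @export
setMethod("dupLoci", "DuplicationMap", function(x) x@loci)

#' @rdname DuplicationMap-accessors
#' @export
setMethod("placements", "DuplicationMap", function(x) x@placements)

#' @rdname DuplicationMap-accessors
#' @export
setMethod("mapSubunits", "DuplicationMap", function(x) x@subunits)

setMethod("show", "DuplicationMap", function(object) {
  nl <- length(object@loci)
  ng <- length(unique(object@loci$group_id))
  cat("DuplicationMap:", nl, "duplication loci in", ng, "group(s)\n")
  if (nrow(object@placements)) {
    placed <- sum(!object@placements$is_anchor &
                  !is.na(object@placements$anchor_offset))
    cat(sprintf("  %d anchor(s); %d member locus/loci placed on anchors\n",
                sum(object@placements$is_anchor), placed))
  }
  invisible(NULL)
})
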