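# Internal helpers shared across modules.
#
# Decomposition works in "cut coordinates": a cut at c separates base
# c-1 from base c (1-based closed genomic bases). A duplicon [s, e]
# owns cuts s and e+1; a segment between cuts c1 < c2 is the range
# [c1, c2-1] of width c2 - c1.

# Cut-space endpoints of an SDPairSet side.
.cuts_of <- function(gr) {
  cbind(BiocGenerics::start(gr), BiocGenerics::end(gr) + 1L)
}

# Project cut positions through one pair's proportional map.
# `from`/`to`: numeric length-2 cut intervals c(lo, hi); inverted flips.
.project_cut <- function(p, from, to, inverted) {
  w_from <- from[2] - from[1]
  w_to <- to[2] - to[1]
  rel <- (p - from[1]) / w_from
  if (inverted) to[2] - rel * w_to else to[1] + rel * w_to
}

# Cluster sorted numeric positions: group values whose consecutive gap
# is <= tol, represent each cluster by its minimum (deterministic).
.snap_positions <- function(pos, tol) {
  if (!length(pos)) return(numeric())
  pos <- sort(pos)
  grp <- cumsum(c(TRUE, diff(pos) > tol))
  as.numeric(tapply(pos, grp, min))
}

# Single chromosome name of a GRanges (error if mixed).
.one_chrom <- function(gr) {
  ch <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(ch) > 1L)
    stop("expected records on a single chromosome, got: ",
         paste(ch, collapse = ", "))
  ch
}

# Connected components over n nodes given an edge matrix (2 columns of
# node indices); returns integer membership vector of length n.
# Deterministic relabelling: components numbered by smallest member.
.components <- function(n, edges) {
  if (n == 0L) return(integer())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)))
  memb <- as.integer(igraph::components(g)$membership)
  k <- max(memb)
  first <- vapply(seq_len(k), function(cc) min(which(memb == cc)), 1L)
  relab <- as.integer(rank(first, ties.method = "first"))
  relab[memb]
}

.stopifnot_scalar <- function(x, what) {
  if (length(x) != 1L || is.na(x)) stop(what, " must be a non-NA scalar")
  invisible(x)
}
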