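# Exact per-base paralogy closure, shared by the test oracle and the
# simulator's ground-truth construction. Independent of the fast
# breakpoint-propagation path: it never projects endpoints, it unions
# individual bases.

# membership of each covered base in the paralogy closure
# pairs: SDPairSet; returns list(pos = covered positions sorted,
# comp = component id per position)
.base_closure <- function(pairs) {
  sidesA <- pairs@first
  sidesB <- pairs@second
  inv <- pairs@orientation == "inverted"
  pos_list <- list()
  edge_list <- list()
  for (i in seq_along(inv)) {
    a <- BiocGenerics::start(sidesA)[i]:BiocGenerics::end(sidesA)[i]
    lenA <- length(a)
    sB <- BiocGenerics::start(sidesB)[i]; eB <- BiocGenerics::end(sidesB)[i]
    lenB <- eB - sB + 1L
    off <- if (lenA == 1L) rep(0, lenA) else
      (a - a[1]) * (lenB - 1) / (lenA - 1)
    b <- if (inv[i]) round(eB - off) else round(sB + off)
    pos_list[[i]] <- c(a, sB:eB)
    edge_list[[i]] <- cbind(a, b)
  }
  pos <- sort(unique(unlist(pos_list)))
  em <- do.call(rbind, edge_list)
  ei <- cbind(match(em[, 1], pos), match(em[, 2], pos))
  comp <- .components(length(pos), ei)
  list(pos = pos, comp = comp)
}

# boundary (cut) positions implied by a base closure
.closure_boundaries <- function(cl) {
  pos <- cl$pos; comp <- cl$comp
  if (!length(pos)) return(numeric())
  members <- split(pos, comp)
  run_break <- c(TRUE, diff(pos) != 1)
  cuts <- c(pos[run_break], pos[c(run_break[-1], TRUE)] + 1)
  # interior consistency: between adjacent covered bases p, p+1 the
  # sorted paralog sets must differ elementwise by exactly +/-1
  adj <- which(!run_break)          # pos[adj] == pos[adj-1] + 1
  if (length(adj)) {
    key <- paste(comp[adj - 1L], comp[adj])
    uk <- !duplicated(key)
    ok_map <- vapply(which(uk), function(w) {
      m1 <- sort(members[[as.character(comp[adj[w] - 1L])]])
      m2 <- sort(members[[as.character(comp[adj[w]])]])
      length(m1) == length(m2) && all(abs(m2 - m1) == 1)
    }, TRUE)
    names(ok_map) <- key[uk]
    bad <- adj[!ok_map[key]]
    cuts <- c(cuts, pos[bad])
  }
  sort(unique(cuts))
}

#' Per-base oracle decomposition
#'
#' Exact, tolerance-free reference implementation of subunit boundary
#' detection: every base covered by a duplicon is linked to its partner
#' base through each pair's map, the paralogy relation is closed by
#' union-find, and a boundary is placed between two adjacent bases
#' whenever their paralog-position sets are not shift-consistent. Meant
#' as an independent check of [propagateBreakpoints()] on toy instances;
#' it refuses inputs larger than 1 Mb.
#'
#' @param pairs An [SDPairSet-class] on a single chromosome.
#' @param maxBases Scale guard: refuse instances whose duplicon union
#'   covers more than this many bases (default 1e6).
#' @return Sorted numeric vector of boundary (cut) positions, same
#'   convention as [propagateBreakpoints()].
#' @export
oracleDecompose <- function(pairs, maxBases = 1e6) {
  if (!length(pairs)) return(numeric())
  .one_chrom(c(pairs@first, pairs@second))
  covered <- sum(BiocGenerics::width(GenomicRanges::reduce(
    c(pairs@first, pairs@second), ignore.strand = TRUE)))
  if (covered > maxBases)
    stop("oracleDecompose is a toy-scale reference (duplicon union up to ",
         maxBases, " bases); got ", covered)
  .closure_boundaries(.base_closure(pairs))
}
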