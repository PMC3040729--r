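#' Decomposition parameters
#'
#' Bundle of tuning parameters for the subunit decomposition.
#'
#' @param mergeTolerance Breakpoints closer than this many bases are
#'   treated as one (default 20, well inside the <200 bp boundary drift
#'   observed between independent runs of interval-resolution
#'   decompositions of the same region).
#' @param minSubunitLength Segments shorter than this are merged into a
#'   neighbour (default 30 b, the smallest subunit observed on real
#'   input).
#' @param familyIdentity Minimum identity for a paralogy edge between
#'   subunits (default 0.90).
#' @param familyOverlap Minimum reciprocal overlap between a projected
#'   subunit and a target subunit for a paralogy edge (default 0.8).
#' @param maxIterations Iteration cap for breakpoint propagation
#'   (default 50).
#' @return A named list of parameters.
#' @export
decompositionParams <- function(mergeTolerance = 20,
                                minSubunitLength = 30,
                                familyIdentity = 0.90,
                                familyOverlap = 0.8,
                                maxIterations = 50L) {
  stopifnot(mergeTolerance >= 0, minSubunitLength >= 1,
            familyIdentity > 0, familyIdentity <= 1,
            familyOverlap > 0, familyOverlap <= 1, maxIterations >= 1)
  list(mergeTolerance = mergeTolerance,
       minSubunitLength = minSubunitLength,
       familyIdentity = familyIdentity,
       familyOverlap = familyOverlap,
       maxIterations = as.integer(maxIterations))
}

# cut-space endpoint matrix for both sides of every pair:
# list of per-pair list(from=c(lo,hi), to=c(lo,hi), inverted)
.pair_maps <- function(pairs) {
  cutsA <- .cuts_of(pairs@first)
  cutsB <- .cuts_of(pairs@second)
  inv <- pairs@orientation == "inverted"
  maps <- vector("list", 2L * length(pairs))
  for (i in seq_along(pairs@orientation)) {
    maps[[2L * i - 1L]] <- list(from = cutsA[i, ], to = cutsB[i, ],
                                inverted = inv[i])
    maps[[2L * i]] <- list(from = cutsB[i, ], to = cutsA[i, ],
                           inverted = inv[i])
  }
  maps
}

#' Propagate duplicon breakpoints to a fixpoint
#'
#' Every duplicon endpoint is a candidate breakpoint; because the two
#' sides of a pair are copies of each other, any breakpoint falling
#' inside one side must also exist at the corresponding position of the
#' other side. This function projects breakpoints through the
#' orientation-aware proportional map of every pair, repeatedly, until
#' no projection lands farther than `mergeTolerance` from an existing
#' breakpoint. Positions are reported in cut coordinates (a breakpoint
#' at `c` separates base `c - 1` from base `c`), snapped so that each
#' tolerance-cluster is represented by its minimum member.
#'
#' @param pairs An [SDPairSet-class]; all records must be on one
#'   chromosome.
#' @param params See [decompositionParams()].
#' @return Sorted numeric vector of breakpoint (cut) positions.
#' @examples
#' p <- SDPairSet(
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)),
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 600)))
#' propagateBreakpoints(p)  # 101 201 501 601
#' @export
propagateBreakpoints <- function(pairs, params = decompositionParams()) {
  if (!length(pairs)) return(numeric())
  .one_chrom(c(pairs@first, pairs@second))
  tol <- params$mergeTolerance
  maps <- .pair_maps(pairs)
  bp <- sort(unique(c(.cuts_of(pairs@first), .cuts_of(pairs@second))))
  for (iter in seq_len(params$maxIterations)) {
    proj <- unlist(lapply(maps, function(mp) {
      sel <- bp >= mp$from[1] & bp <= mp$from[2]
      if (!any(sel)) return(numeric())
      .project_cut(bp[sel], mp$from, mp$to, mp$inverted)
    }))
    if (!length(proj)) break
    # distance of each projection to the nearest existing breakpoint
    idx <- findInterval(proj, bp)
    lo <- bp[pmax(idx, 1L)]
    hi <- bp[pmin(idx + 1L, length(bp))]
    d <- pmin(abs(proj - lo), abs(proj - hi))
    fresh <- proj[d > tol]
    if (!length(fresh)) break
    if (iter == params$maxIterations)
      stop("breakpoint propagation did not converge within ",
           params$maxIterations, " iterations; oscillating positions near ",
           paste(round(sort(unique(fresh))[seq_len(min(5, length(fresh)))]),
                 collapse = ", "))
    bp <- sort(c(bp, .snap_positions(fresh, tol)))
  }
  round(.snap_positions(bp, tol))
}

#' Build subunits from breakpoints
#'
#' Cuts the union of all duplicon intervals at the propagated
#' breakpoints; every resulting segment covered by at least one duplicon
#' becomes a subunit. Segments shorter than `minSubunitLength` are
#' merged into the neighbouring segment with which they share the most
#' duplicon coverage (paralogy edges); ties go to the left neighbour.
#'
#' @param breakpoints Output of [propagateBreakpoints()].
#' @param pairs The [SDPairSet-class] the breakpoints came from.
#' @param params See [decompositionParams()].
#' @return A `GRanges` of non-overlapping subunits with metadata column
#'   `subunit_id`, tiling the duplicon union exactly.
#' @export
buildSubunits <- function(breakpoints, pairs,
                          params = decompositionParams()) {
  if (!length(pairs))
    return(GenomicRanges::GRanges(subunit_id = character()))
  chrom <- .one_chrom(c(pairs@first, pairs@second))
  cov <- GenomicRanges::reduce(c(pairs@first, pairs@second),
                               ignore.strand = TRUE)
  segs <- list()
  for (k in seq_along(cov)) {
    lo <- BiocGenerics::start(cov)[k]
    hi <- BiocGenerics::end(cov)[k] + 1L
    inner <- breakpoints[breakpoints > lo & breakpoints < hi]
    cuts <- sort(unique(c(lo, inner, hi)))
    st <- cuts[-length(cuts)]
    en <- cuts[-1] - 1
    # merge short segments into the neighbour sharing most coverage
    repeat {
      w <- en - st + 1
      short <- which(w < params$minSubunitLength & length(w) > 1)
      short <- short[short <= length(w)]
      if (!length(short) || length(w) == 1L) break
      i <- short[1]
      if (i == 1L) j <- 2L
      else if (i == length(w)) j <- i - 1L
      else {
        nshared <- function(a, b) {
          ga <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st[a], en[a]))
          gb <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st[b], en[b]))
          sides <- c(pairs@first, pairs@second)
          sum(IRanges::overlapsAny(sides, ga) &
              IRanges::overlapsAny(sides, gb))
        }
        left <- nshared(i, i - 1L); rightn <- nshared(i, i + 1L)
        j <- if (rightn > left) i + 1L else i - 1L
      }
      a <- min(i, j); b <- max(i, j)
      st <- c(st[seq_len(a - 1L)], st[a],
              if (b < length(st)) st[(b + 1L):length(st)])
      en <- c(en[seq_len(a - 1L)], en[b],
              if (b < length(en)) en[(b + 1L):length(en)])
    }
    segs[[k]] <- cbind(st, en)
  }
  segs <- do.call(rbind, segs)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(segs[, 1], segs[, 2]))
  gr <- BiocGenerics::sort(gr)
  gr$subunit_id <- sprintf("S%03d", seq_along(gr))
  gr
}

# project a cut interval c(lo,hi) through a map; returns ordered c(lo,hi)
.project_interval <- function(iv, mp) {
  a <- .project_cut(iv[1], mp$from, mp$to, mp$inverted)
  b <- .project_cut(iv[2], mp$from, mp$to, mp$inverted)
  sort(c(a, b))
}

#' Classify subunits into paralogous families
#'
#' Two subunits are paralogous when some duplicon pair maps one onto the
#' other with reciprocal overlap at least `familyOverlap` and identity
#' at least `familyIdentity`. Families are the connected components of
#' that relation with two or more members; subunits in singleton
#' components keep `family_id = NA` and are reported.
#'
#' Identity is the pair's `fracMatch` by default. When `sequences` (a
#' `DNAStringSet` with one entry named after the chromosome) is
#' supplied, identity is instead computed from the subunit sequences by
#' pairwise alignment of each candidate edge.
#'
#' @param subunits Output of [buildSubunits()].
#' @param pairs The [SDPairSet-class].
#' @param params See [decompositionParams()].
#' @param sequences Optional `DNAStringSet` for direct sequence
#'   identity.
#' @return A list with `subunits` (input `GRanges` plus `family_id`
#'   column), `families` (data frame `family_id`, `n_members`,
#'   `member_ids`), and `unassigned` (subunit ids in singleton
#'   components).
#' @export
classifyFamilies <- function(subunits, pairs,
                             params = decompositionParams(),
                             sequences = NULL) {
  n <- length(subunits)
  if (!n) {
    return(list(subunits = subunits,
                families = data.frame(family_id = character(),
                                      n_members = integer(),
                                      member_ids = character()),
                unassigned = character()))
  }
  maps <- .pair_maps(pairs)
  frac <- rep(pairs@fracMatch, each = 2L)
  su_cut <- cbind(BiocGenerics::start(subunits),
                  BiocGenerics::end(subunits) + 1L)
  edges <- matrix(integer(), ncol = 2)
  elist <- list()
  for (m in seq_along(maps)) {
    mp <- maps[[m]]
    inside <- which(su_cut[, 1] < mp$from[2] & su_cut[, 2] > mp$from[1])
    for (i in inside) {
      iv <- c(max(su_cut[i, 1], mp$from[1]), min(su_cut[i, 2], mp$from[2]))
      # require the subunit to lie (mostly) within the duplicon
      if ((iv[2] - iv[1]) / (su_cut[i, 2] - su_cut[i, 1]) <
          params$familyOverlap) next
      pr <- .project_interval(iv, mp)
      targets <- which(su_cut[, 1] < pr[2] & su_cut[, 2] > pr[1])
      for (j in targets) {
        if (j == i) next
        olo <- max(pr[1], su_cut[j, 1]); ohi <- min(pr[2], su_cut[j, 2])
        ov <- ohi - olo
        if (ov / (pr[2] - pr[1]) >= params$familyOverlap &&
            ov / (su_cut[j, 2] - su_cut[j, 1]) >= params$familyOverlap) {
          ident <- if (is.null(sequences)) frac[m] else
            .sequence_identity(subunits[i], subunits[j], sequences)
          if (ident >= params$familyIdentity)
            elist[[length(elist) + 1L]] <- c(i, j)
        }
      }
    }
  }
  if (length(elist)) edges <- do.call(rbind, elist)
  comp <- .components(n, edges)
  sizes <- table(comp)
  fam_comps <- as.integer(names(sizes)[sizes >= 2])
  # family ids ordered by leftmost member
  starts <- vapply(fam_comps, function(cc)
    min(BiocGenerics::start(subunits)[comp == cc]), 1)
  fam_comps <- fam_comps[order(starts)]
  fid <- rep(NA_character_, n)
  fam_rows <- lapply(seq_along(fam_comps), function(k) {
    members <- which(comp == fam_comps[k])
    fid[members] <<- sprintf("F%03d", k)
    data.frame(family_id = sprintf("F%03d", k),
               n_members = length(members),
               member_ids = paste(subunits$subunit_id[members],
                                  collapse = ","))
  })
  subunits$family_id <- fid
  list(subunits = subunits,
       families = if (length(fam_rows)) do.call(rbind, fam_rows) else
         data.frame(family_id = character(), n_members = integer(),
                    member_ids = character()),
       unassigned = subunits$subunit_id[is.na(fid)])
}

# identity between two subunit sequences by global alignment
.sequence_identity <- function(su1, su2, sequences) {
  ch <- as.character(GenomicRanges::seqnames(su1))
  s1 <- Biostrings::subseq(sequences[[ch]],
                           BiocGenerics::start(su1), BiocGenerics::end(su1))
  s2 <- Biostrings::subseq(sequences[[ch]],
                           BiocGenerics::start(su2), BiocGenerics::end(su2))
  aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global")
  Biostrings::pid(aln) / 100
}

#' Decompose SD pairs into subunits and families
#'
#' Convenience wrapper: [propagateBreakpoints()], [buildSubunits()] and
#' [classifyFamilies()] in sequence.
#'
#' @inheritParams classifyFamilies
#' @param pairs An [SDPairSet-class].
#' @return A list with `breakpoints`, `subunits` (GRanges with
#'   `subunit_id` and `family_id`), `families`, and `unassigned`.
#' @export
decomposeSDs <- function(pairs, params = decompositionParams(),
                         sequences = NULL) {
  bp <- propagateBreakpoints(pairs, params)
  su <- buildSubunits(bp, pairs, params)
  fam <- classifyFamilies(su, pairs, params, sequences)
  list(breakpoints = bp, subunits = fam$subunits,
       families = fam$families, unassigned = fam$unassigned)
}

#' Summary statistics of subunit lengths
#'
#' @param subunits A subunit `GRanges`.
#' @return A one-row data frame: `n`, `mean_bp`, `median_bp`, `min_bp`,
#'   `max_bp` (all zero for empty input).
#' @export
subunitStats <- function(subunits) {
  if (!length(subunits))
    return(data.frame(n = 0L, mean_bp = 0, median_bp = 0,
                      min_bp = 0, max_bp = 0))
  w <- BiocGenerics::width(subunits)
  data.frame(n = length(w), mean_bp = mean(w), median_bp = stats::median(w),
             min_bp = min(w), max_bp = max(w))
}
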