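# map a human interval [s, e] (clipped to the block's reference side)
# to target coordinates through one alignment block row
.project_through_block <- function(s, e, b) {
  s <- max(s, b$ref_start); e <- min(e, b$ref_end)
  if (b$strand == "-") {
    c(b$query_end - (e - b$ref_start), b$query_end - (s - b$ref_start))
  } else {
    c(b$query_start + (s - b$ref_start), b$query_start + (e - b$ref_start))
  }
}

#' Build a landmark map from unique-sequence anchors
#'
#' The synteny caller needs a frame of reference in the target genome.
#' It is built from the unique (non-duplicated) intervals of the human
#' region: each unique interval covered by target alignment at
#' `minCoverage` or more becomes an anchor linking its human
#' coordinates to the matched target coordinates. Anchors must be
#' monotone along both genomes; a maximal monotone subset is kept
#' (longest increasing subsequence on target position) and dropped
#' anchors are reported in the `dropped` attribute.
#'
#' @param unique_intervals `GRanges` of unique (non-SD) human
#'   intervals.
#' @param blocks Alignment blocks ([readAlignmentBlocks()] format) with
#'   the target genome as `query` and human as `ref`.
#' @param minCoverage Minimum fraction of a unique interval that must
#'   be aligned (default 0.5).
#' @return A data frame of anchors: `human_start`, `human_end`,
#'   `target_chrom`, `target_start`, `target_end`, `strand`; ordered by
#'   human position. Attribute `dropped` lists non-monotone anchors.
#' @export
buildLandmarkMap <- function(unique_intervals, blocks,
                             minCoverage = 0.5) {
  empty <- data.frame(human_start = integer(), human_end = integer(),
                      target_chrom = character(),
                      target_start = integer(), target_end = integer(),
                      strand = character())
  if (!length(unique_intervals) || !nrow(blocks)) {
    attr(empty, "dropped") <- empty
    return(empty)
  }
  bgr <- GenomicRanges::GRanges(blocks$ref,
                                IRanges::IRanges(blocks$ref_start,
                                                 blocks$ref_end))
  anchors <- list()
  for (k in seq_along(unique_intervals)) {
    u <- unique_intervals[k]
    ov <- GenomicRanges::findOverlaps(bgr, u)
    hits <- S4Vectors::queryHits(ov)
    if (!length(hits)) next
    covered <- sum(BiocGenerics::width(IRanges::intersect(
      IRanges::ranges(bgr[hits]), IRanges::ranges(u))))
    if (covered / BiocGenerics::width(u) < minCoverage) next
    # project the unique interval through the largest covering block
    main <- hits[order(-BiocGenerics::width(bgr[hits]))][1]
    tgt <- .project_through_block(BiocGenerics::start(u),
                                  BiocGenerics::end(u), blocks[main, ])
    anchors[[length(anchors) + 1L]] <- data.frame(
      human_start = BiocGenerics::start(u),
      human_end = BiocGenerics::end(u),
      target_chrom = blocks$query[main],
      target_start = tgt[1],
      target_end = tgt[2],
      strand = blocks$strand[main])
  }
  if (!length(anchors)) {
    attr(empty, "dropped") <- empty
    return(empty)
  }
  a <- do.call(rbind, anchors)
  a <- a[order(a$human_start), , drop = FALSE]
  # longest increasing subsequence of target_start: keep monotone set
  n <- nrow(a)
  best <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (a$target_start[j] < a$target_start[i] &&
          best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  keep <- integer()
  cands <- which(best == max(best))
  cur <- cands[which.min(a$target_start[cands])]
  while (!is.na(cur)) { keep <- c(cur, keep); cur <- prev[cur] }
  dropped <- a[-keep, , drop = FALSE]
  a <- a[keep, , drop = FALSE]
  rownames(a) <- NULL
  attr(a, "dropped") <- dropped
  a
}

#' Call presence/absence of subunits in a target species
#'
#' Applies, in fixed precedence order, the three rules of
#' landmark-based synteny calling. A subunit is `present` when an
#' alignment block covering at least `covFrac` of it lands between the
#' target coordinates of its flanking anchors; `present_rescued` when
#' the expected target window is at least `nFrac` ambiguous (`N`) bases
#' and the subunit aligns anywhere on an unplaced/random target contig;
#' `absent` when neither holds and the target inter-anchor distance is
#' less than half the human distance (the duplication simply is not
#' there); otherwise `ambiguous`.
#'
#' @param subunits Subunit `GRanges` with `subunit_id`.
#' @param map Landmark map from [buildLandmarkMap()].
#' @param blocks Alignment blocks (target as `query`, human as `ref`).
#' @param species Species label recorded in the calls.
#' @param targetN Optional `GRanges` on target coordinates marking `N`
#'   runs (assembly gaps).
#' @param covFrac Minimum aligned fraction of the subunit for a present
#'   call (default 0.5).
#' @param nFrac Minimum `N` fraction of the expected window for the
#'   rescue rule (default 0.5).
#' @param randomPattern Regular expression identifying
#'   unplaced/random target contig names (default
#'   `"random|Un|unplaced"`).
#' @return A data frame of calls: `subunit_id`, `species`, `status`,
#'   `note`.
#' @export
callSynteny <- function(subunits, map, blocks, species,
                        targetN = NULL, covFrac = 0.5, nFrac = 0.5,
                        randomPattern = "random|Un|unplaced") {
  status <- rep("ambiguous", length(subunits))
  note <- rep("", length(subunits))
  if (!nrow(map)) {
    note[] <- "no landmark map"
    return(data.frame(subunit_id = subunits$subunit_id,
                      species = species, status = status, note = note))
  }
  bgr <- GenomicRanges::GRanges(blocks$ref,
                                IRanges::IRanges(blocks$ref_start,
                                                 blocks$ref_end))
  on_random <- grepl(randomPattern, blocks$query)
  for (k in seq_along(subunits)) {
    su <- subunits[k]
    s <- BiocGenerics::start(su); e <- BiocGenerics::end(su)
    left <- map[map$human_end <= s, , drop = FALSE]
    right <- map[map$human_start >= e, , drop = FALSE]
    if (!nrow(left) || !nrow(right)) {
      note[k] <- "outside anchored span"
      next
    }
    la <- left[nrow(left), ]; ra <- right[1, ]
    t_lo <- min(la$target_end, ra$target_start)
    t_hi <- max(la$target_end, ra$target_start)
    human_dist <- ra$human_start - la$human_end
    target_dist <- t_hi - t_lo
    # rule (a): aligned sequence in the expected syntenic window
    ov <- GenomicRanges::findOverlaps(bgr, su)
    hits <- S4Vectors::queryHits(ov)
    placed <- FALSE
    for (h in hits) {
      cov <- min(blocks$ref_end[h], e) - max(blocks$ref_start[h], s) + 1L
      if (cov / BiocGenerics::width(su) < covFrac) next
      tgt <- .project_through_block(s, e, blocks[h, ])
      in_window <- !on_random[h] &&
        blocks$query[h] == la$target_chrom &&
        tgt[1] >= t_lo - 1L && tgt[2] <= t_hi + 1L
      if (in_window) { placed <- TRUE; break }
    }
    if (placed) { status[k] <- "present"; note[k] <- "aligned in window"
                  next }
    # rule (b): window is N-rich and the subunit aligns on a random
    # contig
    if (!is.null(targetN) && length(targetN) && target_dist > 0) {
      win <- GenomicRanges::GRanges(la$target_chrom,
                                    IRanges::IRanges(t_lo, t_hi))
      nn <- GenomicRanges::intersect(
        GenomicRanges::reduce(targetN, ignore.strand = TRUE), win,
        ignore.strand = TRUE)
      n_frac_obs <- sum(BiocGenerics::width(nn)) /
        BiocGenerics::width(win)
      random_hit <- any(vapply(hits, function(h) {
        cov <- min(blocks$ref_end[h], e) - max(blocks$ref_start[h], s) + 1L
        on_random[h] && cov / BiocGenerics::width(su) >= covFrac
      }, TRUE))
      if (n_frac_obs >= nFrac && random_hit) {
        status[k] <- "present_rescued"
        note[k] <- "N-gap window; hit on unplaced contig"
        next
      }
    }
    # rule (c): collapsed target window implies true absence
    if (human_dist > 0 && target_dist < 0.5 * human_dist) {
      status[k] <- "absent"
      note[k] <- sprintf("target window %d < 0.5 x human %d",
                         target_dist, human_dist)
    } else {
      note[k] <- "no aligned sequence; window not collapsed"
    }
  }
  data.frame(subunit_id = subunits$subunit_id, species = species,
             status = status, note = note)
}

#' Summarise synteny calls
#'
#' @param calls Data frame of calls from [callSynteny()] (possibly
#'   several species concatenated).
#' @return A list with `per_species` (percentage of subunits present -
#'   `present` plus `present_rescued` - per species), `any_species`
#'   (percentage present in at least one species), and `human_only`
#'   (percentage called absent in every species).
#' @export
syntenySummary <- function(calls) {
  present <- c("present", "present_rescued")
  species <- sort(unique(calls$species))
  per_species <- vapply(species, function(sp) {
    sub <- calls[calls$species == sp, ]
    100 * mean(sub$status %in% present)
  }, 1)
  ids <- unique(calls$subunit_id)
  any_sp <- vapply(ids, function(id) {
    any(calls$status[calls$subunit_id == id] %in% present)
  }, TRUE)
  all_absent <- vapply(ids, function(id) {
    all(calls$status[calls$subunit_id == id] == "absent")
  }, TRUE)
  list(per_species = per_species,
       any_species = 100 * mean(any_sp),
       human_only = 100 * mean(all_absent))
}
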