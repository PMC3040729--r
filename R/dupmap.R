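#' Merge duplicons into duplication loci
#'
#' A duplication locus is a maximal genomic region covered by one or
#' more (overlapping) duplicons and not interrupted by unique sequence:
#' the standard interval merge of all duplicon intervals.
#'
#' @param pairs An [SDPairSet-class].
#' @return A `GRanges` of loci with metadata column `locus_id`, ordered
#'   by position.
#' @export
mergeLoci <- function(pairs) {
  if (!length(pairs))
    return(GenomicRanges::GRanges(locus_id = character()))
  loci <- BiocGenerics::sort(GenomicRanges::reduce(
    c(pairs@first, pairs@second), ignore.strand = TRUE))
  loci$locus_id <- sprintf("L%03d", seq_along(loci))
  loci
}

#' Group duplication loci by shared paralogous families
#'
#' Two loci belong to one group when they contain subunits of the same
#' family (connected components of that relation). Groups are numbered
#' by the leftmost coordinate of their leftmost locus.
#'
#' @param loci Output of [mergeLoci()].
#' @param subunits Subunit `GRanges` with `family_id` (from
#'   [classifyFamilies()]).
#' @return `loci` with an added `group_id` metadata column.
#' @export
groupLoci <- function(loci, subunits) {
  n <- length(loci)
  if (!n) { loci$group_id <- character(); return(loci) }
  hit <- GenomicRanges::findOverlaps(subunits, loci, type = "within")
  su_locus <- rep(NA_integer_, length(subunits))
  su_locus[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  fam <- subunits$family_id
  edges <- list()
  for (f in unique(fam[!is.na(fam)])) {
    in_loci <- sort(unique(su_locus[!is.na(fam) & fam == f]))
    in_loci <- in_loci[!is.na(in_loci)]
    if (length(in_loci) > 1)
      edges[[f]] <- cbind(in_loci[-length(in_loci)], in_loci[-1])
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(), ncol = 2)
  comp <- .components(n, em)
  loci$group_id <- sprintf("G%02d", comp)
  loci
}

# longest common contiguous run between two label vectors; returns
# list(len, offset_a, offset_b) with 0-based offsets, leftmost-in-a tie
.lc_substring <- function(a, b) {
  na <- length(a); nb <- length(b)
  best <- list(len = 0L, offset_a = NA_integer_, offset_b = NA_integer_)
  if (!na || !nb) return(best)
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (!is.na(a[i]) && !is.na(b[j]) && a[i] == b[j]) {
        cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
        if (cur[j] > best$len) {
          best <- list(len = cur[j],
                       offset_a = i - cur[j],
                       offset_b = j - cur[j])
        }
      }
    }
    prev <- cur
  }
  best
}

#' Align group members to the anchor locus
#'
#' Within each locus group the largest locus (ties: leftmost) is the
#' anchor. Every member locus is represented by the ordered string of
#' its subunit family labels and matched to the anchor's string by the
#' longest common contiguous run of family labels, testing both
#' orientations. Member subunits outside the matched run are counted as
#' disruptions; a member with no shared label is reported unplaced
#' (`anchor_offset = NA`), not an error.
#'
#' @param loci Output of [groupLoci()].
#' @param subunits Subunit `GRanges` with `family_id`.
#' @return A data frame with columns `locus_id`, `group_id`,
#'   `is_anchor`, `anchor_id`, `anchor_offset` (0-based offset of the
#'   matched run in the anchor's label string), `orientation`,
#'   `n_matched`, `n_disrupted`.
#' @export
alignToAnchor <- function(loci, subunits) {
  hit <- GenomicRanges::findOverlaps(subunits, loci, type = "within")
  su_locus <- rep(NA_integer_, length(subunits))
  su_locus[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  labels_of <- function(k) {
    members <- which(su_locus == k)
    members <- members[order(BiocGenerics::start(subunits)[members])]
    subunits$family_id[members]
  }
  out <- list()
  for (g in unique(loci$group_id)) {
    idx <- which(loci$group_id == g)
    w <- BiocGenerics::width(loci)[idx]
    st <- BiocGenerics::start(loci)[idx]
    anchor <- idx[order(-w, st)][1]
    a_lab <- labels_of(anchor)
    for (k in idx) {
      if (k == anchor) {
        out[[length(out) + 1L]] <- data.frame(
          locus_id = loci$locus_id[k], group_id = g, is_anchor = TRUE,
          anchor_id = loci$locus_id[anchor], anchor_offset = 0L,
          orientation = "same", n_matched = length(a_lab),
          n_disrupted = 0L)
        next
      }
      m_lab <- labels_of(k)
      fwd <- .lc_substring(m_lab, a_lab)
      rev_ <- .lc_substring(rev(m_lab), a_lab)
      use_rev <- rev_$len > fwd$len
      hitx <- if (use_rev) rev_ else fwd
      out[[length(out) + 1L]] <- data.frame(
        locus_id = loci$locus_id[k], group_id = g, is_anchor = FALSE,
        anchor_id = loci$locus_id[anchor],
        anchor_offset = if (hitx$len > 0L) hitx$offset_b else NA_integer_,
        orientation = if (use_rev) "inverted" else "same",
        n_matched = hitx$len,
        n_disrupted = length(m_lab) - hitx$len)
    }
  }
  df <- do.call(rbind, out)
  df[order(match(df$locus_id, loci$locus_id)), , drop = FALSE]
}

#' Build the full hierarchical duplication map
#'
#' Runs [mergeLoci()], [groupLoci()] and [alignToAnchor()] and returns a
#' [DuplicationMap-class].
#'
#' @param pairs An [SDPairSet-class].
#' @param subunits Subunit `GRanges` with `family_id`.
#' @return A [DuplicationMap-class].
#' @export
buildDuplicationMap <- function(pairs, subunits) {
  loci <- groupLoci(mergeLoci(pairs), subunits)
  pl <- alignToAnchor(loci, subunits)
  methods::new("DuplicationMap", loci = loci, placements = pl,
               subunits = subunits)
}

#' Recurrent breakpoint families and their Alu adjacency
#'
#' Tallies the family of the first and last subunit of every placed
#' non-anchor member locus (the two ends of a putative duplication
#' event). A family is recurrent when its end-count exceeds
#' `recurrentThreshold` (strict). A family is Alu-adjacent when any of
#' its member subunits overlaps, or lies within `W` bases of, a
#' SINE/Alu repeat record. The summary fraction is the fraction of
#' subunits belonging to recurrent breakpoint families that are
#' themselves Alu-adjacent.
#'
#' @param map A [DuplicationMap-class].
#' @param repeats Repeat `GRanges` (with `repClass`), or `NULL` to skip
#'   the Alu annotation.
#' @param W Adjacency window in bases (default 10).
#' @param recurrentThreshold Count above which a family is recurrent
#'   (default 5).
#' @return A list with `report` (data frame: `family_id`,
#'   `n_breakpoint_occurrences`, `recurrent`, `alu_adjacent`) and
#'   `alu_fraction` (the summary fraction; `NA` when no recurrent
#'   family or no repeats given).
#' @export
breakpointFamilies <- function(map, repeats = NULL, W = 10,
                               recurrentThreshold = 5) {
  subunits <- map@subunits
  loci <- map@loci
  pl <- map@placements
  hit <- GenomicRanges::findOverlaps(subunits, loci, type = "within")
  su_locus <- rep(NA_integer_, length(subunits))
  su_locus[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  end_fams <- character()
  members <- pl[!pl$is_anchor & !is.na(pl$anchor_offset), , drop = FALSE]
  for (lid in members$locus_id) {
    k <- which(loci$locus_id == lid)
    su <- which(su_locus == k)
    if (!length(su)) next
    su <- su[order(BiocGenerics::start(subunits)[su])]
    fams <- subunits$family_id[c(su[1], su[length(su)])]
    end_fams <- c(end_fams, fams[!is.na(fams)])
  }
  if (!length(end_fams)) {
    return(list(report = data.frame(family_id = character(),
                                    n_breakpoint_occurrences = integer(),
                                    recurrent = logical(),
                                    alu_adjacent = logical()),
                alu_fraction = NA_real_))
  }
  tab <- table(end_fams)
  alu_adj_subunit <- rep(NA, length(subunits))
  if (!is.null(repeats) && length(repeats)) {
    alus <- repeats[grepl("Alu", repeats$repClass) |
                    grepl("^Alu", repeats$name)]
    alu_adj_subunit <- IRanges::overlapsAny(
      subunits + W, alus, ignore.strand = TRUE)
  }
  fam_alu <- vapply(names(tab), function(f) {
    members <- which(!is.na(subunits$family_id) & subunits$family_id == f)
    if (anyNA(alu_adj_subunit[members])) NA else
      any(alu_adj_subunit[members])
  }, TRUE)
  report <- data.frame(
    family_id = names(tab),
    n_breakpoint_occurrences = as.integer(tab),
    recurrent = as.integer(tab) > recurrentThreshold,
    alu_adjacent = fam_alu,
    row.names = NULL)
  rec_fams <- report$family_id[report$recurrent]
  frac <- NA_real_
  if (length(rec_fams) && !is.null(repeats)) {
    rec_su <- which(subunits$family_id %in% rec_fams)
    if (length(rec_su)) frac <- mean(alu_adj_subunit[rec_su])
  }
  list(report = report, alu_fraction = frac)
}

#' Fraction of SD sequence contained in anchor loci
#'
#' The anchors (one per group) form the top level of the hierarchical
#' map; this reports how much of the duplicated sequence they account
#' for. Two denominators are reported because duplicons can overlap:
#' `fraction_locus_bases` uses the union of loci (each base once),
#' `fraction_duplicon_bases` the summed lengths of all duplicons
#' (bases counted with multiplicity).
#'
#' @param map A [DuplicationMap-class].
#' @param pairs The [SDPairSet-class] the map was built from.
#' @return A named list with both fractions.
#' @export
topLevelFraction <- function(map, pairs) {
  pl <- map@placements
  anchors <- pl$locus_id[pl$is_anchor]
  loci <- map@loci
  anchor_bp <- sum(BiocGenerics::width(loci)[loci$locus_id %in% anchors])
  locus_bp <- sum(BiocGenerics::width(loci))
  dup_bp <- sum(BiocGenerics::width(pairs@first)) +
    sum(BiocGenerics::width(pairs@second))
  list(fraction_locus_bases = anchor_bp / locus_bp,
       fraction_duplicon_bases = anchor_bp / dup_bp)
}
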