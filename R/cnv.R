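#' Call CNVs from clone-versus-reference alignment gaps
#'
#' Scans the alignment blocks of each clone along the reference. An
#' unaligned reference stretch longer than `minGap` between consecutive
#' blocks is a loss (deletion in the clone); an unaligned clone stretch
#' longer than `minGap` is a gain (insertion), anchored at the
#' reference junction point. Gaps of `minGap` bases or fewer are
#' ignored.
#'
#' Coordinates follow the printed-table dialect: for a loss, `cnv_start`
#' and `cnv_end` are the two reference breakpoints with
#' `cnv_end - cnv_start == length_bp`; for a gain, `cnv_start ==
#' cnv_end` (the insertion point) with a positive `length_bp`.
#'
#' @param blocks Alignment blocks as returned by
#'   [readAlignmentBlocks()]; may contain several clones (column
#'   `query`).
#' @param minGap Gap threshold in bases (default 200; the strict
#'   `> 200 bp` rule).
#' @return A data frame with columns `source_id`, `ref`, `cnv_start`,
#'   `cnv_end`, `length_bp`, `kind`.
#' @export
callCNVs <- function(blocks, minGap = 200) {
  empty <- data.frame(source_id = character(), ref = character(),
                      cnv_start = integer(), cnv_end = integer(),
                      length_bp = integer(), kind = character())
  if (!nrow(blocks)) return(empty)
  out <- list()
  for (clone in unique(blocks$query)) {
    b <- blocks[blocks$query == clone, , drop = FALSE]
    b <- b[order(b$ref_start), , drop = FALSE]
    if (nrow(b) > 1) {
      if (any(diff(b$query_start) < 0) ||
          any(b$query_start[-1] <= b$query_end[-nrow(b)]))
        stop("alignment blocks out of order or overlapping on clone ",
             clone)
      if (any(b$ref_start[-1] <= b$ref_end[-nrow(b)]))
        stop("alignment blocks overlapping on reference for clone ",
             clone)
    }
    for (i in seq_len(nrow(b) - 1L)) {
      ref_gap <- b$ref_start[i + 1L] - b$ref_end[i] - 1L
      clone_gap <- b$query_start[i + 1L] - b$query_end[i] - 1L
      if (ref_gap > minGap) {
        out[[length(out) + 1L]] <- data.frame(
          source_id = clone, ref = b$ref[i],
          cnv_start = b$ref_end[i], cnv_end = b$ref_end[i] + ref_gap,
          length_bp = ref_gap, kind = "loss")
      }
      if (clone_gap > minGap) {
        out[[length(out) + 1L]] <- data.frame(
          source_id = clone, ref = b$ref[i],
          cnv_start = b$ref_end[i], cnv_end = b$ref_end[i],
          length_bp = clone_gap, kind = "gain")
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$source_id, res$cnv_start), , drop = FALSE]
}

#' CNV size classes
#'
#' Partitions calls into the three canonical classes: small (< 1 kb),
#' intermediate (1-10 kb, bounds inclusive) and large (> 10 kb).
#'
#' @param cnvs Data frame with a `length_bp` column.
#' @return Named integer vector `c(small, intermediate, large)`.
#' @export
sizeClasses <- function(cnvs) {
  len <- cnvs$length_bp
  c(small = sum(len < 1000),
    intermediate = sum(len >= 1000 & len <= 10000),
    large = sum(len > 10000))
}

#' CNVs flanked by paralogous subunits
#'
#' Reports catalog CNVs whose two breakpoints each fall inside subunits
#' sharing a family: the NAHR-compatible configuration in which unequal
#' crossover between the two paralogs deletes or duplicates the
#' intervening sequence.
#'
#' @param cnvs Data frame with columns `cnv_start`, `cnv_end`,
#'   `length_bp` (breakpoints, 1-based).
#' @param subunits Subunit `GRanges` with `family_id` (and optionally
#'   `subunit_id`).
#' @return A list with `report` (one row per qualifying CNV: input
#'   columns plus `left_subunit`, `right_subunit`, `family_id`) and
#'   `mean_length` (mean `length_bp` over qualifying CNVs, `NA` if
#'   none).
#' @export
paralogFlanked <- function(cnvs, subunits) {
  chrom <- if (length(subunits)) .one_chrom(subunits) else "chr"
  locate <- function(pos) {
    hit <- which(BiocGenerics::start(subunits) <= pos &
                 BiocGenerics::end(subunits) >= pos)
    if (length(hit)) hit[1] else NA_integer_
  }
  rows <- list()
  for (i in seq_len(nrow(cnvs))) {
    li <- locate(cnvs$cnv_start[i])
    ri <- locate(cnvs$cnv_end[i])
    if (is.na(li) || is.na(ri)) next
    lf <- subunits$family_id[li]; rf <- subunits$family_id[ri]
    if (is.na(lf) || is.na(rf) || lf != rf) next
    rows[[length(rows) + 1L]] <- data.frame(
      cnvs[i, , drop = FALSE],
      left_subunit = sprintf("%s:%d-%d", chrom,
                             BiocGenerics::start(subunits)[li],
                             BiocGenerics::end(subunits)[li]),
      right_subunit = sprintf("%s:%d-%d", chrom,
                              BiocGenerics::start(subunits)[ri],
                              BiocGenerics::end(subunits)[ri]),
      family_id = lf)
  }
  if (!length(rows))
    return(list(report = data.frame(), mean_length = NA_real_))
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report, mean_length = mean(report$length_bp))
}
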