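#' Assign subunits to LCR-style blocks
#'
#' Single-linkage chaining by genomic adjacency: consecutive subunits
#' whose end-to-start gap is strictly less than `maxGap` share a block.
#' Non-duplicated sequence inside a block span is permitted; only the
#' gap between consecutive subunits matters.
#'
#' @param subunits Sorted subunit `GRanges` (with `subunit_id`).
#' @param maxGap Gap threshold in bases (default 500000; the strict
#'   `< 500 kb` rule).
#' @return A list with `subunits` (input plus `block_id` column) and
#'   `blocks`: a `GRanges` of block spans (outermost subunit
#'   coordinates) with columns `block_id` and `n_subunits`, ordered and
#'   non-overlapping.
#' @export
assignBlocks <- function(subunits, maxGap = 500000) {
  if (!length(subunits)) {
    subunits$block_id <- character()
    return(list(subunits = subunits,
                blocks = GenomicRanges::GRanges(block_id = character(),
                                                n_subunits = integer())))
  }
  subunits <- BiocGenerics::sort(subunits)
  st <- BiocGenerics::start(subunits)
  en <- BiocGenerics::end(subunits)
  gap <- st[-1] - en[-length(en)] - 1L   # non-covered bases between
  newblock <- c(TRUE, gap >= maxGap)
  bid <- cumsum(newblock)
  subunits$block_id <- sprintf("B%d", bid)
  bl_start <- tapply(st, bid, min)
  bl_end <- tapply(en, bid, max)
  blocks <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(subunits))[1],
    IRanges::IRanges(as.integer(bl_start), as.integer(bl_end)))
  blocks$block_id <- sprintf("B%d", sort(unique(bid)))
  blocks$n_subunits <- as.integer(table(bid))
  list(subunits = subunits, blocks = blocks)
}

#' Per-block summary table
#'
#' Emits one row per block: subunit count, mean subunit size with its
#' standard error, and - when synteny calls are supplied - the
#' percentage of subunits present in each species and the percentage
#' called absent in every species ("human-only"). Species columns are
#' `NA` when no synteny information is given (missing data, not zero).
#'
#' @param blocks,subunits Output of [assignBlocks()] (subunits must
#'   carry `block_id`).
#' @param synteny Optional data frame of calls from [callSynteny()] /
#'   [syntenySummary()] input: columns `subunit_id`, `species`,
#'   `status`.
#' @return A data frame, one row per block.
#' @export
blockSummary <- function(blocks, subunits, synteny = NULL) {
  out <- lapply(seq_along(blocks), function(k) {
    bid <- blocks$block_id[k]
    members <- subunits[subunits$block_id == bid]
    w <- BiocGenerics::width(members)
    row <- data.frame(
      block_id = bid,
      start = BiocGenerics::start(blocks)[k],
      end = BiocGenerics::end(blocks)[k],
      n_subunits = length(members),
      mean_size = round(mean(w), 1),
      se_size = round(stats::sd(w) / sqrt(length(w)), 1)
    )
    if (!is.null(synteny) && nrow(synteny)) {
      species <- sort(unique(synteny$species))
      present <- c("present", "present_rescued")
      per_sp <- vapply(species, function(sp) {
        sub <- synteny[synteny$species == sp &
                       synteny$subunit_id %in% members$subunit_id, ]
        100 * mean(sub$status %in% present)
      }, 1)
      absent_all <- vapply(members$subunit_id, function(id) {
        sub <- synteny[synteny$subunit_id == id, ]
        nrow(sub) > 0 && all(sub$status == "absent")
      }, TRUE)
      row$human_only_pct <- round(100 * mean(absent_all), 1)
      for (sp in species)
        row[[paste0("pct_", sp)]] <- round(per_sp[[sp]], 1)
    } else {
      row$human_only_pct <- NA_real_
    }
    row
  })
  do.call(rbind, out)
}
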