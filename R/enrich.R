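#' Random length-preserving placement null
#'
#' Generates the permutation null for interval enrichment tests: in
#' each replicate, every query interval is placed uniformly at random
#' (length preserved, orientation preserved) within the universe, and a
#' user-supplied statistic is evaluated on the placed set. Placements
#' are independent across queries (overlaps among placed queries are
#' allowed).
#'
#' @param query `GRanges` of query intervals (e.g. subunits or CNVs).
#' @param universe `GRanges` of allowed region(s); every query must fit
#'   inside one universe interval.
#' @param statistic Function taking a placed `GRanges` and returning a
#'   single number (e.g. the number of queries with an Alu within
#'   10 bases).
#' @param n Number of replicates (default 1000).
#' @param seed Integer seed; the full null distribution is reproducible
#'   from it.
#' @return Numeric vector of `n` null statistic values.
#' @export
permutePlacements <- function(query, universe, statistic, n = 1000,
                              seed = 1L) {
  qw <- BiocGenerics::width(query)
  uw <- BiocGenerics::width(universe)
  if (length(qw) && max(qw) > max(uw))
    stop("query of length ", max(qw),
         " does not fit inside any universe interval")
  set.seed(seed)
  chrom <- as.character(GenomicRanges::seqnames(universe))
  ust <- BiocGenerics::start(universe)
  # template object updated in place per replicate: the repeated
  # high-level GRanges construction would dominate the runtime
  template <- GenomicRanges::GRanges(
    rep(chrom[1], length(qw)),
    IRanges::IRanges(rep(1L, length(qw)), width = pmax(qw, 1L)),
    strand = BiocGenerics::strand(query))
  GenomeInfoDb::seqlevels(template) <- unique(chrom)
  vapply(seq_len(n), function(rep_i) {
    # choose a universe interval per query, weighted by the number of
    # valid start positions, then a uniform start within it
    placed_start <- integer(length(qw))
    placed_chrom <- character(length(qw))
    for (q in seq_along(qw)) {
      slots <- pmax(uw - qw[q] + 1L, 0L)
      if (sum(slots) == 0L)
        stop("query of length ", qw[q], " does not fit in the universe")
      ui <- sample.int(length(uw), 1L, prob = slots)
      placed_start[q] <- ust[ui] + sample.int(slots[ui], 1L) - 1L
      placed_chrom[q] <- chrom[ui]
    }
    gr <- template
    gr@ranges <- IRanges::IRanges(placed_start, width = qw)
    gr@seqnames <- methods::as(
      factor(placed_chrom, levels = unique(chrom)), "Rle")
    statistic(gr)
  }, 1)
}

#' Empirical p-value from a permutation null
#'
#' Upper-tail test with the add-one convention:
#' `p = (r + 1) / (n + 1)` where `r` is the number of null replicates
#' greater than or equal to the observed statistic. Never returns 0.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistic values.
#' @return The empirical p-value.
#' @export
empiricalP <- function(observed, null) {
  .stopifnot_scalar(observed, "observed")
  (sum(null >= observed) + 1) / (length(null) + 1)
}

#' Fold enrichment over the permutation null
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistic values.
#' @return `observed / mean(null)`; `NA` when the null mean is zero
#'   (fold undefined).
#' @export
foldEnrichment <- function(observed, null) {
  m <- mean(null)
  if (m == 0) return(NA_real_)
  observed / m
}

#' Run a full enrichment test
#'
#' Convenience wrapper returning the observed statistic, null summary,
#' fold enrichment and empirical p-value in one structure.
#'
#' @inheritParams permutePlacements
#' @return A list: `observed`, `null_mean`, `null_sd`, `fold`,
#'   `empirical_p`, `n_permutations`, `seed`.
#' @export
enrichmentTest <- function(query, universe, statistic, n = 1000,
                           seed = 1L) {
  obs <- statistic(query)
  null <- permutePlacements(query, universe, statistic, n, seed)
  list(observed = obs, null_mean = mean(null), null_sd = stats::sd(null),
       fold = foldEnrichment(obs, null),
       empirical_p = empiricalP(obs, null),
       n_permutations = n, seed = seed)
}

#' Base-fraction overlap of a feature set in two regions
#'
#' Fraction of the bases of region A (and of region B) covered by the
#' features, with a permutation p-value for the contrast obtained by
#' re-placing the features uniformly within the union of the two
#' regions and comparing the observed difference of fractions to its
#' null.
#'
#' @param features Feature `GRanges` (e.g. pseudogene annotations).
#' @param regionA,regionB `GRanges` of the two regions to compare.
#' @param n Number of permutation replicates (default 1000).
#' @param seed Integer seed.
#' @return A list: `fraction_a`, `fraction_b`, `empirical_p` (upper
#'   tail for `fraction_a - fraction_b`; `1` when there are no
#'   features).
#' @export
baseFractionOverlap <- function(features, regionA, regionB, n = 1000,
                                seed = 1L) {
  frac_in <- function(f, region) {
    if (!length(f) || !length(region)) return(0)
    ov <- GenomicRanges::intersect(
      GenomicRanges::reduce(f, ignore.strand = TRUE),
      GenomicRanges::reduce(region, ignore.strand = TRUE),
      ignore.strand = TRUE)
    sum(BiocGenerics::width(ov)) / sum(BiocGenerics::width(region))
  }
  fa <- frac_in(features, regionA)
  fb <- frac_in(features, regionB)
  if (!length(features))
    return(list(fraction_a = fa, fraction_b = fb, empirical_p = 1))
  universe <- GenomicRanges::reduce(c(regionA, regionB),
                                    ignore.strand = TRUE)
  null <- permutePlacements(
    features, universe,
    function(placed) frac_in(placed, regionA) - frac_in(placed, regionB),
    n, seed)
  list(fraction_a = fa, fraction_b = fb,
       empirical_p = empiricalP(fa - fb, null))
}
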