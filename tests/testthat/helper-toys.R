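# Shared test utilities: toy instance generators and small independent
# oracles used across the suite.

library(GenomicRanges)
library(IRanges)

# quick constructor for an SDPairSet on one chromosome
toy_pairs <- function(a_start, a_end, b_start, b_end,
                      orientation = "same", frac = 0.97,
                      chrom = "chrT") {
  n <- length(a_start)
  SDPairSet(
    GRanges(rep(chrom, n), IRanges(a_start, a_end)),
    GRanges(rep(chrom, n), IRanges(b_start, b_end)),
    orientation, frac)
}

# random toy SD-pair instance with endpoints on a coarse grid (both
# sides equal length) so that genuine boundaries are well separated
# and the per-base oracle is exact. Sides are pairwise disjoint or
# strictly nested (never partially overlapping): partial overlaps can
# compose into quasi-periodic self-maps where interval-resolution
# decomposition over-fragments by construction, so the equivalence
# with the per-base oracle is only claimed on laminar instances.
random_grid_instance <- function(n_pairs, genome = 10000, grid = 50,
                                 min_w = 200, max_w = 1000,
                                 nest_prob = 0.4) {
  slots <- genome %/% grid
  sides <- list()   # existing side intervals c(start, end)
  disjoint_from_all <- function(s, e) {
    !length(sides) ||
      all(vapply(sides, function(x) e < x[1] - 1 || s > x[2] + 1, TRUE))
  }
  pick_virgin <- function(w) {
    for (try in 1:200) {
      s <- grid * sample.int(slots - w %/% grid - 1, 1) + 1
      if (disjoint_from_all(s, s + w - 1)) return(c(s, s + w - 1))
    }
    NULL
  }
  a_start <- integer(); a_end <- integer()
  b_start <- integer(); b_end <- integer()
  orient <- character()
  for (i in seq_len(n_pairs)) {
    w <- grid * sample(seq(min_w %/% grid, max_w %/% grid), 1)
    laminar_ok <- function(s, e) {
      all(vapply(sides, function(x)
        e < x[1] - 1 || s > x[2] + 1 ||      # disjoint
          (s >= x[1] && e <= x[2]) ||        # contained
          (s <= x[1] && e >= x[2]), TRUE))   # contains
    }
    nested <- NULL
    if (length(sides) && stats::runif(1) < nest_prob) {
      # nest the first side strictly inside an existing side
      wide <- which(vapply(sides, function(x)
        x[2] - x[1] + 1 >= w + 2 * grid, TRUE))
      if (length(wide)) {
        host <- sides[[sample(wide, 1)]]
        room <- (host[2] - host[1] + 1 - w) %/% grid - 1
        for (try in 1:20) {
          off <- grid * sample.int(room, 1)
          cand <- c(host[1] + off, host[1] + off + w - 1)
          if (laminar_ok(cand[1], cand[2])) { nested <- cand; break }
        }
      }
    }
    a <- if (!is.null(nested)) nested else pick_virgin(w)
    if (is.null(a)) next
    b <- NULL
    for (try in 1:200) {
      cand <- pick_virgin(w)
      if (is.null(cand)) break
      # the second side must also avoid the first side of this pair
      if (cand[2] < a[1] - 1 || cand[1] > a[2] + 1) { b <- cand; break }
    }
    if (is.null(b)) next
    a_start <- c(a_start, a[1]); a_end <- c(a_end, a[2])
    b_start <- c(b_start, b[1]); b_end <- c(b_end, b[2])
    orient <- c(orient, sample(c("same", "inverted"), 1))
    sides <- c(sides, list(a), list(b))
  }
  toy_pairs(a_start, a_end, b_start, b_end, orient)
}

# plain Rand index between two partitions given as label vectors
rand_index <- function(a, b) {
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}

# naive position-by-position IUPAC motif scan (independent of
# Biostrings matching); counts overlapping hits on both strands
naive_motif_count <- function(seq_str, motif = "CCNCCNTNNCCNC",
                              bothStrands = TRUE) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"),
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))
  count_one <- function(s, pat) {
    sc <- strsplit(s, "")[[1]]
    pc <- strsplit(pat, "")[[1]]
    m <- length(pc); n <- length(sc)
    if (n < m) return(0L)
    # sliding-window check, one pattern position at a time
    ok <- rep(TRUE, n - m + 1L)
    for (j in seq_len(m))
      ok <- ok & sc[seq.int(j, n - m + j)] %in% iupac[[pc[j]]]
    sum(ok)
  }
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
          collapse = "")
  }
  n <- count_one(seq_str, motif)
  if (bothStrands) n <- n + count_one(revcomp(seq_str), motif)
  n
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
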