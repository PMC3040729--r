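test_that("overlapping duplicons merge into one locus", {
  p <- toy_pairs(c(1001, 1051), c(1100, 1150), c(5001, 9001),
                 c(5100, 9100))
  loci <- mergeLoci(p)
  expect_equal(length(loci), 3L)
  expect_equal(start(loci)[1], 1001)
  expect_equal(end(loci)[1], 1150)
})

test_that("locus merging matches a per-base coverage oracle", {
  set.seed(9)
  for (rep_i in 1:20) {
    p <- random_grid_instance(n_pairs = sample(3:8, 1))
    loci <- mergeLoci(p)
    # per-base boolean coverage oracle
    mask <- logical(12000)
    for (gr in list(firstRanges(p), secondRanges(p)))
      for (i in seq_along(gr))
        mask[start(gr)[i]:end(gr)[i]] <- TRUE
    runs <- rle(mask)
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    expect_equal(start(loci), starts[runs$values])
    expect_equal(end(loci), ends[runs$values])
  }
})

test_that("loci sharing a family form one group", {
  p <- toy_pairs(1001, 2000, 9001, 10000, frac = 0.95)
  dec <- decomposeSDs(p)
  loci <- groupLoci(mergeLoci(p), dec$subunits)
  expect_equal(length(unique(loci$group_id)), 1L)
  # unrelated pair far away forms its own group
  p2 <- c(p, toy_pairs(50001, 52000, 70001, 72000, frac = 0.95))
  dec2 <- decomposeSDs(p2)
  loci2 <- groupLoci(mergeLoci(p2), dec2$subunits)
  expect_equal(length(unique(loci2$group_id)), 2L)
})

test_that("the five-locus fixture groups around the largest locus", {
  p <- fig1Fixture()
  dec <- decomposeSDs(p)
  map <- buildDuplicationMap(p, dec$subunits)
  loci <- dupLoci(map)
  expect_equal(length(loci), 5L)
  expect_equal(length(unique(loci$group_id)), 1L)
  pl <- placements(map)
  anchor <- pl$locus_id[pl$is_anchor]
  # the anchor is the first (largest, 5 kb) locus
  expect_equal(anchor, loci$locus_id[which.max(width(loci))])
  expect_equal(start(loci[loci$locus_id == anchor]), 17100001)
  # every member shares labels with the anchor and is placed
  expect_true(all(!is.na(pl$anchor_offset)))
})

test_that("anchor alignment detects orientation and disruptions", {
  # member locus whose label string equals an anchor substring
  su <- GRanges("chrT", IRanges(c(1, 101, 201, 1001, 1101),
                                width = 100))
  su$subunit_id <- sprintf("S%d", 1:5)
  su$family_id <- c("F1", "F2", "F3", "F3", "F2")
  loci <- GRanges("chrT", IRanges(c(1, 1001), c(300, 1200)))
  loci$locus_id <- c("L001", "L002")
  loci$group_id <- "G01"
  pl <- alignToAnchor(loci, su)
  expect_true(pl$is_anchor[1])
  # member labels (F3, F2) match the anchor's (F1, F2, F3) reversed
  expect_equal(pl$orientation[2], "inverted")
  expect_equal(pl$n_matched[2], 2L)
  expect_equal(pl$n_disrupted[2], 0L)
})

test_that("member with no shared label is unplaced, not an error", {
  su <- GRanges("chrT", IRanges(c(1, 101, 1001), width = 50))
  su$subunit_id <- sprintf("S%d", 1:3)
  su$family_id <- c("F1", "F2", "F9")
  loci <- GRanges("chrT", IRanges(c(1, 1001), c(150, 1050)))
  loci$locus_id <- c("L001", "L002"); loci$group_id <- "G01"
  pl <- alignToAnchor(loci, su)
  expect_true(is.na(pl$anchor_offset[2]))
  expect_equal(pl$n_matched[2], 0L)
})

test_that("recurrent breakpoint families need strictly more than five hits", {
  mk_map <- function(n_members) {
    # one anchor plus n members, all single-subunit loci of family F1
    starts <- seq(1, by = 1000, length.out = n_members + 1)
    su <- GRanges("chrT", IRanges(starts, width = 100))
    su$subunit_id <- sprintf("S%d", seq_along(su))
    su$family_id <- "F1"
    loci <- GRanges("chrT", IRanges(starts, width = 100))
    loci$locus_id <- sprintf("L%03d", seq_along(loci))
    loci$group_id <- "G01"
    pl <- alignToAnchor(loci, su)
    methods::new("DuplicationMap", loci = loci, placements = pl,
                 subunits = su)
  }
  # 5 placed members -> 10 end hits of F1 -> recurrent
  # (each member contributes its first and last subunit; here both are
  # the same single subunit, so counts double)
  rep5 <- breakpointFamilies(mk_map(2))$report   # 2 members -> 4 hits
  expect_false(rep5$recurrent)
  rep6 <- breakpointFamilies(mk_map(3))$report   # 3 members -> 6 hits
  expect_true(rep6$recurrent)
})

test_that("alu adjacency of breakpoint families uses the +/-W window", {
  su <- GRanges("chrT", IRanges(c(1, 1001, 2001, 3001, 4001, 5001,
                                  6001), width = 100))
  su$subunit_id <- sprintf("S%d", 1:7)
  su$family_id <- "F1"
  loci <- su
  loci$locus_id <- sprintf("L%03d", 1:7)
  loci$group_id <- "G01"
  pl <- alignToAnchor(loci, su[, c("subunit_id", "family_id")])
  map <- methods::new("DuplicationMap", loci = loci, placements = pl,
                      subunits = su)
  reps <- GRanges("chrT", IRanges(110, 400))  # just inside the window
  reps$name <- "AluY"; reps$repClass <- "SINE/Alu"
  res <- breakpointFamilies(map, reps, W = 10)
  expect_true(res$report$recurrent[1])
  expect_true(res$report$alu_adjacent[1])
  # 11 bases away: outside the window
  reps2 <- GenomicRanges::shift(reps, 1)
  res2 <- breakpointFamilies(map, reps2, W = 10)
  expect_false(res2$report$alu_adjacent[1])
})

test_that("top-level fraction is 1 for single-locus groups and 0.5 for
           two equal loci", {
  p1 <- toy_pairs(1001, 2000, 9001, 10000, frac = 0.95)
  dec1 <- decomposeSDs(p1)
  map1 <- buildDuplicationMap(p1, dec1$subunits)
  tf <- topLevelFraction(map1, p1)
  expect_equal(tf$fraction_locus_bases, 0.5)  # anchor is one of two
  # a single locus with itself as anchor
  su <- dec1$subunits[1]
  loci <- mergeLoci(p1)[1]
  loci$group_id <- "G01"
  pl <- alignToAnchor(loci, su)
  map_single <- methods::new("DuplicationMap", loci = loci,
                             placements = pl, subunits = su)
  expect_equal(topLevelFraction(map_single, p1)$fraction_locus_bases, 1)
})
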