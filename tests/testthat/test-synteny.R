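# helpers building small collinear worlds ------------------------------

collinear_blocks <- function(segments, species = "sp") {
  # segments: data.frame(ref_start, ref_end, target_start)
  data.frame(query = paste0(species, "_chr"),
             query_start = segments$target_start,
             query_end = segments$target_start +
               (segments$ref_end - segments$ref_start),
             ref = "chrS",
             ref_start = segments$ref_start, ref_end = segments$ref_end,
             strand = "+", identity = 0.98)
}

test_that("a collinear species yields a full monotone landmark map", {
  uniq <- GRanges("chrS", IRanges(c(1, 20001, 40001),
                                  c(10000, 30000, 50000)))
  blk <- collinear_blocks(data.frame(ref_start = 1, ref_end = 50000,
                                     target_start = 1))
  map <- buildLandmarkMap(uniq, blk)
  expect_equal(nrow(map), 3L)
  expect_equal(map$target_start, c(1, 20001, 40001))
  expect_equal(nrow(attr(map, "dropped")), 0L)
})

test_that("a translocated anchor is dropped from the landmark map", {
  uniq <- GRanges("chrS", IRanges(c(1, 20001, 40001),
                                  c(10000, 30000, 50000)))
  blk <- rbind(
    collinear_blocks(data.frame(ref_start = 1, ref_end = 10000,
                                target_start = 1)),
    collinear_blocks(data.frame(ref_start = 20001, ref_end = 30000,
                                target_start = 90001)),  # translocated
    collinear_blocks(data.frame(ref_start = 40001, ref_end = 50000,
                                target_start = 40001)))
  map <- buildLandmarkMap(uniq, blk)
  expect_equal(nrow(map), 2L)
  expect_equal(nrow(attr(map, "dropped")), 1L)
  expect_equal(attr(map, "dropped")$human_start, 20001)
})

test_that("without alignments every call is ambiguous", {
  su <- GRanges("chrS", IRanges(15001, 16000))
  su$subunit_id <- "S001"
  empty_map <- buildLandmarkMap(GRanges(), data.frame())
  calls <- callSynteny(su, empty_map, data.frame(), "sp")
  expect_equal(calls$status, "ambiguous")
})

test_that("present, absent and ambiguous calls follow the three rules", {
  su <- GRanges("chrS", IRanges(12001, 14000))
  su$subunit_id <- "S001"
  uniq <- GRanges("chrS", IRanges(c(1, 20001), c(10000, 30000)))
  # case 1: subunit aligned between the anchors -> present
  blk1 <- collinear_blocks(data.frame(
    ref_start = c(1, 12001, 20001), ref_end = c(10000, 14000, 30000),
    target_start = c(1, 12001, 20001)))
  m1 <- buildLandmarkMap(uniq, blk1)
  expect_equal(callSynteny(su, m1, blk1, "sp")$status, "present")
  # case 2: no alignment for the subunit, target window collapsed to
  # less than half the human distance -> absent
  blk2 <- collinear_blocks(data.frame(
    ref_start = c(1, 20001), ref_end = c(10000, 30000),
    target_start = c(1, 12001)))   # target window 2 kb vs human 10 kb
  m2 <- buildLandmarkMap(uniq, blk2)
  expect_equal(callSynteny(su, m2, blk2, "sp")$status, "absent")
  # case 3: no alignment but window not collapsed -> ambiguous
  blk3 <- collinear_blocks(data.frame(
    ref_start = c(1, 20001), ref_end = c(10000, 30000),
    target_start = c(1, 20001)))
  m3 <- buildLandmarkMap(uniq, blk3)
  expect_equal(callSynteny(su, m3, blk3, "sp")$status, "ambiguous")
})

test_that("the N-gap plus random-contig rescue rule applies", {
  su <- GRanges("chrS", IRanges(12001, 14000))
  su$subunit_id <- "S001"
  uniq <- GRanges("chrS", IRanges(c(1, 20001), c(10000, 30000)))
  blk <- rbind(
    collinear_blocks(data.frame(
      ref_start = c(1, 20001), ref_end = c(10000, 30000),
      target_start = c(1, 20001))),
    data.frame(query = "chrUn_random", query_start = 501,
               query_end = 2500, ref = "chrS", ref_start = 12001,
               ref_end = 14000, strand = "+", identity = 0.97))
  m <- buildLandmarkMap(uniq, blk)
  # expected window on target is [10000, 20001]; declare it N
  targetN <- GRanges("sp_chr", IRanges(10000, 20001))
  calls <- callSynteny(su, m, blk, "sp", targetN = targetN)
  expect_equal(calls$status, "present_rescued")
  # without the N annotation the same input is ambiguous
  calls2 <- callSynteny(su, m, blk, "sp")
  expect_equal(calls2$status, "ambiguous")
})

test_that("rule precedence puts present above rescue and absence", {
  su <- GRanges("chrS", IRanges(12001, 14000))
  su$subunit_id <- "S001"
  uniq <- GRanges("chrS", IRanges(c(1, 20001), c(10000, 30000)))
  # aligned in window AND N-rich window AND random-contig hit:
  blk <- rbind(
    collinear_blocks(data.frame(
      ref_start = c(1, 12001, 20001), ref_end = c(10000, 14000, 30000),
      target_start = c(1, 12001, 20001))),
    data.frame(query = "chrUn_random", query_start = 501,
               query_end = 2500, ref = "chrS", ref_start = 12001,
               ref_end = 14000, strand = "+", identity = 0.97))
  m <- buildLandmarkMap(uniq, blk)
  targetN <- GRanges("sp_chr", IRanges(10000, 20001))
  expect_equal(callSynteny(su, m, blk, "sp", targetN = targetN)$status,
               "present")
})

test_that("raising the coverage requirement only demotes present calls", {
  su <- GRanges("chrS", IRanges(12001, 14000))
  su$subunit_id <- "S001"
  uniq <- GRanges("chrS", IRanges(c(1, 20001), c(10000, 30000)))
  # block covers 60% of the subunit
  blk <- rbind(
    collinear_blocks(data.frame(
      ref_start = c(1, 20001), ref_end = c(10000, 30000),
      target_start = c(1, 20001))),
    collinear_blocks(data.frame(ref_start = 12001, ref_end = 13200,
                                target_start = 12001)))
  m <- buildLandmarkMap(uniq, blk)
  rank_of <- c(present = 3, present_rescued = 2, ambiguous = 1,
               absent = 1)
  prev <- Inf
  for (cf in c(0.3, 0.5, 0.7, 0.9)) {
    st <- callSynteny(su, m, blk, "sp", covFrac = cf)$status
    expect_true(rank_of[[st]] <= prev)
    prev <- rank_of[[st]]
  }
})

test_that("synteny summary counts rescued calls as present and takes
           the union across species", {
  calls <- data.frame(
    subunit_id = rep(c("S1", "S2"), 2),
    species = rep(c("a", "b"), each = 2),
    status = c("present", "absent", "absent", "present_rescued"))
  s <- syntenySummary(calls)
  expect_equal(unname(s$per_species), c(50, 50))
  expect_equal(s$any_species, 100)  # each subunit present somewhere
  expect_equal(s$human_only, 0)
  calls$status <- "absent"
  expect_equal(syntenySummary(calls)$human_only, 100)
})
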