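test_that("a single pair yields its four endpoints and two subunits", {
  p <- toy_pairs(101, 200, 501, 600)
  bp <- propagateBreakpoints(p)
  expect_equal(bp, c(101, 201, 501, 601))
  su <- buildSubunits(bp, p)
  expect_equal(length(su), 2L)
  expect_equal(width(su), c(100, 100))
  expect_equal(oracleDecompose(p), bp)
})

test_that("zero pairs decompose to zero subunits", {
  p <- toy_pairs(integer(), integer(), integer(), integer(),
                 character(), numeric())
  expect_equal(propagateBreakpoints(p), numeric())
  expect_equal(length(buildSubunits(numeric(), p)), 0L)
  expect_equal(subunitStats(GRanges())$n, 0L)
})

test_that("a nested pair splits the larger side into three subunits", {
  # duplicon B2 [1051,1150] lies strictly inside A1's paralog [1001,1300];
  # its projection into A2 [5001,5300] splits that side in three
  p <- toy_pairs(c(1001, 5051), c(1300, 5150), c(5001, 1051),
                 c(5300, 1150))
  bp <- propagateBreakpoints(p)
  su <- buildSubunits(bp, p)
  side2 <- su[start(su) >= 5001 & end(su) <= 5300]
  expect_equal(length(side2), 3L)
  expect_equal(width(side2), c(50, 100, 150))
  # and the projection propagates back to the first side as well
  side1 <- su[start(su) >= 1001 & end(su) <= 1300]
  expect_equal(length(side1), 3L)
})

test_that("breakpoints propagate across transitive pair chains", {
  # a <-> b and b <-> c: a breakpoint inside a must surface in c
  p <- toy_pairs(c(1001, 2001, 1201), c(1400, 2400, 1300),
                 c(2001, 3001, 5001), c(2400, 3400, 5100))
  bp <- propagateBreakpoints(p)
  # third pair cuts a at 1201/1301 -> b at 2201/2301 -> c at 3201/3301
  expect_true(all(c(3201, 3301) %in% bp))
  expect_equal(sort(bp), sort(oracleDecompose(p)))
})

test_that("subunits tile the duplicon union exactly", {
  set.seed(42)
  for (rep_i in 1:10) {
    p <- random_grid_instance(n_pairs = 6)
    dec <- decomposeSDs(p)
    su <- dec$subunits
    cov <- reduce(c(firstRanges(p), secondRanges(p)),
                  ignore.strand = TRUE)
    # no overlaps
    expect_true(all(start(su)[-1] > end(su)[-length(su)]))
    # exact tiling of the union
    expect_equal(sum(width(su)), sum(width(cov)))
    expect_equal(sum(width(GenomicRanges::setdiff(cov, su))), 0)
  }
})

test_that("decomposition is idempotent on its induced boundaries", {
  set.seed(7)
  p <- random_grid_instance(n_pairs = 8)
  bp1 <- propagateBreakpoints(p)
  bp2 <- propagateBreakpoints(p, decompositionParams())
  expect_identical(bp1, bp2)
})

test_that("fast path agrees with the per-base oracle on random toys", {
  set.seed(101)
  tol <- decompositionParams()$mergeTolerance
  for (rep_i in 1:100) {
    p <- random_grid_instance(n_pairs = sample(3:10, 1))
    fast <- propagateBreakpoints(p)
    slow <- oracleDecompose(p)
    # every fast boundary within tolerance of an oracle boundary
    expect_true(all(vapply(fast, function(b) min(abs(slow - b)), 1) <= tol))
    # and vice versa
    expect_true(all(vapply(slow, function(b) min(abs(fast - b)), 1) <= tol))
  }
})

test_that("short segments merge into their neighbours", {
  # second pair projects a cut 20 b from an existing one; with
  # minSubunitLength 30 the 20 b sliver merges away
  p <- toy_pairs(c(1001, 1021), c(1500, 1520), c(3001, 5001),
                 c(3500, 5500),
                 frac = 0.95)
  su <- buildSubunits(propagateBreakpoints(p, decompositionParams(
    mergeTolerance = 5)), p,
    decompositionParams(mergeTolerance = 5, minSubunitLength = 30))
  expect_true(all(width(su) >= 30))
})

test_that("families form from qualifying pairs and stay symmetric", {
  p <- toy_pairs(1001, 2000, 5001, 6000, frac = 0.95)
  dec <- decomposeSDs(p)
  expect_equal(nrow(dec$families), 1L)
  expect_equal(dec$families$n_members, 2L)
  expect_equal(length(unique(dec$subunits$family_id)), 1L)
  # below the identity threshold no family forms
  p_low <- toy_pairs(1001, 2000, 5001, 6000, frac = 0.85)
  su <- buildSubunits(propagateBreakpoints(p_low), p_low)
  fam <- classifyFamilies(su, p_low)
  expect_equal(nrow(fam$families), 0L)
  expect_equal(length(fam$unassigned), 2L)
})

test_that("family classification is transitive across shared subunits", {
  # a~b via pair1 and b~c via pair2 put a, b, c in one family
  p <- toy_pairs(c(1001, 3001), c(2000, 4000), c(3001, 7001),
                 c(4000, 8000), frac = 0.95)
  dec <- decomposeSDs(p)
  expect_equal(nrow(dec$families), 1L)
  expect_equal(dec$families$n_members, 3L)
})

test_that("inverted pairs project breakpoints through the reversed map", {
  # pair2 cuts the second side of pair1 at 5201; through the inverted
  # map that cut must appear at 1001 + (5301-5201) = 1100/1101 region
  p <- toy_pairs(c(1001, 5201), c(1300, 5300), c(5001, 7001),
                 c(5300, 7100), orientation = c("inverted", "same"))
  bp <- propagateBreakpoints(p)
  expect_true(1101 %in% bp)
  expect_equal(sort(bp), sort(oracleDecompose(p)))
})

test_that("subunit statistics report count and central values", {
  su <- GRanges("chrT", IRanges(c(1, 1001, 100001),
                                width = c(30, 1333, 63800)))
  s <- subunitStats(su)
  expect_equal(s$n, 3L)
  expect_equal(s$median_bp, 1333)
  expect_equal(s$min_bp, 30)
  expect_equal(s$max_bp, 63800)
})
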