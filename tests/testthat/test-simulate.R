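nested_cfg <- function(seed = 42) {
  simConfig(genome_length = 200000, seed = seed,
            event_script = list(
              duplicationEvent(10, 20001, 32000, 100001),
              duplicationEvent(6, 100001, 108000, 150001),
              duplicationEvent(3, 24001, 30000, 180001)))
}

test_that("an empty event script yields no pairs and no boundaries", {
  sim <- simulateGenome(simConfig(genome_length = 50000, n_events = 0,
                                  seed = 3))
  expect_equal(length(sim$truth$pairs), 0L)
  expect_equal(sim$truth$boundaries, numeric())
  expect_equal(length(sim$sequence), 50000L)
})

test_that("a single age-zero event gives an identical pair and its four
           boundaries", {
  cfg <- simConfig(genome_length = 60000, seed = 5,
                   species_split_ages = numeric(),
                   event_script = list(
                     duplicationEvent(0, 10001, 15000, 40001)))
  sim <- simulateGenome(cfg)
  expect_equal(nrow(sim$truth$events), 1L)
  expect_equal(sim$truth$events$identity, 1)
  expect_equal(sim$truth$boundaries, c(10001, 15001, 40001, 45001))
  # the copy is literally identical
  expect_equal(as.character(Biostrings::subseq(sim$sequence, 10001, 15000)),
               as.character(Biostrings::subseq(sim$sequence, 40001, 45000)))
})

test_that("identical configs give byte-identical outputs", {
  s1 <- simulateGenome(simConfig(genome_length = 40000, n_events = 3,
                                 seed = 99))
  s2 <- simulateGenome(simConfig(genome_length = 40000, n_events = 3,
                                 seed = 99))
  expect_identical(as.character(s1$sequence), as.character(s2$sequence))
  expect_identical(s1$truth$events, s2$truth$events)
  expect_identical(as.data.frame(s1$truth$repeats),
                   as.data.frame(s2$truth$repeats))
})

test_that("pair identity tracks the molecular clock, verified by direct
           Hamming count", {
  sim <- simulateGenome(nested_cfg())
  ev <- sim$truth$events
  rate <- sim$truth$config$divergence_rate
  # independent recount from the emitted sequence
  for (i in seq_len(nrow(ev))) {
    a <- strsplit(as.character(Biostrings::subseq(
      sim$sequence, ev$a_start[i], ev$a_end[i])), "")[[1]]
    b <- strsplit(as.character(Biostrings::subseq(
      sim$sequence, ev$b_start[i], ev$b_end[i])), "")[[1]]
    ident <- mean(a == b)
    expect_equal(ident, ev$identity[i])
    expect_lt(abs(ident - (1 - 2 * rate * ev$age[i])), 0.005)
  }
})

test_that("older events never look more identical than younger ones", {
  for (seed in c(1, 2, 3, 4, 5)) {
    sim <- simulateGenome(nested_cfg(seed))
    ev <- sim$truth$events[order(-sim$truth$events$age), ]
    # identities non-decreasing as age decreases, within 3 SE
    se <- sqrt(0.03 * 0.97 / min(ev$a_end - ev$a_start + 1))
    expect_true(all(diff(ev$identity) > -3 * se))
  }
})

test_that("planted repeat bases are conserved through the annotation file", {
  sim <- simulateGenome(simConfig(genome_length = 80000, n_events = 2,
                                  seed = 13))
  tmp <- withr::local_tempfile(fileext = ".out")
  writeRepeatMasker(sim$truth$repeats, tmp)
  back <- readRepeatMasker(tmp)
  expect_equal(sum(width(back)), sum(width(sim$truth$repeats)))
  expect_equal(back$name, sim$truth$repeats$name)
})

test_that("species with split age zero equals the reference", {
  cfg <- simConfig(genome_length = 60000, seed = 21,
                   species_split_ages = c(self = 0),
                   event_script = list(
                     duplicationEvent(5, 10001, 12000, 30001)))
  sim <- simulateGenome(cfg)
  sp <- emitSpeciesGenome(sim, "self")
  expect_equal(as.character(sp$sequence), as.character(sim$sequence))
  expect_true(all(sp$presence$present))
})

test_that("a split older than every event removes all duplications", {
  cfg <- simConfig(genome_length = 60000, seed = 22,
                   species_split_ages = c(old = 50),
                   event_script = list(
                     duplicationEvent(5, 10001, 12000, 30001),
                     duplicationEvent(9, 40001, 42000, 20001)))
  sim <- simulateGenome(cfg)
  sp <- emitSpeciesGenome(sim, "old")
  expect_equal(length(sp$sequence), 60000L)   # no insertions replayed
  # only destination copies are missing; source-side subunits remain
  pres <- merge(sp$presence, as.data.frame(sim$truth$subunits),
                by = "subunit_id")
  dest <- sim$truth$events
  in_dest <- vapply(seq_len(nrow(pres)), function(i)
    any(dest$b_start <= pres$start[i] & dest$b_end >= pres$end[i]),
    TRUE)
  expect_equal(pres$present, !in_dest)
})

test_that("presence tables equal a manual event-age filter", {
  cfg <- simConfig(genome_length = 150000, seed = 31,
                   species_split_ages = c(mid = 7),
                   event_script = list(
                     duplicationEvent(12, 10001, 13000, 60001),
                     duplicationEvent(9, 20001, 22000, 70001),
                     duplicationEvent(5, 30001, 32000, 80001),
                     duplicationEvent(2, 40001, 42000, 90001)))
  sim <- simulateGenome(cfg)
  sp <- emitSpeciesGenome(sim, "mid")
  su <- sim$truth$subunits
  ev <- sim$truth$events
  manual <- vapply(seq_along(su), function(i) {
    hit <- which(ev$b_start <= start(su)[i] & ev$b_end >= end(su)[i])
    if (!length(hit)) TRUE else ev$age[hit] > 7
  }, TRUE)
  expect_equal(sp$presence$present, manual)
  # events of age 12 and 9 survive; 5 and 2 do not
  expect_equal(length(sp$sequence), 150000L + 3000L + 2000L)
})

test_that("unknown species labels are rejected", {
  sim <- simulateGenome(simConfig(genome_length = 30000, n_events = 0,
                                  seed = 1))
  expect_error(emitSpeciesGenome(sim, "yeti"), "unknown species")
})

test_that("clone with no indels equals the reference substring", {
  sim <- simulateGenome(simConfig(genome_length = 50000, n_events = 0,
                                  seed = 2))
  cl <- emitClones(sim, list(cloneSpec(10001, 30000)))
  expect_equal(as.character(cl$sequences[[1]]),
               as.character(Biostrings::subseq(sim$sequence, 10001,
                                               30000)))
  expect_equal(nrow(callCNVs(cl$blocks)), 0L)
})

test_that("a 300 b gain lengthens the clone by exactly 300", {
  sim <- simulateGenome(simConfig(genome_length = 50000, n_events = 0,
                                  seed = 2))
  cl <- emitClones(sim, list(cloneSpec(10001, 30000, list(
    list(position = 20001, length = 300, kind = "gain",
         breakpoint_mode = "random")))))
  expect_equal(length(cl$sequences[[1]]), 20000L + 300L)
})

test_that("NAHR clone indels must span two same-label planted repeats", {
  sim <- simulateGenome(simConfig(genome_length = 100000, n_events = 0,
                                  seed = 7))
  bad <- list(cloneSpec(10001, 50000, list(
    list(position = 20001, length = 5000, kind = "loss",
         breakpoint_mode = "nahr_alu_pair"))))
  expect_error(emitClones(sim, bad), "same-label")
  # a valid NAHR indel records its repeat pair
  ok_script <- makeCloneScript(sim, n_clones = 3, clone_length = 40000,
                               nahr_fraction = 1, seed = 11)
  cl <- emitClones(sim, ok_script)
  nahr <- cl$truth[cl$truth$breakpoint_mode == "nahr_alu_pair", ]
  expect_gt(nrow(nahr), 0)
  expect_true(all(!is.na(nahr$repeat_span)))
})

test_that("indels outside the clone span are rejected at construction", {
  expect_error(cloneSpec(1000, 5000, list(
    list(position = 9000, length = 300, kind = "loss",
         breakpoint_mode = "random"))), "outside clone span")
  expect_error(cloneSpec(1000, 5000, list(
    list(position = 2000, length = 6000, kind = "loss",
         breakpoint_mode = "random"))), "extends past")
})

test_that("colliding destinations raise a configuration error naming
           events", {
  cfg <- simConfig(genome_length = 60000, seed = 1,
                   species_split_ages = numeric(),
                   event_script = list(
                     duplicationEvent(9, 10001, 12000, 30001),
                     duplicationEvent(5, 40001, 41500, 30501)))
  expect_error(simulateGenome(cfg), "cannot be serialized")
})

test_that("destination inside the source is rejected", {
  expect_error(duplicationEvent(5, 10001, 12000, 11000),
               "outside the source")
})
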