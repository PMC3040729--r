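# Synthetic genomes with scripted duplication histories.
#
# The generator emulates the statistical structure a duplication
# analysis sees - clustered duplication blocks, per-pair divergence
# proportional to event age under a molecular clock, Alu/L1-like decoy
# repeats at a configurable fraction of event endpoints, derived
# species genomes obtained by replaying only events older than the
# split, and clone haplotypes with large indels - together with exact
# ground truth for every quantity the pipeline estimates.

# fixed synthetic decoy consensus sequences (not real repeat sequence;
# the labels drive all downstream logic)
.decoy_library <- function() {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20110126)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                 replace = TRUE,
                                 prob = c(.2, .3, .3, .2)),
                          collapse = "")
  list(AluY = mk(300), AluSx = mk(300), L1 = mk(2000))
}

#' Simulation configuration
#'
#' All generator parameters in one validated list. Defaults describe a
#' compact duplication-cluster region: a 200 kb genome, three decoy
#' repeat consensi (two 300 b Alu-like, one 2 kb L1-like), a molecular
#' clock of 0.0015 substitutions per base per unit age on each lineage
#' (so a pair diverges 3% per 10 age units), and primate-like split
#' ages.
#'
#' @param genome_length Genome size in bases (default 200000).
#' @param gc_content GC fraction of the background sequence
#'   (default 0.48).
#' @param repeat_library Named list of decoy consensus strings
#'   (default: synthetic AluY/AluSx/L1 decoys).
#' @param repeat_density Expected planted repeats per 10 kb
#'   (default 3).
#' @param event_script List of duplication events (see
#'   [duplicationEvent()]); `NULL` auto-generates `n_events` events.
#' @param n_events Number of auto-generated events when `event_script`
#'   is `NULL` (default 3).
#' @param core_reuse_prob For auto-generated scripts: probability that
#'   an event copies the recurring core region rather than a fresh one
#'   (default 0.7).
#' @param alu_at_breakpoint_prob Probability that an auto-generated
#'   event's endpoints are snapped to planted Alu-like repeats
#'   (default 0.5).
#' @param inversion_prob Probability an auto-generated event is
#'   inverted (default 0.2).
#' @param max_age Oldest auto-generated event age (default 20).
#' @param divergence_rate Substitutions per base per unit age per
#'   lineage (default 0.0015).
#' @param species_split_ages Named numeric vector of split ages
#'   (default `c(chimp = 6, orangutan = 16, macaque = 25)`).
#' @param clone_script List of clone specifications (see
#'   [cloneSpec()]); default empty.
#' @param min_event_length Minimum source length in bases
#'   (default 1000, the usual SD length threshold).
#' @param seed Integer RNG seed.
#' @return A validated named list.
#' @export
simConfig <- function(genome_length = 200000,
                      gc_content = 0.48,
                      repeat_library = .decoy_library(),
                      repeat_density = 3,
                      event_script = NULL,
                      n_events = 3,
                      core_reuse_prob = 0.7,
                      alu_at_breakpoint_prob = 0.5,
                      inversion_prob = 0.2,
                      max_age = 20,
                      divergence_rate = 0.0015,
                      species_split_ages = c(chimp = 6, orangutan = 16,
                                             macaque = 25),
                      clone_script = list(),
                      min_event_length = 1000,
                      seed = 1L) {
  stopifnot(genome_length > 0,
            gc_content >= 0, gc_content <= 1,
            alu_at_breakpoint_prob >= 0, alu_at_breakpoint_prob <= 1,
            inversion_prob >= 0, inversion_prob <= 1,
            core_reuse_prob >= 0, core_reuse_prob <= 1,
            divergence_rate >= 0, repeat_density >= 0,
            all(species_split_ages >= 0))
  if (!is.null(event_script)) {
    ages <- vapply(event_script, `[[`, 1, "age")
    if (any(ages < 0)) stop("event ages must be non-negative")
  }
  list(genome_length = as.integer(genome_length),
       gc_content = gc_content,
       repeat_library = repeat_library,
       repeat_density = repeat_density,
       event_script = event_script,
       n_events = n_events,
       core_reuse_prob = core_reuse_prob,
       alu_at_breakpoint_prob = alu_at_breakpoint_prob,
       inversion_prob = inversion_prob,
       max_age = max_age,
       divergence_rate = divergence_rate,
       species_split_ages = species_split_ages,
       clone_script = clone_script,
       min_event_length = as.integer(min_event_length),
       seed = as.integer(seed))
}

#' Construct a duplication event
#'
#' @param age Event age in clock units (applied oldest first;
#'   coordinates of younger events refer to the genome as already
#'   modified by older ones).
#' @param source_start,source_end Source interval, 1-based closed, on
#'   the genome as of the event's time.
#' @param destination Insertion point: the copy will occupy
#'   `[destination, destination + length - 1]` and everything at or
#'   beyond `destination` shifts right.
#' @param orientation `"forward"` or `"reverse"`.
#' @return A named list.
#' @export
duplicationEvent <- function(age, source_start, source_end, destination,
                             orientation = "forward") {
  stopifnot(age >= 0, source_start >= 1, source_end >= source_start,
            orientation %in% c("forward", "reverse"))
  if (destination >= source_start && destination <= source_end + 1L)
    stop("destination must lie outside the source interval")
  list(age = age, source_start = as.integer(source_start),
       source_end = as.integer(source_end),
       destination = as.integer(destination), orientation = orientation)
}

#' Construct a clone specification
#'
#' @param start,end Clone span on the reference, 1-based closed.
#' @param indels List of indel lists with fields `position` (reference
#'   coordinate of the left breakpoint), `length`, `kind`
#'   (`"gain"`/`"loss"`) and `breakpoint_mode` (`"random"` or
#'   `"nahr_alu_pair"`). CNV-scale indels are longer than 200 b, but
#'   shorter ones may be planted deliberately to probe the caller's
#'   gap threshold.
#' @return A named list.
#' @export
cloneSpec <- function(start, end, indels = list()) {
  stopifnot(start >= 1, end > start)
  for (iv in indels) {
    stopifnot(iv$length > 0, iv$kind %in% c("gain", "loss"),
              iv$breakpoint_mode %in% c("random", "nahr_alu_pair"))
    if (iv$position < start || iv$position > end)
      stop("indel at ", iv$position, " outside clone span ",
           start, "-", end)
    if (iv$kind == "loss" && iv$position + iv$length - 1 > end)
      stop("loss at ", iv$position, " extends past clone span")
  }
  list(start = as.integer(start), end = as.integer(end), indels = indels)
}

# substitute `nsub` random positions of a character-vector genome
.mutate <- function(seqc, nsub) {
  if (nsub <= 0) return(seqc)
  pos <- sample.int(length(seqc), min(nsub, length(seqc)))
  bases <- c("A", "C", "G", "T")
  cur <- seqc[pos]
  repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
  seqc[pos] <- repl
  seqc
}

# shift tracked positions for an insertion of `len` at `d`
.shift <- function(x, d, len) ifelse(x >= d, x + len, x)

#' Simulate a genome with a scripted duplication history
#'
#' Replays the event script oldest first on a random background with
#' planted decoy repeats, mutating the whole genome between events at
#' the configured clock rate, so each pair of copies diverges by about
#' `2 * divergence_rate * age`. Species snapshots are taken as the
#' clock passes each configured split age. Fully deterministic for a
#' fixed config (including seed).
#'
#' @param config A [simConfig()].
#' @return A list with `sequence` (a `DNAString`, chromosome name
#'   `"chrS"`), and `truth`: `events` (data frame of final-coordinate
#'   copy pairs with age, orientation and realized identity), `pairs`
#'   (an [SDPairSet-class] ready for decomposition), `boundaries`
#'   (exact subunit cut positions from the per-base genealogy),
#'   `subunits` (`GRanges` with `family_id`), `repeats` (planted
#'   repeat `GRanges`), `species_presence` (data frame subunit x
#'   species), internal species snapshots, and the config.
#' @export
simulateGenome <- function(config = simConfig()) {
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_content
  seqc <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  # ---- plant decoy repeats (replacement keeps coordinates stable)
  lib <- config$repeat_library
  n_rep <- round(config$repeat_density * L / 10000)
  rep_start <- integer(); rep_end <- integer(); rep_name <- character()
  occupied <- IRanges::IRanges()
  tries <- 0L
  while (length(rep_start) < n_rep && tries < 50L * n_rep) {
    tries <- tries + 1L
    lab <- sample(names(lib), 1L)
    w <- nchar(lib[[lab]])
    if (w + 2L >= L) next
    st <- sample.int(L - w - 1L, 1L) + 1L
    cand <- IRanges::IRanges(st, st + w - 1L)
    if (length(occupied) &&
        any(IRanges::overlapsAny(cand, occupied))) next
    occupied <- c(occupied, cand)
    seqc[st:(st + w - 1L)] <- strsplit(lib[[lab]], "")[[1]]
    rep_start <- c(rep_start, st); rep_end <- c(rep_end, st + w - 1L)
    rep_name <- c(rep_name, lab)
  }
  reps <- data.frame(start = rep_start, end = rep_end, name = rep_name)
  reps <- reps[order(reps$start), , drop = FALSE]
  # ---- event script
  script <- config$event_script
  if (is.null(script))
    script <- .auto_event_script(config, reps, L)
  if (length(script)) {
    ages <- vapply(script, `[[`, 1, "age")
    script <- script[order(-ages)]
  }
  # ---- timeline: events and species snapshots, oldest first
  splits <- config$species_split_ages
  rate <- config$divergence_rate
  pair_tab <- data.frame(a_start = integer(), a_end = integer(),
                         b_start = integer(), b_end = integer(),
                         orientation = character(), age = numeric(),
                         event = integer())
  snapshots <- list()
  ev_ages <- if (length(script)) vapply(script, `[[`, 1, "age") else
    numeric()
  t_now <- if (length(ev_ages)) max(c(ev_ages, splits)) else
    (if (length(splits)) max(splits) else 0)
  # species older than every event: snapshot of the pre-event genome
  times <- sort(unique(c(ev_ages, splits)), decreasing = TRUE)
  ev_ptr <- 1L
  for (tp in times) {
    # mutate down from t_now to tp
    dt <- t_now - tp
    if (dt > 0) seqc <- .mutate(seqc, stats::rbinom(1, length(seqc),
                                                    min(1, rate * dt)))
    t_now <- tp
    # snapshot species whose split age == tp (before same-age events:
    # an event of age equal to the split is NOT shared)
    for (sp in names(splits)[splits == tp])
      snapshots[[sp]] <- seqc
    # apply events of age == tp
    while (ev_ptr <= length(script) && script[[ev_ptr]]$age == tp) {
      ev <- script[[ev_ptr]]
      res <- .apply_event(seqc, ev, ev_ptr, pair_tab, reps)
      seqc <- res$seqc; pair_tab <- res$pair_tab; reps <- res$reps
      ev_ptr <- ev_ptr + 1L
    }
  }
  if (t_now > 0) {
    seqc <- .mutate(seqc, stats::rbinom(1, length(seqc),
                                        min(1, rate * t_now)))
    t_now <- 0
  }
  # a species with split age 0 and no age-0 event shares the final
  # genome; its snapshot was taken at time 0 in the loop when a 0 was
  # on the timeline, otherwise take it now
  for (sp in names(splits)[splits == 0])
    if (is.null(snapshots[[sp]])) snapshots[[sp]] <- seqc
  # ---- realized identity per pair (Hamming on emitted copies)
  ident <- vapply(seq_len(nrow(pair_tab)), function(i) {
    a <- seqc[pair_tab$a_start[i]:pair_tab$a_end[i]]
    b <- seqc[pair_tab$b_start[i]:pair_tab$b_end[i]]
    if (pair_tab$orientation[i] == "reverse")
      b <- rev(chartr("ACGT", "TGCA", b))
    mean(a == b)
  }, 1)
  pair_tab$identity <- if (nrow(pair_tab)) ident else numeric()
  chrom <- "chrS"
  pairs <- SDPairSet(
    GenomicRanges::GRanges(rep(chrom, nrow(pair_tab)),
                           IRanges::IRanges(pair_tab$a_start,
                                            pair_tab$a_end)),
    GenomicRanges::GRanges(rep(chrom, nrow(pair_tab)),
                           IRanges::IRanges(pair_tab$b_start,
                                            pair_tab$b_end)),
    ifelse(pair_tab$orientation == "reverse", "inverted", "same"),
    pair_tab$identity)
  # ---- exact truth: boundaries, subunits, families (per-base
  # genealogy closure over the event copy maps)
  truth_su <- .truth_subunits(pairs, chrom)
  # ---- species presence: originating event age vs split age
  presence <- .species_presence(truth_su$subunits, pair_tab, splits)
  rep_gr <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(reps$start, reps$end))
  rep_gr$name <- reps$name
  rep_gr$repClass <- ifelse(grepl("^Alu", reps$name), "SINE/Alu",
                            ifelse(grepl("^L1", reps$name), "LINE/L1",
                                   "Unknown"))
  seq_final <- Biostrings::DNAString(paste(seqc, collapse = ""))
  list(sequence = seq_final,
       chrom = chrom,
       truth = list(events = pair_tab,
                    pairs = pairs,
                    boundaries = truth_su$boundaries,
                    subunits = truth_su$subunits,
                    repeats = rep_gr,
                    species_presence = presence,
                    snapshots = snapshots,
                    config = config))
}

# auto-generate an event script: a recurring "core" source plus fresh
# sources, endpoints snapped to planted Alu-like repeats with the
# configured probability, destinations kept clear of existing copies
.auto_event_script <- function(config, reps, L) {
  n <- config$n_events
  if (n == 0) return(list())
  ages <- sort(stats::runif(n, 1, config$max_age), decreasing = TRUE)
  alus <- reps[grepl("^Alu", reps$name), , drop = FALSE]
  min_len <- config$min_event_length
  taken <- IRanges::IRanges()   # copy intervals in current coords
  script <- list()
  core <- NULL
  cur_L <- L
  pick_source <- function(cur_L, taken) {
    for (try in 1:100) {
      snap <- stats::runif(1) < config$alu_at_breakpoint_prob &&
        nrow(alus) >= 2
      if (snap) {
        i <- sample.int(nrow(alus), 1L)
        js <- which(alus$start > alus$end[i] + min_len - 600 &
                    alus$start < alus$end[i] + 4 * min_len)
        if (!length(js)) next
        j <- js[sample.int(length(js), 1L)]
        s <- alus$start[i]; e <- alus$end[j]
      } else {
        w <- round(stats::runif(1, min_len, 3 * min_len))
        if (w + 2 >= cur_L) next
        s <- sample.int(cur_L - w - 1L, 1L)
        e <- s + w - 1L
      }
      if (e - s + 1 < min_len || e > cur_L) next
      return(c(s, e))
    }
    NULL
  }
  for (k in seq_len(n)) {
    use_core <- !is.null(core) && stats::runif(1) < config$core_reuse_prob
    src <- if (use_core) core else pick_source(cur_L, taken)
    if (is.null(src)) next
    if (is.null(core)) core <- src
    len <- src[2] - src[1] + 1L
    # destination outside source and outside existing copies
    d <- NA
    for (try in 1:200) {
      cand <- sample.int(cur_L, 1L)
      if (cand >= src[1] && cand <= src[2] + 1L) next
      if (length(taken) &&
          any(BiocGenerics::start(taken) < cand &
              BiocGenerics::end(taken) >= cand)) next
      d <- cand; break
    }
    if (is.na(d)) next
    orient <- if (stats::runif(1) < config$inversion_prob) "reverse" else
      "forward"
    script[[length(script) + 1L]] <-
      duplicationEvent(ages[k], src[1], src[2], d, orient)
    # track shifts for subsequent picks
    shift_iv <- function(iv) {
      st <- .shift(BiocGenerics::start(iv), d, len)
      en <- .shift(BiocGenerics::end(iv), d, len)
      IRanges::IRanges(st, en)
    }
    taken <- shift_iv(taken)
    taken <- c(taken, IRanges::IRanges(.shift(src[1], d, len),
                                       .shift(src[2], d, len)),
               IRanges::IRanges(d, d + len - 1L))
    if (!is.null(core)) core <- .shift(core, d, len)
    alus$start <- .shift(alus$start, d, len)
    alus$end <- .shift(alus$end, d, len)
    cur_L <- cur_L + len
  }
  script
}

# apply one duplication event to the genome and all trackers
.apply_event <- function(seqc, ev, ev_id, pair_tab, reps) {
  L <- length(seqc)
  s <- ev$source_start; e <- ev$source_end; d <- ev$destination
  if (e > L || d > L + 1L)
    stop("event ", ev_id, " outside genome (length ", L, ")")
  if (d >= s && d <= e + 1L)
    stop("event ", ev_id, ": destination inside its own source")
  inside <- which((pair_tab$a_start < d & pair_tab$a_end >= d) |
                  (pair_tab$b_start < d & pair_tab$b_end >= d))
  if (length(inside))
    stop("configuration error: event ", ev_id,
         " inserts inside the copy created by event ",
         pair_tab$event[inside[1]],
         "; these events cannot be serialized")
  copy <- seqc[s:e]
  if (ev$orientation == "reverse")
    copy <- rev(chartr("ACGT", "TGCA", copy))
  len <- length(copy)
  seqc <- append(seqc, copy, after = d - 1L)
  # shift existing trackers
  for (cl in c("a_start", "a_end", "b_start", "b_end"))
    pair_tab[[cl]] <- .shift(pair_tab[[cl]], d, len)
  # repeats: shift; truncation impossible at d inside a copy is already
  # excluded, but d may split a background repeat - split the record
  split_hit <- which(reps$start < d & reps$end >= d)
  if (length(split_hit)) {
    for (h in split_hit) {
      reps <- rbind(reps, data.frame(start = d + len,
                                     end = reps$end[h] + len,
                                     name = reps$name[h]))
      reps$end[h] <- d - 1L
    }
  }
  keep <- reps$end >= reps$start
  reps <- reps[keep, , drop = FALSE]
  reps$start <- .shift(reps$start, d, len)
  reps$end <- ifelse(reps$end >= d, reps$end + len, reps$end)
  # repeats inside the source are duplicated into the copy
  s2 <- .shift(s, d, len); e2 <- .shift(e, d, len)
  in_src <- which(reps$start <= e2 & reps$end >= s2 &
                  !(reps$start >= d & reps$end < d + len))
  new_reps <- list()
  for (h in in_src) {
    lo <- max(reps$start[h], s2); hi <- min(reps$end[h], e2)
    if (ev$orientation == "reverse") {
      nlo <- d + (e2 - hi); nhi <- d + (e2 - lo)
    } else {
      nlo <- d + (lo - s2); nhi <- d + (hi - s2)
    }
    new_reps[[length(new_reps) + 1L]] <-
      data.frame(start = nlo, end = nhi, name = reps$name[h])
  }
  if (length(new_reps)) reps <- rbind(reps, do.call(rbind, new_reps))
  reps <- reps[order(reps$start), , drop = FALSE]
  pair_tab <- rbind(pair_tab, data.frame(
    a_start = s2, a_end = e2, b_start = d, b_end = d + len - 1L,
    orientation = ev$orientation, age = ev$age, event = ev_id))
  list(seqc = seqc, pair_tab = pair_tab, reps = reps)
}

# exact subunits + families from the per-base genealogy closure
.truth_subunits <- function(pairs, chrom) {
  if (!length(pairs)) {
    su <- GenomicRanges::GRanges()
    su$subunit_id <- character(); su$family_id <- character()
    return(list(boundaries = numeric(), subunits = su))
  }
  cl <- .base_closure(pairs)
  bounds <- .closure_boundaries(cl)
  pos <- cl$pos
  run_break <- c(TRUE, diff(pos) != 1)
  run_id <- cumsum(run_break)
  segs <- list()
  for (r in unique(run_id)) {
    p <- pos[run_id == r]
    cuts <- sort(unique(c(p[1], bounds[bounds > p[1] &
                                       bounds <= p[length(p)]],
                          p[length(p)] + 1)))
    segs[[r]] <- cbind(cuts[-length(cuts)], cuts[-1] - 1)
  }
  segs <- do.call(rbind, segs)
  su <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(segs[, 1], segs[, 2]))
  su <- BiocGenerics::sort(su)
  su$subunit_id <- sprintf("T%03d", seq_along(su))
  # families: link subunits through the class of their first base
  first_base <- BiocGenerics::start(su)
  comp_of <- function(p) cl$comp[match(p, pos)]
  members <- split(pos, cl$comp)
  seg_of <- function(p) {
    findInterval(p, BiocGenerics::start(su))
  }
  edges <- list()
  for (k in seq_along(su)) {
    cc <- comp_of(first_base[k])
    mem <- members[[as.character(cc)]]
    tgt <- unique(seg_of(mem))
    tgt <- tgt[tgt != k & tgt >= 1]
    if (length(tgt))
      edges[[length(edges) + 1L]] <- cbind(k, tgt)
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(), ncol = 2)
  comp <- .components(length(su), em)
  sizes <- table(comp)
  fam <- rep(NA_character_, length(su))
  fam_comps <- as.integer(names(sizes)[sizes >= 2])
  starts <- vapply(fam_comps, function(cc)
    min(first_base[comp == cc]), 1)
  fam_comps <- fam_comps[order(starts)]
  for (k in seq_along(fam_comps))
    fam[comp == fam_comps[k]] <- sprintf("TF%02d", k)
  su$family_id <- fam
  list(boundaries = bounds, subunits = su)
}

# presence of each truth subunit in each species: the originating event
# (the one whose destination copy contains the subunit) must be older
# than the split
.species_presence <- function(subunits, pair_tab, splits) {
  if (!length(subunits) || !length(splits)) {
    return(data.frame(subunit_id = character(), species = character(),
                      present = logical()))
  }
  orig_age <- vapply(seq_along(subunits), function(k) {
    s <- BiocGenerics::start(subunits)[k]
    e <- BiocGenerics::end(subunits)[k]
    hit <- which(pair_tab$b_start <= s & pair_tab$b_end >= e)
    if (!length(hit)) Inf else min(pair_tab$age[hit])
  }, 1)
  out <- list()
  for (sp in names(splits)) {
    out[[sp]] <- data.frame(
      subunit_id = subunits$subunit_id,
      species = sp,
      present = orig_age > splits[[sp]])
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Emit a species genome from the simulation truth
#'
#' Returns the genome of a species that split from the simulated
#' lineage `split age` units ago: the ancestral state at the split
#' (only events older than the split are present) plus the species'
#' own post-split substitutions at the configured clock rate. The
#' presence table marks each truth subunit present iff its originating
#' event predates the split.
#'
#' @param sim Output of [simulateGenome()].
#' @param species A species label from the config's
#'   `species_split_ages`.
#' @return A list with `sequence` (a `DNAString`, chromosome
#'   `"<species>_chr"`), `chrom`, and `presence` (data frame
#'   `subunit_id`, `present`).
#' @export
emitSpeciesGenome <- function(sim, species) {
  truth <- sim$truth
  splits <- truth$config$species_split_ages
  if (!species %in% names(splits))
    stop("unknown species label: ", species,
         " (configured: ", paste(names(splits), collapse = ", "), ")")
  seqc <- truth$snapshots[[species]]
  set.seed(truth$config$seed + 7919L * match(species, names(splits)))
  rate <- truth$config$divergence_rate
  seqc <- .mutate(seqc, stats::rbinom(1, length(seqc),
                                      min(1, rate * splits[[species]])))
  pres <- truth$species_presence
  pres <- pres[pres$species == species, c("subunit_id", "present")]
  list(sequence = Biostrings::DNAString(paste(seqc, collapse = "")),
       chrom = paste0(species, "_chr"),
       presence = pres)
}

#' Emit human-versus-species alignment blocks
#'
#' The species genome equals the simulated reference minus the copies
#' inserted by events younger than the split; the collinear segments
#' between those insertions become alignment blocks (target
#' coordinates shifted by the cumulative length of skipped
#' insertions).
#'
#' @param sim Output of [simulateGenome()].
#' @param species Species label.
#' @return A data frame in [readAlignmentBlocks()] format (query =
#'   species contig, ref = simulated chromosome).
#' @export
emitSpeciesAlignment <- function(sim, species) {
  truth <- sim$truth
  splits <- truth$config$species_split_ages
  if (!species %in% names(splits))
    stop("unknown species label: ", species)
  split_age <- splits[[species]]
  L <- length(sim$sequence)
  ev <- truth$events
  young <- ev[ev$age <= split_age, , drop = FALSE]
  young <- young[order(young$b_start), , drop = FALSE]
  blocks <- list()
  cum <- 0L
  prev_end <- 0L
  add_block <- function(h_lo, h_hi, cum) {
    if (h_hi < h_lo) return(NULL)
    data.frame(query = paste0(species, "_chr"),
               query_start = h_lo - cum, query_end = h_hi - cum,
               ref = sim$chrom, ref_start = h_lo, ref_end = h_hi,
               strand = "+",
               identity = max(0, 1 - 2 * truth$config$divergence_rate *
                                split_age))
  }
  for (i in seq_len(nrow(young))) {
    blocks[[length(blocks) + 1L]] <-
      add_block(prev_end + 1L, young$b_start[i] - 1L, cum)
    cum <- cum + (young$b_end[i] - young$b_start[i] + 1L)
    prev_end <- young$b_end[i]
  }
  blocks[[length(blocks) + 1L]] <- add_block(prev_end + 1L, L, cum)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Emit clone haplotypes with planted indels
#'
#' Applies each clone specification to the reference: the clone is the
#' reference substring over its span with its indels applied (losses
#' delete reference sequence, gains insert novel random sequence). For
#' `nahr_alu_pair` indels the two breakpoints are validated to fall
#' inside planted repeats of the same label. Alongside the sequences,
#' per-clone alignment blocks are emitted the way an aligner would see
#' them: for homology-mediated (NAHR) losses the alignment gap is
#' placed at the left-most consistent position (the start of the left
#' repeat copy), so called breakpoints are ambiguous within the repeat
#' pair exactly as in real data.
#'
#' @param sim Output of [simulateGenome()].
#' @param clone_script Optional list of [cloneSpec()]s (default: the
#'   config's `clone_script`).
#' @return A list with `sequences` (named `DNAStringSet`), `blocks`
#'   (alignment-block data frame for all clones), and `truth` (data
#'   frame of planted indels with reference coordinates,
#'   breakpoint_mode and - for NAHR indels - the repeat pair span).
#' @export
emitClones <- function(sim, clone_script = NULL) {
  truth <- sim$truth
  if (is.null(clone_script)) clone_script <- truth$config$clone_script
  if (!length(clone_script))
    stop("clone_script is empty; nothing to emit")
  ref <- sim$sequence
  reps <- truth$repeats
  set.seed(truth$config$seed + 104729L)
  seqs <- list(); blocks <- list(); tr <- list()
  for (ci in seq_along(clone_script)) {
    cs <- clone_script[[ci]]
    cname <- sprintf("clone%02d", ci)
    if (cs$end > length(ref))
      stop("clone ", cname, " extends past the reference")
    indels <- cs$indels
    if (length(indels)) {
      pos <- vapply(indels, `[[`, 1, "position")
      indels <- indels[order(pos)]
    }
    # validate NAHR indels and note their repeat-pair span
    for (iv in indels) {
      if (iv$breakpoint_mode != "nahr_alu_pair") next
      if (iv$kind != "loss")
        stop("nahr_alu_pair mode requires a loss indel")
      lhit <- which(BiocGenerics::start(reps) <= iv$position &
                    BiocGenerics::end(reps) >= iv$position)
      rpos <- iv$position + iv$length
      rhit <- which(BiocGenerics::start(reps) <= rpos &
                    BiocGenerics::end(reps) >= rpos)
      ok <- length(lhit) && length(rhit) &&
        any(outer(reps$name[lhit], reps$name[rhit], "=="))
      if (!ok)
        stop("clone ", cname, ": nahr_alu_pair indel at ", iv$position,
             " does not span two same-label planted repeats")
    }
    # build clone sequence (apply right-to-left so coordinates hold)
    frag <- as.character(Biostrings::subseq(ref, cs$start, cs$end))
    fragc <- strsplit(frag, "")[[1]]
    if (length(indels)) {
      for (iv in rev(indels)) {
        p <- iv$position - cs$start + 1L
        if (iv$kind == "loss") {
          fragc <- fragc[-(p:(p + iv$length - 1L))]
        } else {
          ins <- sample(c("A", "C", "G", "T"), iv$length, replace = TRUE)
          fragc <- append(fragc, ins, after = p - 1L)
        }
      }
    }
    seqs[[cname]] <- paste(fragc, collapse = "")
    # alignment blocks: walk the indels along the reference
    ref_pos <- cs$start; clone_pos <- 1L
    for (iv in indels) {
      # aligned segment before the indel; for NAHR losses shift the
      # reported gap to the left-most consistent position
      gap_left <- iv$position - 1L
      if (iv$breakpoint_mode == "nahr_alu_pair") {
        lhit <- which(BiocGenerics::start(reps) <= iv$position &
                      BiocGenerics::end(reps) >= iv$position)
        gap_left <- BiocGenerics::start(reps)[lhit[1]] - 1L
      }
      seg_len <- gap_left - ref_pos + 1L
      blocks[[length(blocks) + 1L]] <- data.frame(
        query = cname, query_start = clone_pos,
        query_end = clone_pos + seg_len - 1L,
        ref = sim$chrom, ref_start = ref_pos, ref_end = gap_left,
        strand = "+", identity = 1)
      clone_pos <- clone_pos + seg_len
      if (iv$kind == "loss") {
        ref_pos <- gap_left + iv$length + 1L
      } else {
        ref_pos <- gap_left + 1L
        clone_pos <- clone_pos + iv$length
      }
      nahr_span <- NA_character_
      if (iv$breakpoint_mode == "nahr_alu_pair") {
        lhit <- which(BiocGenerics::start(reps) <= iv$position &
                      BiocGenerics::end(reps) >= iv$position)[1]
        rhit <- which(BiocGenerics::start(reps) <= iv$position + iv$length &
                      BiocGenerics::end(reps) >= iv$position + iv$length)[1]
        nahr_span <- sprintf("%d-%d", BiocGenerics::start(reps)[lhit],
                             BiocGenerics::end(reps)[rhit])
      }
      tr[[length(tr) + 1L]] <- data.frame(
        source_id = cname, position = iv$position, length_bp = iv$length,
        kind = iv$kind, breakpoint_mode = iv$breakpoint_mode,
        repeat_span = nahr_span)
    }
    blocks[[length(blocks) + 1L]] <- data.frame(
      query = cname, query_start = clone_pos,
      query_end = clone_pos + (cs$end - ref_pos),
      ref = sim$chrom, ref_start = ref_pos, ref_end = cs$end,
      strand = "+", identity = 1)
  }
  list(sequences = Biostrings::DNAStringSet(unlist(seqs)),
       blocks = do.call(rbind, c(blocks, make.row.names = FALSE)),
       truth = if (length(tr))
         do.call(rbind, c(tr, make.row.names = FALSE)) else
         data.frame())
}

#' Build a clone script with planted indels from the truth
#'
#' Convenience generator for validation runs: clones tile the
#' reference, and each receives indels larger than `minLen` with
#' either random breakpoints or NAHR-style breakpoints placed inside a
#' pair of same-label planted repeats.
#'
#' @param sim Output of [simulateGenome()].
#' @param n_clones Number of clones (default 4).
#' @param clone_length Clone span in bases (default 40000).
#' @param indels_per_clone Indels per clone (default 1).
#' @param nahr_fraction Fraction of indels given NAHR-style breakpoints
#'   (default 0.5; silently lowered when no same-label repeat pair fits
#'   in a clone).
#' @param minLen,maxLen Indel length bounds (default 250 and 6000).
#' @param gain_fraction Fraction of random-mode indels that are gains
#'   (default 0.4).
#' @param seed Integer seed.
#' @return A list of [cloneSpec()]s.
#' @export
makeCloneScript <- function(sim, n_clones = 4, clone_length = 40000,
                            indels_per_clone = 1, nahr_fraction = 0.5,
                            minLen = 250, maxLen = 6000,
                            gain_fraction = 0.4, seed = 1L) {
  set.seed(seed)
  L <- length(sim$sequence)
  reps <- sim$truth$repeats
  out <- list()
  for (ci in seq_len(n_clones)) {
    st <- sample.int(max(L - clone_length, 1L), 1L)
    en <- min(st + clone_length - 1L, L)
    indels <- list()
    for (k in seq_len(indels_per_clone)) {
      want_nahr <- stats::runif(1) < nahr_fraction
      made <- FALSE
      if (want_nahr) {
        inside <- which(BiocGenerics::start(reps) > st + 500 &
                        BiocGenerics::end(reps) < en - 500)
        if (length(inside) >= 2) {
          cand <- inside[order(BiocGenerics::start(reps)[inside])]
          labs <- reps$name[cand]
          for (i in seq_along(cand)) {
            js <- which(labs == labs[i] & seq_along(cand) > i)
            js <- js[BiocGenerics::start(reps)[cand[js]] -
                     BiocGenerics::end(reps)[cand[i]] > minLen]
            if (!length(js)) next
            j <- js[1]
            # align the two copies: delete from inside copy i to the
            # same offset inside copy j
            off <- sample.int(
              min(BiocGenerics::width(reps)[cand[i]],
                  BiocGenerics::width(reps)[cand[j]]) - 2L, 1L)
            p <- BiocGenerics::start(reps)[cand[i]] + off
            lenv <- BiocGenerics::start(reps)[cand[j]] + off - p
            if (lenv <= max(200, minLen) || p + lenv > en) next
            indels[[length(indels) + 1L]] <- list(
              position = as.integer(p), length = as.integer(lenv),
              kind = "loss", breakpoint_mode = "nahr_alu_pair")
            made <- TRUE
            break
          }
        }
      }
      if (!made) {
        lenv <- sample(seq(max(201, minLen), maxLen), 1L)
        kind <- if (stats::runif(1) < gain_fraction) "gain" else "loss"
        lo <- st + 1000L
        hi <- en - 1000L - (if (kind == "loss") lenv else 0L)
        if (hi <= lo) next
        p <- sample(lo:hi, 1L)
        indels[[length(indels) + 1L]] <- list(
          position = as.integer(p), length = as.integer(lenv),
          kind = kind, breakpoint_mode = "random")
      }
    }
    out[[length(out) + 1L]] <- cloneSpec(st, en, indels)
  }
  out
}
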