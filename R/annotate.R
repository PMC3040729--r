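# repeat superfamily used by the NAHR classifier
.superfamily <- function(label) {
  vapply(label, function(x) {
    if (is.na(x) || x %in% c("Na", ".", "")) return("Na")
    if (grepl("^Subunit", x)) return("Subunit")
    if (grepl("^Alu", x) || grepl("/Alu", x)) return("Alu")
    if (grepl("^L1", x)) return("L1")
    if (grepl("^\\(", x) || grepl("_rich$", x) || grepl("\\)n$", x))
      return("Simple")
    # everything else: named interspersed repeat (L2, LTR, MLT, MER...)
    sub("^([A-Za-z0-9]+).*$", "\\1", x)
  }, "", USE.NAMES = FALSE)
}

#' Annotate CNV breakpoints with flanking repeat features
#'
#' For every breakpoint, the reported feature is the repeat that
#' overlaps the breakpoint or lies within `W` bases of it; the nearest
#' wins, overlap beats proximity, remaining ties go to the leftmost
#' repeat. Breakpoints with no repeat within the window get `"Na"`.
#' Gains (insertion point) receive one feature; losses receive a
#' left and a right feature.
#'
#' @param cnvs Data frame from [callCNVs()] (columns `cnv_start`,
#'   `cnv_end`, `kind`).
#' @param repeats Repeat `GRanges` with `name` metadata.
#' @param W Window in bases (default 10).
#' @return `cnvs` with added columns `feature_left` and `feature_right`
#'   (`feature_right` is `NA` for gains).
#' @export
annotateFlankFeatures <- function(cnvs, repeats, W = 10) {
  feat_at <- function(pos) {
    if (!length(repeats)) return("Na")
    st <- BiocGenerics::start(repeats); en <- BiocGenerics::end(repeats)
    d <- ifelse(pos < st, st - pos, ifelse(pos > en, pos - en, 0L))
    ok <- which(d <= W)
    if (!length(ok)) return("Na")
    ok <- ok[order(d[ok], st[ok])]
    repeats$name[ok[1]]
  }
  cnvs$feature_left <- vapply(cnvs$cnv_start, feat_at, "")
  cnvs$feature_right <- ifelse(cnvs$kind == "loss",
                               vapply(cnvs$cnv_end, feat_at, ""),
                               NA_character_)
  cnvs
}

#' Micro-homology between two breakpoint flanks
#'
#' Position-wise identity of two equal-length sequences (the 10-mers
#' flanking the two breakpoints of a rearrangement). Micro-homology is
#' declared when identity strictly exceeds 0.8 (for 10-mers: at least
#' 9 of 10 positions).
#'
#' @param left,right Character strings or `DNAString`s of equal length.
#' @param threshold Strict lower bound on identity (default 0.8).
#' @return A list with `identity` (fraction of matching positions) and
#'   `is_homologous` (logical).
#' @export
microHomology <- function(left, right, threshold = 0.8) {
  l <- strsplit(as.character(left), "")[[1]]
  r <- strsplit(as.character(right), "")[[1]]
  if (length(l) != length(r))
    stop("flank sequences must have equal length")
  id <- mean(l == r)
  list(identity = id, is_homologous = id > threshold)
}

#' Classify a CNV's breakpoint pair for NAHR compatibility
#'
#' Uses the two breakpoint feature labels: `alu_alu` when both are Alu
#' subfamilies (any subfamily; Alu elements are homologous enough for
#' non-allelic crossover regardless of subfamily), `l1_l1` when both
#' are L1 elements, `subunit_pair` when both breakpoints fall in
#' paralogous duplication subunits, `cross_family` when both sides are
#' interspersed repeats of different superfamilies, otherwise `none`.
#' Simple/low-complexity repeats (e.g. `(TA)n`, `AT_rich`) are never
#' treated as homologous pairs.
#'
#' @param left,right Feature labels (vectorised).
#' @return Character vector of classes.
#' @export
classifyNAHR <- function(left, right) {
  sl <- .superfamily(left); sr <- .superfamily(right)
  mapply(function(a, b) {
    if (a == "Na" || b == "Na") return("none")
    if (a == "Alu" && b == "Alu") return("alu_alu")
    if (a == "L1" && b == "L1") return("l1_l1")
    if (a == "Subunit" && b == "Subunit") return("subunit_pair")
    if (a == "Simple" || b == "Simple") return("none")
    if (a != b) return("cross_family")
    "none"
  }, sl, sr, USE.NAMES = FALSE)
}

#' Scan sequence windows for a degenerate motif
#'
#' Counts occurrences of an IUPAC degenerate motif (default the
#' recombination hotspot 13-mer `CCNCCNTNNCCNC`) in each window,
#' on both strands by default, counting overlapping matches.
#'
#' @param windows A `DNAStringSet`, `DNAString`, or character vector of
#'   sequences.
#' @param motif IUPAC pattern (default `"CCNCCNTNNCCNC"`).
#' @param bothStrands Scan the reverse complement too (default TRUE).
#' @return Integer vector of per-window hit counts.
#' @export
scanMotif <- function(windows, motif = "CCNCCNTNNCCNC",
                      bothStrands = TRUE) {
  if (is.character(windows) || methods::is(windows, "DNAString"))
    windows <- Biostrings::DNAStringSet(windows)
  pat <- Biostrings::DNAString(motif)
  rcp <- Biostrings::reverseComplement(pat)
  vapply(seq_along(windows), function(i) {
    s <- windows[[i]]
    n <- length(Biostrings::matchPattern(pat, s, fixed = FALSE))
    if (bothStrands)
      n <- n + length(Biostrings::matchPattern(rcp, s, fixed = FALSE))
    as.integer(n)
  }, 1L)
}

#' Extract breakpoint flank sequences
#'
#' Returns the `2 * W`-base reference sequence centred on each
#' breakpoint (the `W` bases ending at the breakpoint plus the `W`
#' bases after it), for micro-homology and motif analysis.
#'
#' @param positions Integer vector of breakpoint positions (1-based).
#' @param sequence A `DNAString` (the reference chromosome).
#' @param W Half-window in bases (default 10).
#' @return A `DNAStringSet` with one entry per breakpoint; positions
#'   too close to the sequence ends are clipped.
#' @export
breakpointFlanks <- function(positions, sequence, W = 10) {
  n <- length(sequence)
  st <- pmax(positions - W + 1L, 1L)
  en <- pmin(positions + W, n)
  Biostrings::DNAStringSet(lapply(seq_along(positions), function(i)
    Biostrings::subseq(sequence, st[i], en[i])))
}
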