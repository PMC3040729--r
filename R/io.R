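#' Read pairwise segmental-duplication records
#'
#' Parses the genomicSuperDups-like tab format with columns
#' `chromA, startA, endA, chromB, startB, endB, strand, fracMatch`
#' (1-based inclusive coordinates; `strand` is `+` for same-orientation
#' pairs and `-` for inverted ones). Records are filtered the way a
#' segmental-duplication analysis defines its input: identity at least
#' `minIdentity`, duplicon length at least `minLength`, and both sides
#' inside `region` (pairs reaching outside the analysis region are
#' dropped, keeping the analysis strictly intra-region). Symmetric
#' duplicate rows (the same pair listed as A,B and B,A) are collapsed to
#' a single record.
#'
#' @param path Path to the TSV file (a header line is detected and
#'   skipped automatically).
#' @param region Optional `GRanges` of length 1; pairs with either side
#'   not fully inside it are dropped. Default `NULL` keeps everything.
#' @param minIdentity Minimum `fracMatch` to retain (default 0.9).
#' @param minLength Minimum duplicon length in bases (default 1000).
#' @param lengthRatio Allowed ratio of the two side lengths
#'   (default `c(0.95, 1.05)`); rows outside the band are dropped with a
#'   warning since no base-level alignment backs a strongly asymmetric
#'   pair.
#' @return An [SDPairSet-class].
#' @export
readSDPairs <- function(path, region = NULL, minIdentity = 0.9,
                        minLength = 1000, lengthRatio = c(0.95, 1.05)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    gr0 <- GenomicRanges::GRanges()
    return(SDPairSet(gr0, gr0, character(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (suppressWarnings(is.na(as.numeric(fields[[1]][2])))) {
    fields <- fields[-1]
    offset <- 1L
  } else offset <- 0L
  if (!length(fields)) {
    gr0 <- GenomicRanges::GRanges()
    return(SDPairSet(gr0, gr0, character(), numeric()))
  }
  bad <- which(vapply(fields, length, 1L) < 8L)
  if (length(bad))
    stop("malformed SD pair row (fewer than 8 fields) at line ",
         bad[1] + offset, " of ", path)
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, c(2, 3, 5, 6, 8), drop = FALSE], 2,
                                as.numeric))
  num <- matrix(num, ncol = 5)
  badn <- which(apply(is.na(num), 1, any))
  if (length(badn))
    stop("malformed SD pair row (non-numeric coordinate/identity) at line ",
         badn[1] + offset, " of ", path)
  startA <- num[, 1]; endA <- num[, 2]
  startB <- num[, 3]; endB <- num[, 4]
  frac <- num[, 5]
  rejected <- startA > endA | startB > endB
  if (any(rejected)) {
    warning(sum(rejected), " row(s) rejected: start > end (lines ",
            paste(which(rejected) + offset, collapse = ","), ")")
  }
  keep <- !rejected
  # collapse symmetric duplicates (A,B) / (B,A)
  key_fwd <- paste(m[, 1], startA, endA, m[, 4], startB, endB)
  key_rev <- paste(m[, 4], startB, endB, m[, 1], startA, endA)
  canon <- ifelse(key_fwd <= key_rev, key_fwd, key_rev)
  keep <- keep & !duplicated(canon)
  lenA <- endA - startA + 1
  lenB <- endB - startB + 1
  keep <- keep & frac >= minIdentity & lenA >= minLength & lenB >= minLength
  ratio <- lenA / lenB
  off_ratio <- keep & (ratio < lengthRatio[1] | ratio > lengthRatio[2])
  if (any(off_ratio)) {
    warning(sum(off_ratio), " pair(s) dropped: side-length ratio outside [",
            lengthRatio[1], ", ", lengthRatio[2], "]")
    keep <- keep & !off_ratio
  }
  grA <- GenomicRanges::GRanges(m[, 1],
                                IRanges::IRanges(startA, endA))[keep]
  grB <- GenomicRanges::GRanges(m[, 4],
                                IRanges::IRanges(startB, endB))[keep]
  orient <- ifelse(m[keep, 7] %in% c("-", "inverted"), "inverted", "same")
  frac <- frac[keep]
  if (!is.null(region)) {
    inA <- IRanges::overlapsAny(grA, region, type = "within")
    inB <- IRanges::overlapsAny(grB, region, type = "within")
    grA <- grA[inA & inB]; grB <- grB[inA & inB]
    orient <- orient[inA & inB]; frac <- frac[inA & inB]
  }
  SDPairSet(grA, grB, orient, frac)
}

#' Write pairwise SD records
#'
#' Inverse of [readSDPairs()]: emits the genomicSuperDups-like TSV
#' dialect with 1-based inclusive coordinates and a header line.
#'
#' @param pairs An [SDPairSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSDPairs <- function(pairs, path) {
  df <- data.frame(
    chromA = as.character(GenomicRanges::seqnames(pairs@first)),
    startA = BiocGenerics::start(pairs@first),
    endA = BiocGenerics::end(pairs@first),
    chromB = as.character(GenomicRanges::seqnames(pairs@second)),
    startB = BiocGenerics::start(pairs@second),
    endB = BiocGenerics::end(pairs@second),
    strand = ifelse(pairs@orientation == "inverted", "-", "+"),
    fracMatch = pairs@fracMatch
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read RepeatMasker annotation
#'
#' Parses the whitespace-separated RepeatMasker `.out` dialect (columns:
#' score, divergence, deletion, insertion, query, begin, end, left,
#' strand, repeat name, class/family). The up-to-three header lines of
#' real RepeatMasker output are skipped if present.
#'
#' @param path Path to the `.out` file.
#' @return A `GRanges` with metadata columns `name` (repeat subfamily,
#'   e.g. `AluY`) and `repClass` (e.g. `SINE/Alu`).
#' @export
readRepeatMasker <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_data <- grepl("^\\s*[0-9]", lines)
  lines <- lines[is_data]
  if (!length(lines))
    return(GenomicRanges::GRanges(name = character(),
                                  repClass = character()))
  fields <- strsplit(trimws(lines), "\\s+")
  short <- which(vapply(fields, length, 1L) < 11L)
  if (length(short))
    stop("malformed RepeatMasker row: ", lines[short[1]])
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  gr <- GenomicRanges::GRanges(
    m[, 5],
    IRanges::IRanges(as.integer(m[, 6]), as.integer(m[, 7])),
    strand = ifelse(m[, 9] == "C", "-", "+")
  )
  gr$name <- m[, 10]
  gr$repClass <- m[, 11]
  gr
}

#' Write RepeatMasker-style annotation
#'
#' @param repeats A `GRanges` with `name` and `repClass` metadata
#'   columns (as returned by [readRepeatMasker()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRepeatMasker <- function(repeats, path) {
  n <- length(repeats)
  df <- data.frame(
    score = rep(1000L, n), div = 0, del = 0, ins = 0,
    query = as.character(GenomicRanges::seqnames(repeats)),
    begin = BiocGenerics::start(repeats),
    end = BiocGenerics::end(repeats),
    left = "(0)",
    strand = ifelse(as.character(BiocGenerics::strand(repeats)) == "-",
                    "C", "+"),
    name = repeats$name,
    class = repeats$repClass
  )
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read pairwise alignment blocks
#'
#' Parses the tab dialect used for clone-versus-reference and
#' cross-species alignments: columns `query, query_start, query_end,
#' ref, ref_start, ref_end, strand[, identity]`, 1-based inclusive on
#' both sides. A header line is detected and skipped.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with those columns (identity `NA` when
#'   absent).
#' @export
readAlignmentBlocks <- function(path) {
  empty <- data.frame(query = character(), query_start = integer(),
                      query_end = integer(), ref = character(),
                      ref_start = integer(), ref_end = integer(),
                      strand = character(), identity = numeric())
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (suppressWarnings(is.na(as.numeric(fields[[1]][2]))))
    fields <- fields[-1]
  if (!length(fields)) return(empty)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 7L))
    stop("malformed alignment block row: ",
         paste(fields[[which(nf < 7L)[1]]], collapse = "\t"))
  m <- do.call(rbind, lapply(fields, function(f) c(f, NA)[1:8]))
  data.frame(
    query = m[, 1],
    query_start = as.integer(m[, 2]), query_end = as.integer(m[, 3]),
    ref = m[, 4],
    ref_start = as.integer(m[, 5]), ref_end = as.integer(m[, 6]),
    strand = m[, 7],
    identity = suppressWarnings(as.numeric(m[, 8]))
  )
}

#' Write alignment blocks
#' @param blocks A `data.frame` as returned by [readAlignmentBlocks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentBlocks <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] so every file
#' format the pipeline touches has a read/write pair in one place.
#'
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
readFastaFile <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#' @param seqs A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaFile <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write genomic ranges as BED
#'
#' Standard BED: 0-based half-open, columns chrom/start/end/name/score/
#' strand. Interval containers in this package are 1-based closed
#' `GRanges`; the conversion happens here and only here.
#'
#' @param gr A `GRanges`; if a metadata column `name` exists it becomes
#'   the BED name field.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedFile <- function(gr, path) {
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    rep(".", length(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = nm,
    score = 0L,
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "*", ".",
                    as.character(BiocGenerics::strand(gr)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into GRanges
#'
#' @param path BED path (at least 3 columns; name/score/strand used when
#'   present).
#' @return A `GRanges` (1-based closed) with a `name` metadata column.
#' @export
readBedFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(GenomicRanges::GRanges(name = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(fields, function(f) c(f, ".", "0", ".")[1:6]))
  gr <- GenomicRanges::GRanges(
    m[, 1],
    IRanges::IRanges(as.integer(m[, 2]) + 1L, as.integer(m[, 3])),
    strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*")
  )
  gr$name <- m[, 4]
  gr
}

#' Write a data frame as TSV
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsvFile <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [writeTsvFile()]
#' @param path Input path.
#' @return A data frame.
#' @export
readTsvFile <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
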