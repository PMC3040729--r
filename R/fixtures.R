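# Bundled worked-example fixtures: the two printed CNV catalogs of the
# 22q11.2 clone-mapping analysis and a seven-pair duplicon fixture
# reproducing the classic five-locus decomposition cartoon.

.fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "SDmosaic")
  if (!nzchar(p)) {
    # during development (package not installed)
    p <- file.path("inst", "extdata", name)
  }
  if (!file.exists(p)) stop("fixture not found: ", name)
  p
}

#' Copy the bundled fixture files to a directory
#'
#' Writes the three bundled fixtures - the catalog of 13 CNVs flanked
#' by paralogous subunits, the catalog of 28 clone-derived CNVs with
#' breakpoint features, and the seven-pair duplicon fixture - into
#' `outdir`.
#'
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
makeFixtures <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- c(table2 = "table2_cnvs.tsv", table3 = "table3_cnvs.tsv",
             fig1 = "fig1_sd_pairs.tsv")
  out <- vapply(files, function(f) {
    dest <- file.path(outdir, f)
    file.copy(.fixture_path(f), dest, overwrite = TRUE)
    dest
  }, "")
  out
}

#' Catalog of CNVs flanked by paralogous subunits
#'
#' The bundled 13-record catalog of previously reported CNVs whose two
#' breakpoints fall in subunits of the same paralogous family, with
#' the flanking subunit intervals and family ids.
#'
#' @return A list with `cnvs` (data frame: `cnv_start`, `cnv_end`,
#'   `length_bp`, `kind`, ...) and `subunits` (a `GRanges` with
#'   `subunit_id` and `family_id` built from the catalog's flanking
#'   subunit columns).
#' @export
paralogCnvFixture <- function() {
  df <- readTsvFile(.fixture_path("table2_cnvs.tsv"))
  su <- unique(rbind(
    data.frame(start = df$left_subunit_start, end = df$left_subunit_end,
               family_id = as.character(df$family_id)),
    data.frame(start = df$right_subunit_start,
               end = df$right_subunit_end,
               family_id = as.character(df$family_id))))
  su <- su[order(su$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(rep("chr22", nrow(su)),
                               IRanges::IRanges(su$start, su$end))
  gr$subunit_id <- sprintf("S%03d", seq_along(gr))
  gr$family_id <- su$family_id
  list(cnvs = df, subunits = gr)
}

#' Catalog of clone-derived CNVs with breakpoint features
#'
#' The bundled 28-record catalog of CNVs called from clone-versus-
#' reference alignment gaps (> 200 bp), with the printed breakpoint
#' feature labels (`feature_right` is `NA` for gains, which have a
#' single breakpoint).
#'
#' @return A data frame.
#' @export
cloneCnvFixture <- function() {
  df <- readTsvFile(.fixture_path("table3_cnvs.tsv"))
  df$feature_right[df$feature_right == "."] <- NA_character_
  df
}

#' Seven-pair duplicon fixture
#'
#' A synthetic SD-pair set whose topology reproduces the canonical
#' five-locus decomposition example: seven duplicon pairs over loci
#' a-e that decompose into fifteen subunits in six paralogous
#' families, with locus "a" the anchor of the single group.
#'
#' @return An [SDPairSet-class].
#' @export
fig1Fixture <- function() {
  readSDPairs(.fixture_path("fig1_sd_pairs.tsv"))
}
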