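#' Read a two-column chromosome-sizes file
#'
#' @param path Tab-separated file with chromosome name and length, no header.
#' @return A [genome_index()] tibble.
#' @export
read_genome_index <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  genome_index(x$chrom, x$length)
}

#' Read genomic intervals from BED or GFF3
#'
#' Uses rtracklayer's parsers and converts to the package's 0-based half-open
#' convention. For GFF3, only the feature intervals are kept.
#'
#' @param path A BED or GFF/GFF3 file (format guessed from the extension).
#' @param name Annotation set name (default: the file name).
#' @return An [annotation_set()] tibble.
#' @export
read_annotation <- function(path, name = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  format <- switch(ext,
    bed = "bed",
    gff = "gff3", gff3 = "gff3", gtf = "gtf",
    abort(sprintf("unsupported annotation format '.%s' (use BED or GFF3).", ext))
  )
  gr <- rtracklayer::import(path, format = format)
  annotation_set(
    tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr)
    ),
    name = name %||% basename(path)
  )
}

#' Read mapped-read start positions from BED
#'
#' Each BED record contributes one read at its (0-based) start position.
#'
#' @param path BED file of mapped reads.
#' @return Tibble of reads: `chrom`, `pos`.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1
  )
}

#' Read mapped-read start positions from BAM
#'
#' Takes the leftmost position of primary alignments (secondary and unmapped
#' records are skipped). Requires the Rsamtools package.
#'
#' @param path BAM file.
#' @return Tibble of reads: `chrom`, `pos`.
#' @export
read_reads_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading BAM requires the Rsamtools package.")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos"))
  )[[1]]
  keep <- !is.na(res$pos)
  tibble(chrom = as.character(res$rname)[keep], pos = res$pos[keep] - 1)
}

#' Write a track as bedGraph
#'
#' One line per bin: chrom, start, end, value. Values are written as-is (raw
#' integer counts or normalized reals).
#'
#' @param track A `binned_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  check_track(track)
  w <- attr(track, "bin_width")
  lens <- setNames(attr(track, "genome")$length, attr(track, "genome")$chrom)
  readr::write_tsv(
    tibble(
      chrom = track$chrom,
      start = track$bin_start,
      end = pmin(track$bin_start + w, lens[track$chrom]),
      value = track$count
    ),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Write a paired per-bin count matrix as TSV
#'
#' Columns: chromosome, bin_start, wt_count, trf4_count (plus a blacklisted
#' flag), one row per bin.
#'
#' @param wt,trf4 `binned_track`s on the same lattice.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(wt, trf4, path) {
  check_track(wt, "wt"); check_track(trf4, "trf4")
  if (!same_lattice(wt, trf4)) abort("tracks are on different genomes or bin lattices.")
  readr::write_tsv(
    tibble(
      chrom = wt$chrom, bin_start = wt$bin_start,
      wt_count = wt$count, trf4_count = trf4$count,
      blacklisted = wt$blacklisted | trf4$blacklisted
    ),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a paired per-bin count matrix written by [write_counts_tsv()]
#'
#' @param path TSV with columns chrom, bin_start, wt_count, trf4_count (and
#'   optionally blacklisted).
#' @param genome A [genome_index()] tibble.
#' @param bin_width Bin width the matrix was computed at.
#' @return Named list of two raw `binned_track`s, `wt` and `trf4`.
#' @export
read_counts_tsv <- function(path, genome, bin_width) {
  x <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  need <- c("chrom", "bin_start", "wt_count", "trf4_count")
  if (!all(need %in% names(x))) {
    abort(sprintf("count matrix must have columns: %s.", paste(need, collapse = ", ")))
  }
  if (!"blacklisted" %in% names(x)) x$blacklisted <- FALSE
  mk <- function(col, label) {
    binned_track(
      tibble(chrom = x$chrom, bin_start = x$bin_start, count = x[[col]],
             blacklisted = x$blacklisted),
      genome, bin_width, library = label
    )
  }
  list(wt = mk("wt_count", "wt"), trf4 = mk("trf4_count", "trf4"))
}

#' Write intervals as BED6
#'
#' @param x Intervals with `chrom`, `start`, `end` and optionally `name`;
#'   `score` supplies the BED score column (default 0).
#' @param path Output file.
#' @param score Numeric vector recycled to the number of rows.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path, score = 0) {
  x <- as_tibble(x)
  check_intervals(x, what = "x")
  readr::write_tsv(
    tibble(
      chrom = x$chrom,
      start = as.integer(x$start),
      end = as.integer(x$end),
      name = if ("name" %in% names(x)) x$name else sprintf("feature_%d", seq_len(nrow(x))),
      score = as.integer(round(rep_len(score, nrow(x)))),
      strand = "."
    ),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Write annotated CUT calls
#'
#' `write_calls_bed()` writes BED6 with the score column holding
#' `round(10 * region_log2_enrichment)`; `write_calls_tsv()` writes the
#' catalogue table (chromosome, start, end, length, bins, log2 enrichment,
#' max bin count).
#'
#' @param calls An annotated `cut_calls` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  score <- if ("region_log2_enrichment" %in% names(calls) && nrow(calls) > 0) {
    round(10 * calls$region_log2_enrichment)
  } else 0
  write_bed6(calls, path, score = score)
}

#' @rdname write_calls_bed
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- intersect(
    c("name", "chrom", "start", "end", "length", "n_bins",
      "region_log2_enrichment", "max_bin_count"),
    names(calls)
  )
  readr::write_tsv(as_tibble(calls)[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write planted truth as BED6
#'
#' The score column holds the planted fold, rounded.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  write_bed6(truth$cuts, path,
             score = if (nrow(truth$cuts) > 0) round(truth$cuts$fold) else 0)
}
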