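#' Fraction of a library's reads falling in an annotation
#'
#' Computes the within-library fraction of blacklist-filtered reads attributed
#' to an annotation set: the sum of counts in bins overlapping any annotated
#' interval divided by the effective library total. Bins partially overlapping
#' an interval are counted wholly inside (bin-resolution attribution). The
#' fraction is depth-invariant, so raw (unnormalized) counts are the intended
#' input; fractions over a partition of the genome sum to one exactly.
#'
#' @param track A blacklist-filtered raw `binned_track`.
#' @param annotation An annotation set (or any `chrom`/`start`/`end` tibble,
#'   or a `cut_calls` table).
#' @return One-row tibble: `library`, `reads_in_set`, `effective_total`,
#'   `fraction`.
#' @export
occupancy_fraction <- function(track, annotation) {
  check_track(track)
  if (attr(track, "normalized")) {
    warn("occupancy is defined on raw counts; this track is normalized (the fraction is depth-invariant, but totals will not be read counts).")
  }
  eff <- attr(track, "effective_total")
  if (eff <= 0) abort("empty library: effective total is zero.")
  ann <- as_annotation_set(annotation, "annotation")
  reads_in <- 0
  if (nrow(ann) > 0) {
    w <- attr(track, "bin_width")
    lens <- setNames(attr(track, "genome")$length, attr(track, "genome")$chrom)
    bins_gr <- GenomicRanges::GRanges(
      seqnames = track$chrom,
      ranges = IRanges::IRanges(
        start = track$bin_start + 1,
        width = pmin(w, lens[track$chrom] - track$bin_start)
      )
    )
    hit <- GenomicRanges::countOverlaps(bins_gr, intervals_to_granges(ann)) > 0
    reads_in <- sum(track$count[hit & !track$blacklisted])
  }
  tibble(
    library = attr(track, "library"),
    reads_in_set = reads_in,
    effective_total = eff,
    fraction = reads_in / eff
  )
}

#' Paired log-count scatter table
#'
#' Rebins two tracks to `region_width` (default 500 bp) and returns paired
#' log-transformed counts per region, the data behind a two-library
#' log-log scatter plot. The log base defaults to 10 with a pseudocount of 1;
#' both are recorded in the output's attributes.
#'
#' @param a,b `binned_track`s on the same lattice (typically normalized).
#' @param region_width Region width in bases; a multiple of the bin width.
#' @param pseudocount Reads added before the log (keeps zeros finite).
#' @param log_base Base of the log transform.
#' @return A `scatter_table` tibble: `chrom`, `region_start`, `count_a`,
#'   `count_b`, `log_a`, `log_b`.
#' @export
scatter_table <- function(a, b, region_width = 500, pseudocount = 1,
                          log_base = 10) {
  check_track(a, "a"); check_track(b, "b")
  if (!same_lattice(a, b)) abort("tracks are on different genomes or bin lattices.")
  ra <- rebin(a, region_width)
  rb <- rebin(b, region_width)
  out <- tibble(
    chrom = ra$chrom,
    region_start = ra$bin_start,
    count_a = ra$count,
    count_b = rb$count,
    log_a = log(ra$count + pseudocount, base = log_base),
    log_b = log(rb$count + pseudocount, base = log_base)
  )
  structure(
    out,
    class = c("scatter_table", class(out)),
    region_width = region_width,
    pseudocount = pseudocount,
    log_base = log_base,
    libraries = c(attr(a, "library"), attr(b, "library"))
  )
}

#' Per-bin series for one chromosome
#'
#' Extracts the ordered (bin start, untransformed count) series for a single
#' chromosome, suitable for plotting a raw read-count chromosome track. The
#' series length is `ceiling(chromosome length / bin_width)` and its sum is
#' the chromosome's contribution to the library total.
#'
#' @param track A `binned_track`.
#' @param chromosome Chromosome name.
#' @return Tibble: `bin_start`, `count`.
#' @export
chromosome_track_export <- function(track, chromosome) {
  check_track(track)
  if (!chromosome %in% attr(track, "genome")$chrom) {
    abort(sprintf("unknown chromosome '%s'.", chromosome))
  }
  track |>
    as_tibble() |>
    filter(.data$chrom == chromosome) |>
    select("bin_start", "count")
}
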