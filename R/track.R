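#' Binned coverage tracks
#'
#' A binned track is a tibble with one row per genomic bin (columns `chrom`,
#' `bin_start`, `count`, `blacklisted`) covering the whole genome lattice, plus
#' metadata attributes: the genome index, bin width, raw library total,
#' effective (post-blacklist) total, the normalization factor applied and a
#' library label. Raw tracks hold integer counts; normalized tracks hold
#' non-negative reals.
#'
#' @param bins Tibble with columns `chrom`, `bin_start`, `count` (and
#'   optionally `blacklisted`). Bins absent from `bins` are filled with zero,
#'   so a sparse count table is accepted.
#' @param genome A [genome_index()] tibble.
#' @param bin_width Bin width in bases.
#' @param library Library label (e.g. `"wt"`, `"trf4"`).
#' @return A `binned_track` tibble.
#' @examples
#' gen <- genome_index("chrI", 1000)
#' binned_track(tibble::tibble(chrom = "chrI", bin_start = 0, count = 5),
#'              gen, bin_width = 100)
#' @export
binned_track <- function(bins, genome, bin_width, library = NA_character_) {
  genome <- check_genome(genome)
  if (!is.data.frame(bins) || !all(c("chrom", "bin_start", "count") %in% names(bins))) {
    abort("`bins` must have columns chrom, bin_start, count.")
  }
  if (any(bins$count < 0)) abort("bin counts must be non-negative.")
  if (any(bins$bin_start %% bin_width != 0)) {
    abort("`bin_start` values must be multiples of `bin_width`.")
  }
  lattice <- bin_lattice(genome, bin_width)
  filled <- lattice |>
    left_join(
      bins |> select(any_of(c("chrom", "bin_start", "count", "blacklisted"))),
      by = c("chrom", "bin_start")
    )
  if (nrow(filled) != nrow(lattice)) {
    abort("duplicate bins in `bins` for the given lattice.")
  }
  filled$count <- ifelse(is.na(filled$count), 0, filled$count)
  if (!"blacklisted" %in% names(filled)) filled$blacklisted <- FALSE
  filled$blacklisted <- ifelse(is.na(filled$blacklisted), FALSE, filled$blacklisted)
  new_binned_track(filled, genome, bin_width,
                   library_total = sum(filled$count),
                   effective_total = sum(filled$count[!filled$blacklisted]),
                   library = library)
}

new_binned_track <- function(bins, genome, bin_width, library_total,
                             effective_total = library_total,
                             norm_factor = 1, normalized = FALSE,
                             library = NA_character_) {
  out <- as_tibble(bins[, c("chrom", "bin_start", "count", "blacklisted")])
  structure(
    out,
    class = c("binned_track", class(out)),
    genome = genome,
    bin_width = bin_width,
    library_total = library_total,
    effective_total = effective_total,
    norm_factor = norm_factor,
    normalized = normalized,
    library = library
  )
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf(
    "<binned_track> library=%s bin_width=%d bins=%d total=%.6g effective=%.6g factor=%.6g %s\n",
    attr(x, "library"), as.integer(attr(x, "bin_width")), nrow(x),
    attr(x, "library_total"), attr(x, "effective_total"),
    attr(x, "norm_factor"), if (attr(x, "normalized")) "(normalized)" else "(raw)"
  ))
  NextMethod()
}

check_track <- function(x, what = "track") {
  if (!inherits(x, "binned_track")) {
    abort(sprintf("`%s` must be a binned_track (see binned_track(), bin_reads()).", what))
  }
  invisible(x)
}

same_lattice <- function(a, b) {
  identical(attr(a, "bin_width"), attr(b, "bin_width")) &&
    isTRUE(all.equal(attr(a, "genome"), attr(b, "genome"))) &&
    nrow(a) == nrow(b) &&
    all(a$chrom == b$chrom) && all(a$bin_start == b$bin_start)
}

#' Track metadata accessors
#'
#' @param track A `binned_track`.
#' @return `track_bin_width()` the bin width; `track_totals()` a one-row tibble
#'   of library metadata.
#' @export
track_bin_width <- function(track) {
  check_track(track)
  attr(track, "bin_width")
}

#' @rdname track_bin_width
#' @export
track_totals <- function(track) {
  check_track(track)
  tibble(
    library = attr(track, "library"),
    library_total = attr(track, "library_total"),
    effective_total = attr(track, "effective_total"),
    norm_factor = attr(track, "norm_factor"),
    normalized = attr(track, "normalized")
  )
}

#' Sum mapped reads into fixed-width genomic bins
#'
#' Each read is assigned to exactly one bin by its mapped start position; bin
#' `i` covers `[i*w, (i+1)*w)` in 0-based half-open coordinates, and the final
#' bin of a chromosome may be partial. The read count is conserved exactly:
#' the track's bins sum to the number of input reads.
#'
#' @param reads Tibble of mapped read start positions, columns `chrom` and
#'   `pos` (0-based).
#' @param genome A [genome_index()] tibble.
#' @param bin_width Bin width in bases (default 100, the resolution at which
#'   the CUT annotation was defined).
#' @param library Library label stored in the track metadata.
#' @return A raw `binned_track`.
#' @examples
#' gen <- genome_index("chrI", 300)
#' reads <- tibble::tibble(chrom = "chrI", pos = c(0, 99, 100))
#' bin_reads(reads, gen, bin_width = 100)$count  # 2, 1, 0
#' @export
bin_reads <- function(reads, genome, bin_width = 100, library = NA_character_) {
  genome <- check_genome(genome)
  if (!is.data.frame(reads) || !all(c("chrom", "pos") %in% names(reads))) {
    abort("`reads` must be a data frame with columns chrom, pos.")
  }
  lens <- setNames(genome$length, genome$chrom)
  if (nrow(reads) > 0) {
    unknown <- setdiff(unique(reads$chrom), genome$chrom)
    if (length(unknown) > 0) {
      abort(sprintf("reads on chromosomes absent from the genome: %s",
                    paste(unknown, collapse = ", ")))
    }
    bad <- which(reads$pos < 0 | reads$pos >= lens[reads$chrom])
    if (length(bad) > 0) {
      abort(sprintf(
        "read %d (%s:%d) lies outside its chromosome (length %d).",
        bad[1], reads$chrom[bad[1]], reads$pos[bad[1]], lens[reads$chrom[bad[1]]]
      ))
    }
  }
  counts <- pmap(genome, function(chrom, length) {
    nb <- n_bins(length, bin_width)
    pos <- reads$pos[reads$chrom == chrom]
    tibble(
      chrom = chrom,
      bin_start = seq(0, length - 1, by = bin_width),
      count = as.numeric(tabulate(floor(pos / bin_width) + 1, nbins = nb))
    )
  }) |>
    list_rbind()
  counts$blacklisted <- FALSE
  new_binned_track(counts, genome, bin_width,
                   library_total = nrow(reads), library = library)
}

#' Zero out blacklisted bins
#'
#' Bins overlapping any blacklist interval (by >= 1 bp) are set to zero,
#' flagged, and excluded from the effective library total used for
#' normalization and occupancy. The raw library total is retained. The
#' motivating use is removal of an abundant contaminant such as the 37S
#' pre-rRNA locus.
#'
#' @param track A `binned_track`.
#' @param blacklist Tibble of intervals (`chrom`, `start`, `end`), 0-based
#'   half-open. Empty blacklist leaves the track unchanged.
#' @return The filtered `binned_track` with updated effective total.
#' @export
apply_blacklist <- function(track, blacklist) {
  check_track(track)
  genome <- attr(track, "genome")
  w <- attr(track, "bin_width")
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    return(track)
  }
  check_intervals(blacklist, genome, "blacklist")
  bins_gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$bin_start + 1,
                              width = pmin(w, setNames(genome$length, genome$chrom)[track$chrom] - track$bin_start))
  )
  hit <- GenomicRanges::countOverlaps(bins_gr, intervals_to_granges(blacklist)) > 0
  out <- track
  out$count[hit] <- 0
  out$blacklisted <- out$blacklisted | hit
  attr(out, "effective_total") <- sum(out$count[!out$blacklisted])
  out
}

#' Total read-count normalization of a track pair
#'
#' Scales each track by `reference_total / own_effective_total`, where the
#' reference is the larger of the two effective (post-blacklist) totals, so the
#' shallower library is scaled up to the deeper one. Any common-total scheme is
#' equivalent for ratio-based calling; scaling up keeps the deeper library's
#' counts on the raw scale, which makes the noise cut-off interpretable as a
#' read count.
#'
#' @param a,b Raw `binned_track`s on the same lattice, blacklist already
#'   applied.
#' @return A list of the two normalized tracks, in input order.
#' @examples
#' gen <- genome_index("chrI", 200)
#' t1 <- binned_track(tibble::tibble(chrom = "chrI", bin_start = c(0, 100),
#'                                   count = c(10, 6)), gen, 100)
#' t2 <- binned_track(tibble::tibble(chrom = "chrI", bin_start = c(0, 100),
#'                                   count = c(20, 1)), gen, 100)
#' lapply(normalize_pair(t1, t2), track_totals)
#' @export
normalize_pair <- function(a, b) {
  check_track(a, "a"); check_track(b, "b")
  if (attr(a, "normalized") || attr(b, "normalized")) {
    abort("both tracks must be raw (not already normalized).")
  }
  if (!same_lattice(a, b)) abort("tracks are on different genomes or bin lattices.")
  ea <- attr(a, "effective_total")
  eb <- attr(b, "effective_total")
  if (ea <= 0 || eb <= 0) abort("empty library: effective total is zero.")
  ref <- max(ea, eb)
  scale1 <- function(tr, f) {
    out <- tr
    out$count <- out$count * f
    attr(out, "norm_factor") <- f
    attr(out, "normalized") <- TRUE
    out
  }
  list(scale1(a, ref / ea), scale1(b, ref / eb))
}

#' Rebin a track to a coarser resolution
#'
#' Sums counts over consecutive groups of `new_width / bin_width` bins; the
#' last group on each chromosome may be partial. Counts are conserved exactly.
#'
#' @param track A `binned_track`.
#' @param new_width New bin width; must be a positive multiple of the current
#'   bin width.
#' @return A `binned_track` at the new resolution.
#' @export
rebin <- function(track, new_width) {
  check_track(track)
  w <- attr(track, "bin_width")
  if (new_width <= 0 || new_width %% w != 0) {
    abort(sprintf("`new_width` must be a positive multiple of the bin width (%d).", w))
  }
  if (new_width == w) return(track)
  regrouped <- track |>
    mutate(bin_start = (.data$bin_start %/% new_width) * new_width) |>
    group_by(.data$chrom, .data$bin_start) |>
    summarise(count = sum(.data$count), blacklisted = any(.data$blacklisted),
              .groups = "drop")
  lattice <- bin_lattice(attr(track, "genome"), new_width)
  regrouped <- lattice |>
    left_join(regrouped, by = c("chrom", "bin_start"))
  new_binned_track(regrouped, attr(track, "genome"), new_width,
                   library_total = attr(track, "library_total"),
                   effective_total = attr(track, "effective_total"),
                   norm_factor = attr(track, "norm_factor"),
                   normalized = attr(track, "normalized"),
                   library = attr(track, "library"))
}

#' Uniformly rescale a track's raw counts
#'
#' Multiplies every bin count and the library totals by a constant. Mainly
#' useful for depth-invariance checks: calling is unchanged when either raw
#' library is rescaled, because normalization divides the factor back out.
#'
#' @param track A raw `binned_track`.
#' @param factor Positive multiplier.
#' @return The rescaled `binned_track`.
#' @export
scale_track <- function(track, factor) {
  check_track(track)
  if (factor <= 0) abort("`factor` must be positive.")
  out <- track
  out$count <- out$count * factor
  attr(out, "library_total") <- attr(out, "library_total") * factor
  attr(out, "effective_total") <- attr(out, "effective_total") * factor
  out
}
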