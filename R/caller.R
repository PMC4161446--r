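#' Parameters for CUT calling
#'
#' Defaults implement the published rule: regions of three or more consecutive
#' 100 bp bins over-represented by at least 4-fold in the degradation mutant,
#' longer than 200 nt, with a noise cut-off removing calls from bins with very
#' low read counts.
#'
#' @param fold_threshold Minimum per-bin enrichment of mutant over wild-type,
#'   computed on pseudocounted normalized counts (default 4).
#' @param min_consecutive_bins Minimum run length in bins (default 3).
#' @param noise_min_count Noise cut-off: minimum normalized mutant count per
#'   bin (default 10 reads).
#' @param pseudocount Reads added to both conditions before the ratio
#'   (default 1); keeps ratios finite over zero wild-type bins.
#' @param min_length Minimum genomic span of a call in bases, strict
#'   inequality (default 200).
#' @return A `caller_params` list.
#' @export
caller_params <- function(fold_threshold = 4, min_consecutive_bins = 3,
                          noise_min_count = 10, pseudocount = 1,
                          min_length = 200) {
  if (fold_threshold <= 1) abort("`fold_threshold` must be > 1.")
  if (min_consecutive_bins < 1) abort("`min_consecutive_bins` must be >= 1.")
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  if (noise_min_count < 0) abort("`noise_min_count` must be >= 0.")
  structure(
    list(
      fold_threshold = fold_threshold,
      min_consecutive_bins = min_consecutive_bins,
      noise_min_count = noise_min_count,
      pseudocount = pseudocount,
      min_length = min_length
    ),
    class = "caller_params"
  )
}

check_params <- function(params) {
  if (!inherits(params, "caller_params")) {
    abort("`params` must come from caller_params().")
  }
  invisible(params)
}

#' Per-bin enrichment of mutant over wild-type
#'
#' Computes, for every bin, `log2((trf4 + p) / (wt + p))` on normalized counts
#' with pseudocount `p`, plus pass/fail flags for the fold criterion (ratio,
#' without log, at least `fold_threshold`) and the noise criterion (normalized
#' mutant count at least `noise_min_count`). Blacklisted bins always fail both
#' flags, so no call can be emitted inside a filtered region.
#'
#' @param trf4,wt Normalized `binned_track`s on the same lattice (mutant and
#'   wild-type respectively).
#' @param params A [caller_params()] object.
#' @return An `enrichment_track` tibble: `chrom`, `bin_start`, `wt`, `trf4`,
#'   `log2_ratio`, `fold_pass`, `noise_pass`, `blacklisted`.
#' @export
compute_enrichment <- function(trf4, wt, params = caller_params()) {
  check_track(trf4, "trf4"); check_track(wt, "wt")
  check_params(params)
  if (!same_lattice(trf4, wt)) abort("tracks are on different genomes or bin lattices.")
  p <- params$pseudocount
  black <- trf4$blacklisted | wt$blacklisted
  t_count <- trf4$count
  w_count <- wt$count
  out <- tibble(
    chrom = trf4$chrom,
    bin_start = trf4$bin_start,
    wt = w_count,
    trf4 = t_count,
    log2_ratio = log2((t_count + p) / (w_count + p)),
    fold_pass = (t_count + p) >= params$fold_threshold * (w_count + p) & !black,
    noise_pass = t_count >= params$noise_min_count & !black,
    blacklisted = black
  )
  structure(
    out,
    class = c("enrichment_track", class(out)),
    genome = attr(trf4, "genome"),
    bin_width = attr(trf4, "bin_width"),
    params = params
  )
}

# maximal runs of TRUE of length >= min_len in a logical vector; returns
# tibble(first, n) of 1-based run starts and lengths
pass_runs <- function(pass, min_len) {
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_len
  tibble(first = (ends - r$lengths + 1)[keep], n = r$lengths[keep])
}

#' Call CUTs as maximal runs of enriched bins
#'
#' A CUT call is a maximal run of consecutive bins on one chromosome in which
#' every bin passes both the fold and the noise criterion, of at least
#' `min_consecutive_bins` bins and spanning more than `min_length` bases.
#' Adjacent runs separated by a failing bin are not merged. Calls are reported
#' on the bin lattice, sorted by genome order, and are pairwise disjoint.
#'
#' @param enrichment An `enrichment_track` from [compute_enrichment()].
#' @param params A [caller_params()] object; defaults to the parameters the
#'   enrichment track was computed with.
#' @return A `cut_calls` tibble: `name`, `chrom`, `start`, `end`, `length`,
#'   `n_bins`.
#' @export
call_cuts <- function(enrichment, params = attr(enrichment, "params")) {
  if (!inherits(enrichment, "enrichment_track")) {
    abort("`enrichment` must come from compute_enrichment().")
  }
  check_params(params)
  genome <- attr(enrichment, "genome")
  w <- attr(enrichment, "bin_width")
  lens <- setNames(genome$length, genome$chrom)
  pass <- enrichment$fold_pass & enrichment$noise_pass
  calls <- enrichment |>
    mutate(.pass = pass) |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      runs <- pass_runs(df$.pass, params$min_consecutive_bins)
      if (nrow(runs) == 0) {
        return(tibble(start = numeric(), end = numeric(), n_bins = integer()))
      }
      tibble(
        start = df$bin_start[runs$first],
        end = pmin(df$bin_start[runs$first] + runs$n * w, lens[key$chrom[1]]),
        n_bins = as.integer(runs$n)
      )
    }) |>
    ungroup() |>
    filter(.data$end - .data$start > params$min_length) |>
    mutate(chrom = as.character(.data$chrom), length = .data$end - .data$start) |>
    arrange(match(.data$chrom, genome$chrom), .data$start) |>
    select("chrom", "start", "end", "length", "n_bins")
  calls <- calls |>
    mutate(name = sprintf("CUT_%04d", seq_len(nrow(calls))), .before = 1)
  structure(
    calls,
    class = c("cut_calls", class(calls)),
    genome = genome,
    bin_width = w,
    params = params
  )
}

#' Annotate calls with region-level enrichment
#'
#' Fills, for each call, the log2 ratio of summed normalized counts over the
#' call's bins (with `pseudocount * n_bins` added to each side, so the region
#' statistic matches the per-bin statistic under a flat signal) and the
#' maximum normalized mutant bin count.
#'
#' @param calls A `cut_calls` tibble from [call_cuts()].
#' @param trf4,wt The normalized tracks the calls were made from.
#' @param params A [caller_params()] object (for the pseudocount).
#' @return The `cut_calls` tibble with `region_log2_enrichment` and
#'   `max_bin_count` columns added.
#' @export
annotate_calls <- function(calls, trf4, wt, params = attr(calls, "params")) {
  if (!inherits(calls, "cut_calls")) abort("`calls` must come from call_cuts().")
  check_track(trf4, "trf4"); check_track(wt, "wt")
  check_params(params)
  if (!same_lattice(trf4, wt)) abort("tracks are on different genomes or bin lattices.")
  p <- params$pseudocount
  w <- attr(trf4, "bin_width")
  if (nrow(calls) == 0) {
    out <- calls |>
      mutate(region_log2_enrichment = numeric(0), max_bin_count = numeric(0))
    return(restore_calls(out, calls))
  }
  bins_gr <- GenomicRanges::GRanges(
    seqnames = trf4$chrom,
    ranges = IRanges::IRanges(start = trf4$bin_start + 1, width = 1)
  )
  hits <- GenomicRanges::findOverlaps(bins_gr, intervals_to_granges(calls))
  sums <- tibble(
    call = S4Vectors::subjectHits(hits),
    trf4 = trf4$count[S4Vectors::queryHits(hits)],
    wt = wt$count[S4Vectors::queryHits(hits)]
  ) |>
    group_by(.data$call) |>
    summarise(sum_trf4 = sum(.data$trf4), sum_wt = sum(.data$wt),
              max_bin_count = max(.data$trf4), .groups = "drop")
  out <- calls |>
    mutate(.call = seq_len(nrow(calls))) |>
    left_join(sums, by = c(".call" = "call")) |>
    mutate(
      region_log2_enrichment = log2((.data$sum_trf4 + p * .data$n_bins) /
                                      (.data$sum_wt + p * .data$n_bins))
    ) |>
    select(-".call", -"sum_trf4", -"sum_wt")
  restore_calls(out, calls)
}

restore_calls <- function(out, template) {
  structure(
    out,
    class = unique(c("cut_calls", class(out))),
    genome = attr(template, "genome"),
    bin_width = attr(template, "bin_width"),
    params = attr(template, "params")
  )
}

#' One-step CUT annotation from a normalized track pair
#'
#' Convenience wrapper running [compute_enrichment()], [call_cuts()] and
#' [annotate_calls()].
#'
#' @inheritParams compute_enrichment
#' @return An annotated `cut_calls` tibble.
#' @export
annotate_cuts <- function(trf4, wt, params = caller_params()) {
  enr <- compute_enrichment(trf4, wt, params)
  calls <- call_cuts(enr, params)
  annotate_calls(calls, trf4, wt, params)
}
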