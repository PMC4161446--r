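#' Annotation sets
#'
#' An annotation set is a named collection of genomic intervals (a CUT
#' catalogue) in 0-based half-open coordinates: a tibble with columns `chrom`,
#' `start`, `end` and a `set` name. Overlapping intervals within one set are
#' legitimate.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`.
#' @param name Set name used in overlap reports.
#' @return An `annotation_set` tibble.
#' @export
annotation_set <- function(intervals, name = "set") {
  check_intervals(intervals, what = "intervals")
  out <- as_tibble(intervals[, c("chrom", "start", "end")])
  out$set <- name
  class(out) <- unique(c("annotation_set", class(out)))
  out
}

as_annotation_set <- function(x, name) {
  if (inherits(x, "annotation_set")) return(x)
  if (inherits(x, "cut_calls")) {
    return(annotation_set(as_tibble(x)[, c("chrom", "start", "end")], name))
  }
  annotation_set(x, name)
}

warn_unmatched_chroms <- function(a, b, name_a, name_b) {
  only_a <- setdiff(unique(a$chrom), unique(b$chrom))
  only_b <- setdiff(unique(b$chrom), unique(a$chrom))
  if (length(only_a) > 0 || length(only_b) > 0) {
    warn(sprintf(
      "chromosome names do not all match between %s and %s (only in %s: %s; only in %s: %s); unmatched chromosomes contribute zero overlaps.",
      name_a, name_b,
      name_a, paste(only_a, collapse = ", ") %|e|% "none",
      name_b, paste(only_b, collapse = ", ") %|e|% "none"
    ))
  }
}

`%|e|%` <- function(x, alt) if (nzchar(x)) x else alt

#' Directional interval overlap count
#'
#' Counts the features of `a` that overlap at least one feature of `b` by at
#' least one base; each feature of `a` is counted at most once. The count is
#' asymmetric: several features in one set can map to a single locus in the
#' other, so `directional_overlap(a, b)` generally differs from
#' `directional_overlap(b, a)`.
#'
#' @param a,b Annotation sets (any tibble with `chrom`/`start`/`end`, an
#'   [annotation_set()], or a `cut_calls` table).
#' @return Integer: features of `a` hitting `b`.
#' @export
directional_overlap <- function(a, b) {
  a <- as_annotation_set(a, "a"); b <- as_annotation_set(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  warn_unmatched_chroms(a, b, a$set[1], b$set[1])
  # suppress GenomicRanges' own seqlevel chatter; the mismatch warning above
  # already covers it
  suppressWarnings(sum(GenomicRanges::countOverlaps(
    intervals_to_granges(a), intervals_to_granges(b)
  ) > 0))
}

#' Direction-averaged overlap summary
#'
#' Computes both directional overlap counts and their arithmetic mean — the
#' direction-averaged count used when a single number per set pair is needed
#' (e.g. for Venn diagrams) — plus the percentage of each set overlapped by
#' the other. Symmetric in `(a, b)` up to field relabeling.
#'
#' @inheritParams directional_overlap
#' @param name_a,name_b Labels for the report (default: the sets' own names).
#' @return One-row tibble: `set_a`, `set_b`, `n_a`, `n_b`, `a_hitting_b`,
#'   `b_hitting_a`, `averaged`, `percent_of_a`, `percent_of_b`.
#' @export
averaged_overlap <- function(a, b, name_a = NULL, name_b = NULL) {
  a <- as_annotation_set(a, name_a %||% "a")
  b <- as_annotation_set(b, name_b %||% "b")
  name_a <- name_a %||% a$set[1]
  name_b <- name_b %||% b$set[1]
  ab <- suppressWarnings(directional_overlap(a, b))
  ba <- suppressWarnings(directional_overlap(b, a))
  if (nrow(a) > 0 && nrow(b) > 0) warn_unmatched_chroms(a, b, name_a, name_b)
  tibble(
    set_a = name_a, set_b = name_b,
    n_a = nrow(a), n_b = nrow(b),
    a_hitting_b = ab, b_hitting_a = ba,
    averaged = (ab + ba) / 2,
    percent_of_a = if (nrow(a) > 0) 100 * ab / nrow(a) else NA_real_,
    percent_of_b = if (nrow(b) > 0) 100 * ba / nrow(b) else NA_real_
  )
}

# features of `a` overlapping >= 1 feature of each of b and c
directional_triple <- function(a, b, c) {
  if (nrow(a) == 0 || nrow(b) == 0 || nrow(c) == 0) return(0L)
  ga <- intervals_to_granges(a)
  suppressWarnings(
    sum(GenomicRanges::countOverlaps(ga, intervals_to_granges(b)) > 0 &
          GenomicRanges::countOverlaps(ga, intervals_to_granges(c)) > 0)
  )
}

#' Three-set Venn region counts from direction-averaged overlaps
#'
#' Builds the region sizes of a three-set Venn diagram from the
#' direction-averaged pairwise overlap counts, with the triple overlap taken
#' as the mean of the three directional triple counts, and the exclusive
#' regions derived by inclusion-exclusion. Because the averaged counts come
#' from asymmetric feature-level overlaps, three-way consistency is
#' approximate by construction: any derived region that comes out negative is
#' clamped to zero and flagged.
#'
#' @param a,b,c Annotation sets.
#' @param names Character vector of three set labels.
#' @return Tibble: `region`, `count`, `clamped`, plus the pairwise summary in
#'   attribute `"pairwise"`.
#' @export
venn_counts <- function(a, b, c, names = c("A", "B", "C")) {
  a <- as_annotation_set(a, names[1])
  b <- as_annotation_set(b, names[2])
  c <- as_annotation_set(c, names[3])
  pair <- bind_rows(
    averaged_overlap(a, b, names[1], names[2]),
    averaged_overlap(a, c, names[1], names[3]),
    averaged_overlap(b, c, names[2], names[3])
  )
  ab <- pair$averaged[1]; ac <- pair$averaged[2]; bc <- pair$averaged[3]
  triple <- mean(c(
    directional_triple(a, b, c),
    directional_triple(b, a, c),
    directional_triple(c, a, b)
  ))
  raw <- c(
    setNames(nrow(a) - ab - ac + triple, sprintf("%s only", names[1])),
    setNames(nrow(b) - ab - bc + triple, sprintf("%s only", names[2])),
    setNames(nrow(c) - ac - bc + triple, sprintf("%s only", names[3])),
    setNames(ab - triple, sprintf("%s & %s", names[1], names[2])),
    setNames(ac - triple, sprintf("%s & %s", names[1], names[3])),
    setNames(bc - triple, sprintf("%s & %s", names[2], names[3])),
    setNames(triple, sprintf("%s & %s & %s", names[1], names[2], names[3]))
  )
  clamped <- raw < 0
  if (any(clamped)) {
    warn(sprintf(
      "negative derived Venn region(s) clamped to zero: %s (asymmetric overlap counts make three-way consistency approximate).",
      paste(names(raw)[clamped], collapse = "; ")
    ))
  }
  out <- tibble(
    region = names(raw),
    count = unname(pmax(raw, 0)),
    clamped = unname(clamped)
  )
  attr(out, "pairwise") <- pair
  attr(out, "triple_averaged") <- triple
  out
}

#' Match calls against planted truth and score recovery
#'
#' A planted CUT counts as recovered when a call overlaps it by at least
#' `min_overlap` of the planted length (and, when `reciprocal = TRUE`, the
#' overlap also covers at least that fraction of the call). Each call/CUT is
#' matched at most once (best overlap wins). When the calls carry
#' `region_log2_enrichment`, the matched pairs' deviation from the planted
#' `log2(fold)` is summarized.
#'
#' @param calls A `cut_calls` tibble (annotated or not).
#' @param truth A `synthetic_truth` or a tibble of planted CUTs with columns
#'   `chrom`, `start`, `end` and optionally `fold`.
#' @param min_overlap Required overlap fraction (default 0.5).
#' @param reciprocal Require the fraction in both directions (default TRUE).
#' @return One-row tibble: `n_calls`, `n_true`, `n_matched`, `recall`,
#'   `precision`, `frac_enrichment_within_1` (NA when enrichment or folds are
#'   absent); matched pairs in attribute `"matches"`.
#' @export
benchmark_calls <- function(calls, truth, min_overlap = 0.5, reciprocal = TRUE) {
  cuts <- if (inherits(truth, "synthetic_truth")) truth$cuts else as_tibble(truth)
  check_intervals(cuts, what = "truth")
  calls_tbl <- as_tibble(calls)
  n_calls <- nrow(calls_tbl); n_true <- nrow(cuts)
  empty_summary <- function(n_matched, frac1) {
    tibble(
      n_calls = n_calls, n_true = n_true, n_matched = n_matched,
      recall = if (n_true > 0) n_matched / n_true else NA_real_,
      precision = if (n_calls > 0) n_matched / n_calls else NA_real_,
      frac_enrichment_within_1 = frac1
    )
  }
  if (n_calls == 0 || n_true == 0) {
    out <- empty_summary(0L, NA_real_)
    attr(out, "matches") <- tibble()
    return(out)
  }
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(calls_tbl), intervals_to_granges(cuts)
  )
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(calls_tbl$end[qh], cuts$end[sh]) - pmax(calls_tbl$start[qh], cuts$start[sh])
  keep <- ov >= min_overlap * (cuts$end[sh] - cuts$start[sh])
  if (reciprocal) {
    keep <- keep & ov >= min_overlap * (calls_tbl$end[qh] - calls_tbl$start[qh])
  }
  pairs <- tibble(call = qh, true = sh, overlap = ov)[keep, ] |>
    arrange(desc(.data$overlap))
  pairs <- pairs[!duplicated(pairs$call) & !duplicated(pairs$true), ]
  frac1 <- NA_real_
  if (nrow(pairs) > 0 &&
      "region_log2_enrichment" %in% names(calls_tbl) &&
      "fold" %in% names(cuts)) {
    err <- calls_tbl$region_log2_enrichment[pairs$call] - log2(cuts$fold[pairs$true])
    pairs$log2_error <- err
    frac1 <- mean(abs(err) <= 1)
  }
  out <- empty_summary(nrow(pairs), frac1)
  attr(out, "matches") <- pairs
  out
}
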