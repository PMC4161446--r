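#' Tidy and summarize CUT call tables
#'
#' `tidy()` returns the call catalogue as a plain tibble; `glance()` returns a
#' one-row summary (number of calls, bases called, median region enrichment).
#'
#' @param x A `cut_calls` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cut_calls <- function(x, ...) {
  new_tibble(as.data.frame(x))
}

#' @rdname tidy.cut_calls
#' @export
glance.cut_calls <- function(x, ...) {
  has_enr <- "region_log2_enrichment" %in% names(x) && nrow(x) > 0
  tibble(
    n_calls = nrow(x),
    total_bases = sum(x$length %||% (x$end - x$start)),
    median_length = if (nrow(x) > 0) stats::median(x$end - x$start) else NA_real_,
    median_log2_enrichment = if (has_enr) stats::median(x$region_log2_enrichment) else NA_real_
  )
}

#' Tidy and summarize planted synthetic truth
#'
#' `tidy()` returns the planted CUT table; `glance()` the feature counts and
#' expected library totals.
#'
#' @param x A `synthetic_truth`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.synthetic_truth <- function(x, ...) {
  as_tibble(x$cuts)
}

#' @rdname tidy.synthetic_truth
#' @export
glance.synthetic_truth <- function(x, ...) {
  tibble(
    n_cuts = nrow(x$cuts),
    n_genes = nrow(x$genes),
    n_contaminant = nrow(x$contaminant),
    genome_bases = sum(x$genome$length),
    expected_total_wt = unname(x$library_totals["wt"]),
    expected_total_trf4 = unname(x$library_totals["trf4"])
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d chromosome(s) of %g bases: %d planted CUTs, %d genes, %d contaminant locus(es); seed %d\n",
    nrow(x$genome), x$genome$length[1], nrow(x$cuts), nrow(x$genes),
    nrow(x$contaminant), x$config$seed
  ))
  invisible(x)
}
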