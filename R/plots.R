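#' Two-library log-count scatter plot
#'
#' The classic two-condition comparison: one point per region, log-transformed
#' counts for each library, with the identity diagonal. Mutant-stabilized
#' transcripts appear as a cloud above the diagonal.
#'
#' @param object A `scatter_table` from [scatter_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scatter_table <- function(object, ...) {
  libs <- attr(object, "libraries")
  base <- attr(object, "log_base")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log_a, y = .data$log_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(
      x = sprintf("log%g read count, %s", base, libs[1] %||% "library A"),
      y = sprintf("log%g read count, %s", base, libs[2] %||% "library B")
    ) +
    ggplot2::theme_classic()
}

#' Chromosome coverage track plot
#'
#' Untransformed per-bin read counts along one or all chromosomes, optionally
#' with called CUT intervals marked underneath.
#'
#' @param object A `binned_track`.
#' @param chromosome Chromosome to show; `NULL` facets over all.
#' @param calls Optional `cut_calls` tibble to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_track <- function(object, chromosome = NULL, calls = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(chromosome)) {
    if (!chromosome %in% df$chrom) abort(sprintf("unknown chromosome '%s'.", chromosome))
    df <- df[df$chrom == chromosome, ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start, y = .data$count)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("reads per %d bp bin", as.integer(attr(object, "bin_width"))),
                  title = attr(object, "library")) +
    ggplot2::theme_classic()
  if (is.null(chromosome)) {
    p <- p + ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x")
  }
  if (!is.null(calls) && nrow(calls) > 0) {
    seg <- as_tibble(calls)
    if (!is.null(chromosome)) seg <- seg[seg$chrom == chromosome, ]
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start, xend = .data$end),
      y = -max(df$count) * 0.03, yend = -max(df$count) * 0.03,
      colour = "firebrick", linewidth = 1.5, inherit.aes = FALSE
    )
  }
  p
}

#' Per-bin enrichment track plot
#'
#' log2 mutant/wild-type ratio along the genome with the fold threshold marked;
#' bins failing the noise cut-off are de-emphasized.
#'
#' @param object An `enrichment_track`.
#' @param chromosome Chromosome to show; `NULL` facets over all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_track <- function(object, chromosome = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(chromosome)) {
    if (!chromosome %in% df$chrom) abort(sprintf("unknown chromosome '%s'.", chromosome))
    df <- df[df$chrom == chromosome, ]
  }
  params <- attr(object, "params")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start, y = .data$log2_ratio,
                                        alpha = .data$noise_pass)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_hline(yintercept = log2(params$fold_threshold),
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.15),
                                guide = "none") +
    ggplot2::labs(x = "position (bp)", y = "log2(trf4 / wt)") +
    ggplot2::theme_classic()
  if (is.null(chromosome)) {
    p <- p + ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x")
  }
  p
}
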