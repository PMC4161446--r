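#' Construct a genome index
#'
#' A genome index is the ordered table of chromosome names and lengths that
#' defines the binning lattice for all downstream operations. Chromosome order
#' is taken from the input and preserved in every track and call table.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-ish vector of chromosome lengths in bases (> 0).
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_index(c("chrI", "chrII"), c(230218, 813184))
#' @export
genome_index <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  if (anyDuplicated(chrom)) {
    abort("chromosome names must be unique.")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("chromosome lengths must be finite and > 0.")
  }
  tibble(chrom = chrom, length = length)
}

check_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort("`genome` must be a data frame with columns `chrom` and `length`.")
  }
  genome_index(genome$chrom, genome$length)
}

#' Full bin lattice for a genome
#'
#' Enumerates every bin of width `bin_width` covering the genome, one row per
#' bin, in genome order. The final bin of each chromosome may be partial.
#'
#' @param genome A [genome_index()] tibble.
#' @param bin_width Bin width in bases (> 0).
#' @return Tibble with columns `chrom` and `bin_start` (0-based).
#' @export
bin_lattice <- function(genome, bin_width) {
  genome <- check_genome(genome)
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    abort("`bin_width` must be a single positive number.")
  }
  pmap(genome, function(chrom, length) {
    tibble(chrom = chrom, bin_start = seq(0, length - 1, by = bin_width))
  }) |>
    list_rbind()
}

n_bins <- function(len, bin_width) as.integer(ceiling(len / bin_width))

# intervals: tibble(chrom, start, end) in 0-based half-open coordinates
check_intervals <- function(x, genome = NULL, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns chrom, start, end.", what))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0) || any(x$end <= x$start)) {
      abort(sprintf("`%s` must satisfy 0 <= start < end.", what))
    }
    if (!is.null(genome)) {
      lens <- setNames(genome$length, genome$chrom)
      unknown <- setdiff(unique(x$chrom), genome$chrom)
      if (length(unknown) > 0) {
        abort(sprintf("`%s` has chromosomes absent from the genome: %s",
                      what, paste(unknown, collapse = ", ")))
      }
      if (any(x$end > lens[x$chrom])) {
        abort(sprintf("`%s` extends beyond chromosome bounds.", what))
      }
    }
  }
  invisible(x)
}

# GRanges from 0-based half-open interval tibble
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}
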