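#' Configuration for the synthetic two-condition experiment
#'
#' Defines a synthetic genome carrying background genes expressed equally in
#' both conditions, planted CUT intervals with strong mutant-specific
#' enrichment and near-detection-limit wild-type signal, and one abundant
#' contaminant locus (emulating the 37S pre-rRNA) that receives a fixed
#' fraction of each library. Per-bin counts are negative-binomial.
#'
#' The defaults emulate the study conditions the pipeline was built for: a
#' trf4-delta : wild-type depth ratio of 21/16, CUT folds of 12-32 (mean 22,
#' the typical enrichment implied by a ~40%/~3% CUT read-occupancy contrast),
#' and a contaminant holding 10% of each library. At these defaults the
#' closed-form expected occupancy of planted CUTs is ~40% of mutant and ~3%
#' of wild-type reads (see [expected_occupancy()]).
#'
#' All planted features are aligned to the bin lattice: the analysis operates
#' at bin resolution, so lattice-aligned truth makes recovery exactly scorable.
#'
#' @param seed Integer seed; identical configs give bit-identical output.
#' @param n_chromosomes,chromosome_length Genome shape (equal-length
#'   chromosomes).
#' @param bin_width Bin width in bases.
#' @param n_background_genes,background_mean,gene_length_range Contiguous
#'   multi-bin blocks expressed equally (up to the depth ratio) in both
#'   conditions; mean is expected reads/bin in the wild-type library.
#' @param intergenic_mean Expected wild-type reads/bin between features.
#' @param dispersion Negative-binomial size parameter (variance =
#'   mu + mu^2 / dispersion); `Inf` gives Poisson counts.
#' @param n_cuts,cut_length_range,cut_fold_range Planted CUTs: count, length
#'   range in bases (min >= 3 bins) and the multiplicative mutant enrichment
#'   range.
#' @param wt_cut_mean Expected wild-type reads/bin inside CUTs (low: CUTs are
#'   nearly undetectable without blocking their degradation).
#' @param depth_ratio Mutant : wild-type library size ratio (default 21/16,
#'   the study's printed depths).
#' @param contaminant_fraction Fraction of each library placed in the single
#'   contaminant locus.
#' @param contaminant_length Length of the contaminant locus in bases
#'   (default 7 kb, the scale of the 37S pre-rRNA precursor).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_chromosomes = 2,
                             chromosome_length = 5e5,
                             bin_width = 100,
                             n_background_genes = 300,
                             background_mean = 30,
                             gene_length_range = c(500, 2000),
                             intergenic_mean = 0.1,
                             dispersion = 20,
                             n_cuts = 60,
                             cut_length_range = c(300, 1500),
                             cut_fold_range = c(12, 32),
                             wt_cut_mean = 6.5,
                             depth_ratio = 21 / 16,
                             contaminant_fraction = 0.1,
                             contaminant_length = 7000) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  pos1 <- c("n_chromosomes", "chromosome_length", "bin_width",
            "dispersion", "depth_ratio", "contaminant_length")
  for (f in pos1) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      abort(sprintf("`%s` must be a single positive number.", f))
    }
  }
  for (f in c("n_background_genes", "n_cuts")) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be >= 0.", f))
  }
  if (cfg$intergenic_mean < 0 || cfg$background_mean < 0 || cfg$wt_cut_mean <= 0) {
    abort("`intergenic_mean` and `background_mean` must be >= 0 and `wt_cut_mean` > 0.")
  }
  for (f in c("gene_length_range", "cut_length_range", "cut_fold_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0) {
      abort(sprintf("`%s` must be c(min, max) with 0 < min <= max.", f))
    }
  }
  if (cfg$cut_fold_range[1] < 1) abort("`cut_fold_range` minimum must be >= 1.")
  if (cfg$cut_length_range[1] < 3 * cfg$bin_width || cfg$cut_length_range[1] < 300) {
    abort("`cut_length_range` minimum must be >= 300 and >= 3 bins, so planted CUTs are callable.")
  }
  if (cfg$contaminant_fraction < 0 || cfg$contaminant_fraction >= 1) {
    abort("`contaminant_fraction` must be in [0, 1).")
  }
  cfg$seed <- as.integer(seed)
  cfg
}

check_config <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config().")
  }
  invisible(config)
}

config_genome <- function(config) {
  genome_index(
    sprintf("chr%d", seq_len(config$n_chromosomes)),
    rep(config$chromosome_length, config$n_chromosomes)
  )
}

# draw a lattice-aligned length uniformly over multiples of bin_width in range
draw_lengths <- function(n, range, w) {
  lo <- ceiling(range[1] / w) * w
  hi <- floor(range[2] / w) * w
  if (hi < lo) abort("length range contains no multiple of the bin width.")
  choices <- seq(lo, hi, by = w)
  if (length(choices) == 1) rep(choices, n) else sample(choices, n, replace = TRUE)
}

# uniform placement over the genome with rejection of overlaps against
# `occupied` (tibble chrom/start/end); lattice-aligned starts
place_intervals <- function(lengths, genome, w, occupied, what) {
  out <- vector("list", length(lengths))
  occ <- split(
    occupied[, c("start", "end"), drop = FALSE],
    factor(occupied$chrom, levels = genome$chrom)
  )
  lens <- setNames(genome$length, genome$chrom)
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    placed <- FALSE
    for (try in seq_len(2000)) {
      chrom <- sample(genome$chrom, 1, prob = genome$length)
      max_start <- lens[[chrom]] - L
      if (max_start < 0) next
      start <- sample.int(max_start %/% w + 1, 1) - 1
      start <- start * w
      end <- start + L
      cur <- occ[[chrom]]
      if (is.null(cur) || nrow(cur) == 0 ||
          all(end <= cur$start | start >= cur$end)) {
        occ[[chrom]] <- bind_rows(cur, tibble(start = start, end = end))
        out[[i]] <- tibble(chrom = chrom, start = start, end = end)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "infeasible config: could not place %s %d of %d without overlap; the genome is too crowded.",
        what, i, length(lengths)
      ))
    }
  }
  list_rbind(out)
}

#' Generate planted ground truth
#'
#' Places the contaminant locus, the planted CUTs (uniformly over the genome,
#' rejecting overlaps) and the background gene blocks, all pairwise disjoint
#' and lattice-aligned, and draws each CUT's fold uniformly from
#' `cut_fold_range`. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_truth` list: `genome`, `cuts` (chrom/start/end/fold/
#'   name), `genes`, `contaminant`, `library_totals` (closed-form expected
#'   reads per condition) and the config.
#' @export
generate_truth <- function(config) {
  check_config(config)
  set.seed(config$seed)
  genome <- config_genome(config)
  w <- config$bin_width
  empty <- tibble(chrom = character(), start = numeric(), end = numeric())

  contaminant <- if (config$contaminant_fraction > 0) {
    place_intervals(
      ceiling(config$contaminant_length / w) * w,
      genome, w, empty, "contaminant locus"
    )
  } else {
    empty
  }

  cuts <- if (config$n_cuts > 0) {
    place_intervals(
      draw_lengths(config$n_cuts, config$cut_length_range, w),
      genome, w, contaminant, "CUT"
    ) |>
      mutate(
        fold = runif(config$n_cuts, config$cut_fold_range[1], config$cut_fold_range[2]),
        name = sprintf("true_cut_%03d", seq_len(config$n_cuts))
      )
  } else {
    empty |> mutate(fold = numeric(), name = character())
  }

  genes <- if (config$n_background_genes > 0) {
    place_intervals(
      draw_lengths(config$n_background_genes, config$gene_length_range, w),
      genome, w, bind_rows(contaminant, cuts[, c("chrom", "start", "end")]),
      "background gene"
    )
  } else {
    empty
  }

  truth <- structure(
    list(genome = genome, cuts = cuts, genes = genes,
         contaminant = contaminant, config = config),
    class = "synthetic_truth"
  )
  truth$library_totals <- expected_totals(truth)
  truth
}

# per-bin expected wild-type means over the whole lattice, excluding the
# contaminant (which is added as a library fraction afterwards)
truth_bin_means <- function(truth) {
  config <- truth$config
  w <- config$bin_width
  lattice <- bin_lattice(truth$genome, w)
  mu_wt <- rep(config$intergenic_mean, nrow(lattice))
  fold <- rep(1, nrow(lattice))
  assign_bins <- function(intervals) {
    if (nrow(intervals) == 0) return(integer(0))
    bins_gr <- GenomicRanges::GRanges(
      seqnames = lattice$chrom,
      ranges = IRanges::IRanges(start = lattice$bin_start + 1, width = 1)
    )
    S4Vectors::queryHits(
      GenomicRanges::findOverlaps(bins_gr, intervals_to_granges(intervals))
    )
  }
  mu_wt[assign_bins(truth$genes)] <- config$background_mean
  cut_hit <- assign_bins(truth$cuts)
  mu_wt[cut_hit] <- config$wt_cut_mean
  if (length(cut_hit) > 0) {
    bins_gr <- GenomicRanges::GRanges(
      seqnames = lattice$chrom,
      ranges = IRanges::IRanges(start = lattice$bin_start + 1, width = 1)
    )
    hits <- GenomicRanges::findOverlaps(bins_gr, intervals_to_granges(truth$cuts))
    fold[S4Vectors::queryHits(hits)] <- truth$cuts$fold[S4Vectors::subjectHits(hits)]
  }
  contam <- rep(FALSE, nrow(lattice))
  contam[assign_bins(truth$contaminant)] <- TRUE
  mu_wt[contam] <- 0
  lattice |>
    mutate(mu_wt = mu_wt,
           mu_trf4 = mu_wt * fold * config$depth_ratio,
           fold = fold, contaminant = contam)
}

expected_totals <- function(truth) {
  mu <- truth_bin_means(truth)
  f <- truth$config$contaminant_fraction
  c(wt = sum(mu$mu_wt) / (1 - f), trf4 = sum(mu$mu_trf4) / (1 - f))
}

#' Simulate binned coverage for both conditions
#'
#' Draws per-bin counts from a negative-binomial law (mean from the planted
#' truth, size = `dispersion`; Poisson when `dispersion = Inf`), then places
#' the contaminant reads so that the contaminant locus holds, on average,
#' `contaminant_fraction` of each library. Library totals are recorded in the
#' track metadata and equal the bin sums exactly. Deterministic given
#' `config$seed`.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param config The same [synthetic_config()] the truth was generated with.
#' @return A named list of two raw `binned_track`s, `wt` and `trf4`.
#' @export
simulate_tracks <- function(truth, config = truth$config) {
  check_config(config)
  if (!inherits(truth, "synthetic_truth")) {
    abort("`truth` must come from generate_truth().")
  }
  set.seed(config$seed + 1L)
  mu <- truth_bin_means(truth)
  draw <- function(m) {
    if (is.infinite(config$dispersion)) rpois(length(m), m)
    else rnbinom(length(m), mu = m, size = config$dispersion)
  }
  one_track <- function(means, label) {
    counts <- draw(means)
    f <- config$contaminant_fraction
    ncb <- sum(mu$contaminant)
    if (f > 0 && ncb > 0) {
      n_contam <- rpois(1, sum(counts) * f / (1 - f))
      counts[mu$contaminant] <- as.numeric(
        rmultinom(1, n_contam, rep(1, ncb))
      )
    }
    new_binned_track(
      tibble(chrom = mu$chrom, bin_start = mu$bin_start, count = counts,
             blacklisted = FALSE),
      truth$genome, config$bin_width,
      library_total = sum(counts), library = label
    )
  }
  list(wt = one_track(mu$mu_wt, "wt"), trf4 = one_track(mu$mu_trf4, "trf4"))
}

#' Emit individual read positions for a simulated library
#'
#' Expands a simulated binned track back into per-read start positions,
#' uniform within each bin, for exercising [bin_reads()]: re-binning the
#' emitted reads at the same width reproduces the track exactly.
#'
#' @param track A raw `binned_track` (e.g. from [simulate_tracks()]).
#' @param seed Integer seed for the within-bin placement.
#' @return Tibble of reads: `chrom`, `pos` (0-based), in genome order.
#' @export
simulate_reads <- function(track, seed = 1) {
  check_track(track)
  set.seed(as.integer(seed))
  w <- attr(track, "bin_width")
  lens <- setNames(attr(track, "genome")$length, attr(track, "genome")$chrom)
  nz <- track[track$count > 0, ]
  if (nrow(nz) == 0) return(tibble(chrom = character(), pos = numeric()))
  reads <- pmap(nz[, c("chrom", "bin_start", "count")],
                function(chrom, bin_start, count) {
    width <- min(w, lens[[chrom]] - bin_start)
    tibble(chrom = chrom,
           pos = bin_start + sample.int(width, count, replace = TRUE) - 1)
  }) |>
    list_rbind()
  reads
}

#' Closed-form expected CUT read occupancy of a planted truth
#'
#' Computes, per library, the expected fraction of (contaminant-filtered)
#' reads falling in the planted CUT intervals, and a delta-method standard
#' error from the negative-binomial bin variances. Used to check that realized
#' occupancy matches the planted design (the study-emulating defaults plant
#' ~40% of mutant and ~3% of wild-type reads in CUTs).
#'
#' @param truth A `synthetic_truth`.
#' @return Tibble: `library`, `expected_fraction`, `se`.
#' @export
expected_occupancy <- function(truth) {
  if (!inherits(truth, "synthetic_truth")) {
    abort("`truth` must come from generate_truth().")
  }
  mu <- truth_bin_means(truth)
  theta <- truth$config$dispersion
  nb_var <- function(m) if (is.infinite(theta)) m else m + m^2 / theta
  one <- function(col) {
    bins_gr <- GenomicRanges::GRanges(
      seqnames = mu$chrom, ranges = IRanges::IRanges(start = mu$bin_start + 1, width = 1)
    )
    in_cut <- rep(FALSE, nrow(mu))
    if (nrow(truth$cuts) > 0) {
      in_cut[S4Vectors::queryHits(
        GenomicRanges::findOverlaps(bins_gr, intervals_to_granges(truth$cuts))
      )] <- TRUE
    }
    m <- mu[[col]]
    X <- sum(m[in_cut]); Y <- sum(m[!in_cut & !mu$contaminant])
    vX <- sum(nb_var(m[in_cut])); vY <- sum(nb_var(m[!in_cut & !mu$contaminant]))
    tot <- X + Y
    tibble(
      expected_fraction = if (tot > 0) X / tot else 0,
      se = if (tot > 0) sqrt(Y^2 * vX + X^2 * vY) / tot^2 else 0
    )
  }
  bind_rows(
    one("mu_wt") |> mutate(library = "wt", .before = 1),
    one("mu_trf4") |> mutate(library = "trf4", .before = 1)
  )
}
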