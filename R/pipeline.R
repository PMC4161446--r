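#' Read a pipeline configuration file
#'
#' YAML with a versioned schema (`config_version: 1`) and up to three blocks:
#' `synthetic` (arguments to [synthetic_config()]), `caller` (arguments to
#' [caller_params()]) and `options` (`region_width`, `log_base`,
#' `scatter_pseudocount`). Missing fields take the package defaults, which
#' mirror the published analysis parameters (100 bp bins, 4-fold, 3 bins,
#' 500 bp scatter regions).
#'
#' @param path YAML file.
#' @return A list with elements `synthetic`, `caller`, `options`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ver <- raw$config_version %||% 1
  if (!identical(as.integer(ver), 1L)) {
    abort(sprintf("unsupported config_version %s (this package reads version 1).", ver))
  }
  list(
    synthetic = do.call(synthetic_config, raw$synthetic %||% list()),
    caller = do.call(caller_params, raw$caller %||% list()),
    options = utils::modifyList(
      list(region_width = 500, log_base = 10, scatter_pseudocount = 1),
      raw$options %||% list()
    )
  )
}

#' Run the full synthetic-mode pipeline
#'
#' Simulates a two-condition experiment from planted truth, then runs the
#' complete analysis: blacklist the contaminant locus, total read-count
#' normalization, per-bin enrichment, CUT calling and annotation, planted-truth
#' recovery benchmarking, CUT read-occupancy fractions (on raw filtered
#' counts), the paired log-count scatter table, and the direction-averaged
#' overlap between called and planted CUTs. All outputs are written to
#' `outdir` as plain-text BED/bedGraph/TSV plus a JSON run manifest recording
#' parameters, seeds, normalization factors and per-stage record counts.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config A [synthetic_config()] (or a list from
#'   [read_pipeline_config()], whose caller/options blocks are then used).
#' @param outdir Output directory, created if needed.
#' @param params A [caller_params()] object.
#' @param region_width,log_base,scatter_pseudocount Scatter-table options.
#' @return Invisibly, a list with the in-memory results (`truth`, `tracks`,
#'   `calls`, `benchmark`, `occupancy`, `scatter`, `overlap`, `manifest`).
#' @export
run_pipeline <- function(config = synthetic_config(), outdir,
                         params = caller_params(),
                         region_width = 500, log_base = 10,
                         scatter_pseudocount = 1) {
  if (is.list(config) && !inherits(config, "synthetic_config") &&
      !is.null(config$synthetic)) {
    params <- config$caller %||% params
    opts <- config$options %||% list()
    region_width <- opts$region_width %||% region_width
    log_base <- opts$log_base %||% log_base
    scatter_pseudocount <- opts$scatter_pseudocount %||% scatter_pseudocount
    config <- config$synthetic
  }
  check_config(config)
  check_params(params)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", label, conditionMessage(e)))
    })
  }

  res <- list()
  res$truth <- stage("simulate/truth", generate_truth(config))
  message(sprintf("simulate: planted %d CUTs, %d background genes, %d contaminant locus(es)",
                  nrow(res$truth$cuts), nrow(res$truth$genes), nrow(res$truth$contaminant)))
  res$tracks <- stage("simulate/tracks", simulate_tracks(res$truth, config))
  message(sprintf("simulate: library totals wt=%d trf4=%d",
                  attr(res$tracks$wt, "library_total"),
                  attr(res$tracks$trf4, "library_total")))

  filtered <- stage("blacklist", lapply(res$tracks, apply_blacklist, res$truth$contaminant))
  message(sprintf("blacklist: effective totals wt=%d trf4=%d",
                  attr(filtered$wt, "effective_total"),
                  attr(filtered$trf4, "effective_total")))
  normed <- stage("normalize", normalize_pair(filtered$wt, filtered$trf4))
  names(normed) <- c("wt", "trf4")
  message(sprintf("normalize: factors wt=%.4f trf4=%.4f",
                  attr(normed$wt, "norm_factor"), attr(normed$trf4, "norm_factor")))

  enr <- stage("enrich", compute_enrichment(normed$trf4, normed$wt, params))
  res$calls <- stage("call", annotate_calls(call_cuts(enr, params),
                                            normed$trf4, normed$wt, params))
  message(sprintf("call: %d CUTs annotated", nrow(res$calls)))

  res$benchmark <- stage("benchmark", benchmark_calls(res$calls, res$truth))
  res$occupancy <- stage("stats/occupancy", bind_rows(
    occupancy_fraction(filtered$wt, res$calls) |> mutate(annotation = "called_cuts"),
    occupancy_fraction(filtered$trf4, res$calls) |> mutate(annotation = "called_cuts"),
    occupancy_fraction(filtered$wt, res$truth$cuts) |> mutate(annotation = "planted_cuts"),
    occupancy_fraction(filtered$trf4, res$truth$cuts) |> mutate(annotation = "planted_cuts")
  ))
  message(sprintf(
    "stats: %.1f%% of trf4 and %.1f%% of wt filtered reads in called CUTs",
    100 * res$occupancy$fraction[res$occupancy$library == "trf4" &
                                   res$occupancy$annotation == "called_cuts"],
    100 * res$occupancy$fraction[res$occupancy$library == "wt" &
                                   res$occupancy$annotation == "called_cuts"]
  ))
  res$scatter <- stage("stats/scatter",
                       scatter_table(normed$wt, normed$trf4, region_width,
                                     scatter_pseudocount, log_base))
  res$overlap <- stage("compare",
                       averaged_overlap(res$calls, res$truth$cuts,
                                        "called", "planted"))

  # compute everything first, write last: a failed write removes its partial
  # outputs so the output directory is never left half-populated
  files <- tryCatch({
    f <- list(
      genome = file.path(outdir, "genome.tsv"),
      truth_bed = file.path(outdir, "truth_cuts.bed"),
      counts = file.path(outdir, "counts_raw.tsv"),
      wt_bedgraph = file.path(outdir, "wt_raw.bedGraph"),
      trf4_bedgraph = file.path(outdir, "trf4_raw.bedGraph"),
      wt_norm_bedgraph = file.path(outdir, "wt_normalized.bedGraph"),
      trf4_norm_bedgraph = file.path(outdir, "trf4_normalized.bedGraph"),
      calls_bed = file.path(outdir, "cut_calls.bed"),
      calls_tsv = file.path(outdir, "cut_calls.tsv"),
      occupancy = file.path(outdir, "occupancy.tsv"),
      scatter = file.path(outdir, "scatter_500bp.tsv"),
      overlap = file.path(outdir, "overlap_called_vs_planted.tsv"),
      manifest = file.path(outdir, "manifest.json")
    )
    readr::write_tsv(res$truth$genome, f$genome, col_names = FALSE, progress = FALSE)
    write_truth_bed(res$truth, f$truth_bed)
    write_counts_tsv(res$tracks$wt, res$tracks$trf4, f$counts)
    write_track_bedgraph(res$tracks$wt, f$wt_bedgraph)
    write_track_bedgraph(res$tracks$trf4, f$trf4_bedgraph)
    write_track_bedgraph(normed$wt, f$wt_norm_bedgraph)
    write_track_bedgraph(normed$trf4, f$trf4_norm_bedgraph)
    write_calls_bed(res$calls, f$calls_bed)
    write_calls_tsv(res$calls, f$calls_tsv)
    readr::write_tsv(res$occupancy, f$occupancy, progress = FALSE)
    readr::write_tsv(as_tibble(res$scatter), f$scatter, progress = FALSE)
    readr::write_tsv(res$overlap, f$overlap, progress = FALSE)
    f
  }, error = function(e) {
    unlink(file.path(outdir, c(
      "genome.tsv", "truth_cuts.bed", "counts_raw.tsv", "wt_raw.bedGraph",
      "trf4_raw.bedGraph", "wt_normalized.bedGraph", "trf4_normalized.bedGraph",
      "cut_calls.bed", "cut_calls.tsv", "occupancy.tsv", "scatter_500bp.tsv",
      "overlap_called_vs_planted.tsv", "manifest.json"
    )))
    abort(sprintf("pipeline stage 'write' failed: %s", conditionMessage(e)))
  })

  res$manifest <- list(
    package = "cutcaller",
    version = as.character(utils::packageVersion("cutcaller")),
    seed = config$seed,
    synthetic_config = unclass(config),
    caller_params = unclass(params),
    options = list(region_width = region_width, log_base = log_base,
                   scatter_pseudocount = scatter_pseudocount),
    normalization_factors = list(wt = attr(normed$wt, "norm_factor"),
                                 trf4 = attr(normed$trf4, "norm_factor")),
    library_totals = list(wt = attr(res$tracks$wt, "library_total"),
                          trf4 = attr(res$tracks$trf4, "library_total")),
    effective_totals = list(wt = attr(filtered$wt, "effective_total"),
                            trf4 = attr(filtered$trf4, "effective_total")),
    stage_counts = list(
      planted_cuts = nrow(res$truth$cuts),
      bins = nrow(res$tracks$wt),
      blacklisted_bins = sum(filtered$wt$blacklisted),
      calls = nrow(res$calls)
    ),
    files = files
  )
  jsonlite::write_json(res$manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
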