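# Shared fixtures: toy genomes, tracks built from explicit count vectors, and
# independent brute-force oracles used to cross-check the fast implementations.

toy_genome <- function(n_chrom = 1, len = 1000) {
  genome_index(sprintf("chr%d", seq_len(n_chrom)), rep(len, n_chrom))
}

# track from a per-chromosome list (or single vector) of counts
track_from_counts <- function(counts, bin_width = 100, genome = NULL,
                              library = NA_character_) {
  if (!is.list(counts)) counts <- list(chr1 = counts)
  if (is.null(names(counts))) names(counts) <- sprintf("chr%d", seq_along(counts))
  if (is.null(genome)) {
    genome <- genome_index(names(counts), lengths(counts) * bin_width)
  }
  bins <- purrr::list_rbind(purrr::imap(counts, function(v, nm) {
    tibble::tibble(chrom = nm, bin_start = (seq_along(v) - 1) * bin_width,
                   count = as.numeric(v))
  }))
  binned_track(bins, genome, bin_width, library = library)
}

# enrichment track constructed directly from pass/fail flags (one chromosome
# per list element), for exercising the run caller in isolation
enrichment_from_flags <- function(flags, bin_width = 100,
                                  params = caller_params(min_length = 0)) {
  if (!is.list(flags)) flags <- list(chr1 = flags)
  if (is.null(names(flags))) names(flags) <- sprintf("chr%d", seq_along(flags))
  genome <- genome_index(names(flags), lengths(flags) * bin_width)
  df <- purrr::list_rbind(purrr::imap(flags, function(v, nm) {
    tibble::tibble(
      chrom = nm, bin_start = (seq_along(v) - 1) * bin_width,
      wt = 0, trf4 = ifelse(v, 100, 0),
      log2_ratio = ifelse(v, log2(101), 0),
      fold_pass = v, noise_pass = v, blacklisted = FALSE
    )
  }))
  structure(df, class = c("enrichment_track", class(df)),
            genome = genome, bin_width = bin_width, params = params)
}

# brute-force maximal-run oracle over all (start, end) index pairs, via
# cumulative sums; independent of the rle-based implementation
oracle_runs_all_pairs <- function(pass, min_len) {
  n <- length(pass)
  if (n == 0) return(data.frame(first = integer(), n = integer()))
  cs <- c(0, cumsum(pass))
  idx <- which(outer(seq_len(n), seq_len(n), function(s, e) e >= s + min_len - 1),
               arr.ind = TRUE)
  s <- idx[, 1]; e <- idx[, 2]
  full <- (cs[e + 1] - cs[s]) == (e - s + 1)
  maximal <- full & (s == 1 | !pass[pmax(s - 1, 1)]) & (e == n | !pass[pmin(e + 1, n)])
  data.frame(first = s[maximal], n = (e - s + 1)[maximal])[order(s[maximal]), ]
}

# second independent oracle: derive maximal runs from the gaps between
# failing positions (linear; used for long vectors)
oracle_runs_gaps <- function(pass, min_len) {
  fails <- c(0, which(!pass), length(pass) + 1)
  first <- fails[-length(fails)] + 1
  last <- fails[-1] - 1
  len <- last - first + 1
  keep <- len >= min_len & len > 0
  data.frame(first = first[keep], n = len[keep])
}

# all-pairs brute-force directional overlap count
oracle_directional <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i]
    hit[i] <- any(same & b$start < a$end[i] & b$end > a$start[i])
  }
  sum(hit)
}

random_interval_set <- function(n, genome, max_len = 2000, name = "set") {
  chrom <- sample(genome$chrom, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (setNames(genome$length, genome$chrom)[chrom] - len))
  annotation_set(tibble::tibble(chrom = chrom, start = start, end = start + len),
                 name = name)
}

# a small simulated experiment shared by several tests
small_config <- function(seed = 1, n_cuts = 8, ...) {
  synthetic_config(
    seed = seed, n_chromosomes = 1, chromosome_length = 1e5,
    n_background_genes = 30, n_cuts = n_cuts, ...
  )
}

simulate_filtered_pair <- function(config) {
  truth <- generate_truth(config)
  tracks <- simulate_tracks(truth, config)
  filtered <- lapply(tracks, apply_blacklist, truth$contaminant)
  list(truth = truth, raw = tracks, filtered = filtered,
       normalized = setNames(normalize_pair(filtered$wt, filtered$trf4),
                             c("wt", "trf4")))
}
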