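test_that("truth generation is deterministic and honors the empty case", {
  cfg <- small_config(seed = 1)
  expect_identical(generate_truth(cfg), generate_truth(cfg))
  none <- generate_truth(small_config(seed = 2, n_cuts = 0))
  expect_equal(nrow(none$cuts), 0)
})

test_that("planted CUTs are pairwise disjoint and inside chromosome bounds", {
  cfg <- synthetic_config(seed = 7, n_chromosomes = 1, chromosome_length = 1e6,
                          n_cuts = 50, cut_length_range = c(300, 1500))
  truth <- generate_truth(cfg)
  cuts <- truth$cuts
  expect_equal(nrow(cuts), 50)
  occupied <- dplyr::bind_rows(cuts[, c("chrom", "start", "end")], truth$contaminant)
  for (i in seq_len(nrow(occupied))) {
    for (j in seq_len(nrow(occupied))) {
      if (i < j && occupied$chrom[i] == occupied$chrom[j]) {
        expect_true(occupied$end[i] <= occupied$start[j] ||
                      occupied$end[j] <= occupied$start[i])
      }
    }
  }
  expect_true(all(cuts$start >= 0 & cuts$end <= 1e6))
  expect_true(all(cuts$end - cuts$start >= 3 * cfg$bin_width))
  expect_true(all(cuts$fold >= cfg$cut_fold_range[1] &
                    cuts$fold <= cfg$cut_fold_range[2]))
})

test_that("an overcrowded genome is rejected as infeasible", {
  expect_error(
    generate_truth(synthetic_config(
      seed = 1, n_chromosomes = 1, chromosome_length = 10000,
      n_cuts = 50, cut_length_range = c(1500, 1500), n_background_genes = 0
    )),
    "infeasible"
  )
})

test_that("simulated tracks are deterministic and conserve the recorded totals", {
  cfg <- small_config(seed = 3)
  truth <- generate_truth(cfg)
  a <- simulate_tracks(truth, cfg)
  b <- simulate_tracks(truth, cfg)
  expect_identical(a, b)
  for (tk in a) {
    expect_equal(sum(tk$count), attr(tk, "library_total"))
    expect_true(all(tk$count >= 0 & tk$count == round(tk$count)))
  }
})

test_that("the Poisson zero-signal limit yields all-zero tracks", {
  cfg <- synthetic_config(seed = 5, n_chromosomes = 1, chromosome_length = 1e4,
                          n_cuts = 0, n_background_genes = 0, background_mean = 0,
                          intergenic_mean = 0, dispersion = Inf,
                          contaminant_fraction = 0)
  tracks <- simulate_tracks(generate_truth(cfg), cfg)
  expect_true(all(tracks$wt$count == 0))
  expect_true(all(tracks$trf4$count == 0))
})

test_that("CUT-bin means match the closed-form expectation (fold x wt mean x depth)", {
  # planted fold 8 on wt mean 5: trf4 CUT bins average 40 * depth_ratio
  cfg <- synthetic_config(
    seed = 9, n_chromosomes = 1, chromosome_length = 1e6,
    n_cuts = 80, cut_length_range = c(1200, 1500), cut_fold_range = c(8, 8),
    wt_cut_mean = 5, n_background_genes = 50, depth_ratio = 1.3125
  )
  truth <- generate_truth(cfg)
  tracks <- simulate_tracks(truth, cfg)
  gr_bins <- tracks$trf4$bin_start
  in_cut <- rep(FALSE, nrow(tracks$trf4))
  for (i in seq_len(nrow(truth$cuts))) {
    in_cut <- in_cut | (tracks$trf4$chrom == truth$cuts$chrom[i] &
                          gr_bins >= truth$cuts$start[i] &
                          gr_bins < truth$cuts$end[i])
  }
  n <- sum(in_cut)
  expect_gte(n, 1000)
  mu <- 5 * 8 * 1.3125
  se <- sqrt((mu + mu^2 / cfg$dispersion) / n)
  expect_lt(abs(mean(tracks$trf4$count[in_cut]) - mu), 3 * se)
  mu_wt <- 5
  se_wt <- sqrt((mu_wt + mu_wt^2 / cfg$dispersion) / n)
  expect_lt(abs(mean(tracks$wt$count[in_cut]) - mu_wt), 3 * se_wt)
})

test_that("the contaminant locus captures its configured library fraction", {
  cfg <- synthetic_config(seed = 4, n_chromosomes = 1, chromosome_length = 5e5,
                          n_background_genes = 100, n_cuts = 20,
                          contaminant_fraction = 0.3)
  truth <- generate_truth(cfg)
  tracks <- simulate_tracks(truth, cfg)
  for (tk in tracks) {
    contam <- apply_blacklist(tk, truth$contaminant)
    frac <- 1 - attr(contam, "effective_total") / attr(tk, "library_total")
    expect_lt(abs(frac - 0.3), 0.01)
  }
})

test_that("emitted read positions re-bin to the originating track exactly", {
  cfg <- small_config(seed = 6)
  tracks <- simulate_tracks(generate_truth(cfg), cfg)
  reads <- simulate_reads(tracks$trf4, seed = 99)
  rebuilt <- bin_reads(reads, attr(tracks$trf4, "genome"), cfg$bin_width)
  expect_equal(rebuilt$count, tracks$trf4$count)
})

test_that("config validation enforces the planted-CUT callability floor", {
  expect_error(synthetic_config(cut_length_range = c(200, 1500)), "callable")
  expect_error(synthetic_config(cut_fold_range = c(0.5, 4)), "cut_fold_range")
  expect_error(synthetic_config(contaminant_fraction = 1), "contaminant_fraction")
  expect_error(synthetic_config(dispersion = 0), "dispersion")
})
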