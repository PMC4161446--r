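test_that("per-bin enrichment arithmetic and flags follow the pseudocounted ratio", {
  trf4 <- track_from_counts(c(100, 80, 8))
  wt <- track_from_counts(c(100, 0, 0))
  enr <- compute_enrichment(trf4, wt, caller_params())
  # identical bins: ratio 1, no fold call
  expect_equal(enr$log2_ratio[1], 0)
  expect_false(enr$fold_pass[1])
  # 80 vs 0 with pseudocount 1: ratio 81, both flags pass
  expect_equal(enr$log2_ratio[2], log2(81), tolerance = 1e-12)
  expect_true(enr$fold_pass[2])
  expect_true(enr$noise_pass[2])
  # 8 vs 0: enriched but below the noise cut-off of 10
  expect_true(enr$fold_pass[3])
  expect_false(enr$noise_pass[3])
})

test_that("blacklisted bins always fail both criteria", {
  trf4 <- track_from_counts(c(500, 500, 500))
  wt <- track_from_counts(c(0, 0, 0))
  bl <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  enr <- compute_enrichment(apply_blacklist(trf4, bl), apply_blacklist(wt, bl))
  expect_equal(enr$fold_pass, c(TRUE, FALSE, TRUE))
  expect_equal(enr$noise_pass, c(TRUE, FALSE, TRUE))
  expect_equal(call_cuts(enr, caller_params())$n_bins, integer(0))
})

test_that("call_cuts returns exactly the maximal qualifying runs", {
  params <- caller_params(min_length = 0)
  enr <- enrichment_from_flags(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), params = params)
  calls <- call_cuts(enr, params)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 0)
  expect_equal(calls$end, 300)
  expect_equal(calls$n_bins, 3L)

  none <- call_cuts(enrichment_from_flags(rep(FALSE, 10), params = params), params)
  expect_equal(nrow(none), 0)
})

test_that("calls never cross chromosome boundaries and come back in genome order", {
  params <- caller_params(min_length = 0)
  enr <- enrichment_from_flags(
    list(chrB = c(TRUE, TRUE, TRUE, TRUE), chrA = c(TRUE, TRUE, TRUE)),
    params = params
  )
  calls <- call_cuts(enr, params)
  expect_equal(calls$chrom, c("chrB", "chrA"))
  expect_equal(calls$n_bins, c(4L, 3L))
})

test_that("the minimum-span rule is a strict inequality on genomic length", {
  params3 <- caller_params(min_consecutive_bins = 2, min_length = 200)
  enr <- enrichment_from_flags(c(TRUE, TRUE, FALSE), params = params3)
  # two bins span exactly 200 bases: not > 200, so rejected
  expect_equal(nrow(call_cuts(enr, params3)), 0)
  params2 <- caller_params(min_consecutive_bins = 2, min_length = 199)
  expect_equal(nrow(call_cuts(enr, params2)), 1)
})

test_that("a qualifying run may end on a terminal partial bin", {
  gen <- genome_index("chr1", 250)
  trf4 <- binned_track(tibble::tibble(chrom = "chr1", bin_start = c(0, 100, 200),
                                      count = c(50, 50, 50)), gen, 100)
  wt <- binned_track(tibble::tibble(chrom = "chr1", bin_start = c(0, 100, 200),
                                    count = c(0, 0, 0)), gen, 100)
  calls <- call_cuts(compute_enrichment(trf4, wt))
  expect_equal(calls$end, 250)
  expect_equal(calls$n_bins, 3L)
  expect_equal(calls$length, 250)
})

test_that("region annotation fills log2 enrichment from pseudocounted sums", {
  trf4 <- track_from_counts(c(33, 33, 33, 0))
  wt <- track_from_counts(c(0, 0, 0, 50))
  calls <- annotate_cuts(trf4, wt, caller_params(min_length = 0))
  expect_equal(nrow(calls), 1)
  # sums 99 vs 0 over 3 bins, pseudocount 1 each side: log2(102/3) = log2(34)
  expect_equal(calls$region_log2_enrichment, log2(34), tolerance = 1e-12)
  expect_equal(calls$max_bin_count, 33)
})

test_that("equal region sums give zero enrichment", {
  gen <- toy_genome(len = 300)
  trf4 <- track_from_counts(c(40, 40, 40), genome = gen)
  wt <- track_from_counts(c(40, 40, 40), genome = gen)
  enr <- compute_enrichment(trf4, wt)
  calls <- call_cuts(enr)
  expect_equal(nrow(calls), 0) # identity ratio can never pass the fold flag
  # annotate a forced region instead
  forced <- enrichment_from_flags(c(TRUE, TRUE, TRUE))
  ann <- annotate_calls(call_cuts(forced, caller_params(min_length = 0)),
                        trf4, wt, caller_params(min_length = 0))
  expect_equal(ann$region_log2_enrichment, 0)
})

test_that("raising thresholds never increases the number of called bases", {
  for (seed in 1:5) {
    sim <- simulate_filtered_pair(small_config(seed))
    bases <- function(fold, noise) {
      calls <- call_cuts(compute_enrichment(
        sim$normalized$trf4, sim$normalized$wt,
        caller_params(fold_threshold = fold, noise_min_count = noise)
      ))
      sum(calls$length)
    }
    expect_gte(bases(4, 10), bases(6, 10))
    expect_gte(bases(6, 10), bases(8, 10))
    expect_gte(bases(4, 10), bases(4, 30))
    expect_gte(bases(4, 30), bases(4, 60))
  }
})

test_that("caller parameter validation rejects degenerate settings", {
  expect_error(caller_params(fold_threshold = 1), "fold_threshold")
  expect_error(caller_params(pseudocount = 0), "pseudocount")
  expect_error(caller_params(min_consecutive_bins = 0), "min_consecutive_bins")
})
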