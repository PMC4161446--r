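test_that("bin_reads assigns reads to half-open bins by start position", {
  gen <- toy_genome(len = 1000)
  tr <- bin_reads(tibble::tibble(chrom = "chr1", pos = c(0, 99, 100)), gen, 100)
  expect_equal(tr$count, c(2, 1, 0, rep(0, 7)))
  expect_equal(attr(tr, "library_total"), 3)

  empty <- bin_reads(tibble::tibble(chrom = character(), pos = numeric()), gen, 100)
  expect_true(all(empty$count == 0))
  expect_equal(nrow(empty), 10)
})

test_that("bin_reads matches an independent per-read tally and conserves counts", {
  set.seed(42)
  gen <- toy_genome(len = 1e5)
  pos <- floor(runif(10000) * 1e5)
  tr <- bin_reads(tibble::tibble(chrom = "chr1", pos = pos), gen, 100)
  tally <- vapply(seq(0, 1e5 - 1, by = 100),
                  function(s) sum(pos >= s & pos < s + 100), numeric(1))
  expect_equal(tr$count, tally)
  expect_equal(sum(tr$count), 10000)
})

test_that("bin_reads handles a terminal partial bin and rejects out-of-bounds reads", {
  gen <- toy_genome(len = 250)
  tr <- bin_reads(tibble::tibble(chrom = "chr1", pos = c(240, 249)), gen, 100)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$count, c(0, 0, 2))
  expect_error(
    bin_reads(tibble::tibble(chrom = "chr1", pos = 250), gen, 100),
    "chr1:250"
  )
  expect_error(
    bin_reads(tibble::tibble(chrom = "chrX", pos = 1), gen, 100),
    "chrX"
  )
})

test_that("apply_blacklist zeroes overlapped bins and adjusts the effective total", {
  tr <- track_from_counts(c(5, 10, 15, 20))
  expect_identical(apply_blacklist(tr, tibble::tibble(chrom = character(),
                                                      start = numeric(),
                                                      end = numeric())), tr)
  # interval clipping into bins 2 and 3 by a single base each
  bl <- tibble::tibble(chrom = "chr1", start = 199, end = 201)
  out <- apply_blacklist(tr, bl)
  expect_equal(out$count, c(5, 0, 0, 20))
  expect_equal(out$blacklisted, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(attr(out, "effective_total"), 25)
  expect_equal(attr(out, "library_total"), 50)

  all_gone <- apply_blacklist(tr, tibble::tibble(chrom = "chr1", start = 0, end = 400))
  expect_true(all(all_gone$count == 0))
  expect_equal(attr(all_gone, "effective_total"), 0)
})

test_that("normalize_pair scales the shallower library up to the deeper one", {
  a <- track_from_counts(c(10, 6))
  b <- track_from_counts(c(20, 1))
  out <- normalize_pair(a, b)
  expect_equal(attr(out[[1]], "norm_factor"), 21 / 16)
  expect_equal(attr(out[[2]], "norm_factor"), 1)
  expect_equal(out[[1]]$count, c(10, 6) * 21 / 16)
  expect_equal(out[[2]]$count, c(20, 1))

  ident <- normalize_pair(a, a)
  expect_equal(attr(ident[[1]], "norm_factor"), 1)
  expect_equal(ident[[1]]$count, a$count)
})

test_that("normalization is symmetric under relabeling and fails on empty libraries", {
  a <- track_from_counts(c(3, 9, 1))
  b <- track_from_counts(c(2, 2, 2))
  ab <- normalize_pair(a, b)
  ba <- normalize_pair(b, a)
  expect_identical(ab[[1]]$count, ba[[2]]$count)
  expect_identical(ab[[2]]$count, ba[[1]]$count)
  zero <- track_from_counts(c(0, 0, 0))
  expect_error(normalize_pair(a, zero), "empty library")
  expect_error(normalize_pair(ab[[1]], b), "raw")
})

test_that("depth rescaling leaves normalized tracks unchanged up to a common reference scale", {
  # rescaling one raw library rescales the common reference total, so the
  # normalized pair changes only by one shared constant: every between-library
  # bin ratio, and hence every call, is invariant
  set.seed(7)
  a <- track_from_counts(rpois(50, 20) + 1)
  b <- track_from_counts(rpois(50, 35) + 1)
  base <- normalize_pair(a, b)
  scaled <- normalize_pair(scale_track(a, 10), b)
  shared <- scaled[[1]]$count[1] / base[[1]]$count[1]
  expect_equal(scaled[[1]]$count, base[[1]]$count * shared, tolerance = 1e-9)
  expect_equal(scaled[[2]]$count, base[[2]]$count * shared, tolerance = 1e-9)
  expect_equal(scaled[[1]]$count / scaled[[2]]$count,
               base[[1]]$count / base[[2]]$count, tolerance = 1e-9)
})

test_that("rebin sums consecutive groups, keeps partial tails, conserves counts", {
  tr <- track_from_counts(c(1, 2, 3, 4, 5))
  expect_identical(rebin(tr, 100), tr)
  out <- rebin(tr, 200)
  expect_equal(out$count, c(3, 7, 5))
  expect_equal(sum(out$count), sum(tr$count))
  expect_error(rebin(tr, 250), "multiple")
})

test_that("rebinning a read-derived track equals binning the reads coarsely", {
  set.seed(11)
  gen <- toy_genome(len = 10150)
  reads <- tibble::tibble(chrom = "chr1", pos = floor(runif(3000) * 10150))
  fine <- bin_reads(reads, gen, 100)
  expect_equal(rebin(fine, 500)$count, bin_reads(reads, gen, 500)$count)
})

test_that("binned_track fills sparse count tables and validates the lattice", {
  gen <- toy_genome(len = 500)
  tr <- binned_track(tibble::tibble(chrom = "chr1", bin_start = 300, count = 7),
                     gen, 100)
  expect_equal(tr$count, c(0, 0, 0, 7, 0))
  expect_error(
    binned_track(tibble::tibble(chrom = "chr1", bin_start = 50, count = 1), gen, 100),
    "multiples"
  )
  expect_error(
    binned_track(tibble::tibble(chrom = "chr1", bin_start = c(0, 0), count = 1), gen, 100),
    "duplicate"
  )
})
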