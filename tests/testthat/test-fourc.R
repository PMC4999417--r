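# Fragment maps, read allocation, binned profiles and smoothing.

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("fragment boundaries sit at primary-site starts", {
  fm <- build_fragment_map("AAGATCAA", chrom = "toy")
  expect_identical(fm$fragments$start, c(0, 2))
  expect_identical(fm$fragments$end, c(2, 8))

  # a fragment containing the secondary site is not blind
  fm2 <- build_fragment_map("GATCAAAGCTTAAGATC", chrom = "toy")
  has_sec <- grepl("AAGCTT", c("GATCAAAGCTTAA"))
  expect_false(fm2$fragments$blind[1])

  # no primary site: one fragment with a warning
  expect_warning(fm3 <- build_fragment_map("AAAACCCC"), "single fragment")
  expect_identical(nrow(fm3$fragments), 1L)
})

test_that("fragment maps partition the sequence and match string search", {
  seq <- random_seq(30000, seed = 47)
  fm <- build_fragment_map(seq, chrom = "chrT", offset = 1000)
  frags <- fm$fragments
  # exact partition
  expect_identical(frags$start[1], 1000)
  expect_identical(frags$end[nrow(frags)], 1000 + 30000)
  expect_identical(frags$start[-1], frags$end[-nrow(frags)])
  expect_identical(sum(frags$end - frags$start), 30000)

  # boundaries recoverable by independent string search
  hits <- gregexpr("GATC", seq, fixed = TRUE)[[1]]
  expect_equal(frags$start[-1] - 1000, as.numeric(hits[hits > 1]) - 1)

  # blind classification by independent substring test
  blind_oracle <- vapply(seq_len(nrow(frags)), function(i) {
    !grepl("AAGCTT",
           substr(seq, frags$start[i] - 1000 + 1, frags$end[i] - 1000),
           fixed = TRUE)
  }, logical(1))
  expect_identical(frags$blind, blind_oracle)
})

test_that("read assignment filters, deduplicates and matches containment", {
  seq <- random_seq(20000, seed = 53)
  fm <- build_fragment_map(seq, chrom = "chrT")
  mk_reads <- function(starts, mapq = 60, strand = "+") {
    data.frame(chrom = "chrT", start = starts, end = starts + 50,
               name = sprintf("r%04d", seq_along(starts)), score = mapq,
               strand = strand, stringsAsFactors = FALSE)
  }

  # everything below the quality threshold drops out
  low <- mk_reads(c(100, 500, 900), mapq = 29)
  expect_identical(sum(assign_reads(low, fm)$counts), 0L)

  # duplicate 5' positions collapse to one unique event
  dup <- mk_reads(c(100, 100, 100, 500))
  expect_identical(sum(assign_reads(dup, fm)$counts), 2L)

  # brute-force interval containment on random reads
  set.seed(59)
  starts <- sample.int(19000, 3000, replace = TRUE)
  reads <- mk_reads(starts)
  res <- assign_reads(reads, fm)
  u <- unique(starts)
  brute <- vapply(seq_len(nrow(fm$fragments)), function(i) {
    sum(u >= fm$fragments$start[i] & u < fm$fragments$end[i])
  }, integer(1))
  expect_identical(res$counts, brute)

  # masking and viewpoint exclusion remove their reads
  res_m <- assign_reads(reads, fm,
                        masked = data.frame(start = 5000, end = 6000))
  expect_identical(sum(res_m$counts[fm$fragments$start >= 5000 &
                                      fm$fragments$end <= 6000]), 0L)
  res_v <- assign_reads(reads, fm, viewpoint = 10000,
                        exclusion_radius = 1500)
  expect_identical(sum(res_v$counts), sum(!(unique(starts) >= 8500 &
                                              unique(starts) <= 11500)))
})

test_that("binned profiles spread counts by overlap and conserve signal", {
  # one fragment exactly spanning three bins with count 6 -> 2 per bin
  seq <- paste0(strrep("A", 100), "GATC", strrep("C", 296), "GATC",
                strrep("T", 96))
  fm <- build_fragment_map(seq, chrom = "toy")
  expect_identical(fm$fragments$start, c(0, 100, 400))
  counts <- c(0L, 6L, 0L)
  prof <- binned_profile(counts, fm, resolution = 100)
  expect_equal(prof$bins$combined[2:4], c(2, 2, 2))

  # conservation of total signal on random data
  seq2 <- random_seq(25000, seed = 61)
  fm2 <- build_fragment_map(seq2, chrom = "chrT")
  set.seed(67)
  cts <- rpois(nrow(fm2$fragments), 3)
  prof2 <- binned_profile(cts, fm2, resolution = 100)
  expect_equal(sum(prof2$bins$combined), sum(cts), tolerance = 1e-9)
  expect_equal(prof2$bins$combined, prof2$bins$blind + prof2$bins$nonblind,
               tolerance = 1e-12)

  # per-base accumulation oracle
  per_base <- numeric(25000)
  for (i in seq_len(nrow(fm2$fragments))) {
    s <- fm2$fragments$start[i]; e <- fm2$fragments$end[i]
    per_base[(s + 1):e] <- cts[i] / (e - s)
  }
  brute_bins <- vapply(seq_len(nrow(prof2$bins)), function(b) {
    sum(per_base[(prof2$bins$start[b] + 1):prof2$bins$end[b]])
  }, 0)
  expect_equal(prof2$bins$combined, brute_bins, tolerance = 1e-9)
})

test_that("running-window smoothing is a masked centred mean", {
  seq <- random_seq(20000, seed = 71)
  fm <- build_fragment_map(seq, chrom = "chrT")
  cts <- rep(0L, nrow(fm$fragments))

  # constant profile smooths to itself (edges included: mean of a constant)
  prof_c <- binned_profile(rep(1L, nrow(fm$fragments)), fm)
  prof_c$bins$combined <- 3.5
  sm_c <- smooth_profile(prof_c, window = 5000)
  expect_equal(sm_c$bins$smoothed, rep(3.5, nrow(sm_c$bins)),
               tolerance = 1e-12)

  # a single spike spreads into a plateau of height h / (window/resolution)
  spike_frag <- which(fm$fragments$end - fm$fragments$start == 1)
  prof_s <- binned_profile(cts, fm)
  mid_bin <- 100
  prof_s$bins$combined[mid_bin] <- 50
  sm_s <- smooth_profile(prof_s, window = 5000)
  expect_equal(sm_s$bins$smoothed[mid_bin], 50 / 51, tolerance = 1e-9)
  expect_equal(sm_s$bins$smoothed[mid_bin + 25], 50 / 51, tolerance = 1e-9)
  expect_equal(sm_s$bins$smoothed[mid_bin + 26], 0, tolerance = 1e-12)

  # windowed-mean brute force, with masked bins excluded
  set.seed(73)
  prof_r <- binned_profile(rpois(nrow(fm$fragments), 2), fm,
                           masked = data.frame(start = 4000, end = 6000))
  sm_r <- smooth_profile(prof_r, window = 1000)
  x <- prof_r$bins$combined
  ok <- !prof_r$bins$masked
  brute <- vapply(seq_along(x), function(i) {
    w <- max(1, i - 5):min(length(x), i + 5)
    w <- w[ok[w]]
    if (length(w) == 0) NA_real_ else mean(x[w])
  }, 0)
  expect_equal(sm_r$bins$smoothed, brute, tolerance = 1e-9)

  expect_error(smooth_profile(prof_r, window = 50), "smaller than")
})
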