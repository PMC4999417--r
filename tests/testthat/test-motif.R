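# JASPAR parsing, PWM scanning and allele-specific disruption scores.

make_test_pwm <- function(pseudocount = 0.25) {
  counts <- rbind(A = c(0, 8, 0, 2, 1),
                  C = c(10, 0, 1, 2, 1),
                  G = c(0, 1, 9, 2, 1),
                  T = c(0, 1, 0, 4, 7))
  pwm(counts, id = "TEST1", name = "test_motif", pseudocount = pseudocount)
}

# independent per-window rescoring, character by character
brute_score <- function(seq, p, pos, strand) {
  win <- substr(seq, pos + 1, pos + p$length)
  if (strand == "-") {
    win <- paste(rev(strsplit(chartr("ACGT", "TGCA", win), "")[[1]]),
                 collapse = "")
  }
  b <- strsplit(win, "")[[1]]
  sum(vapply(seq_along(b), function(i) p$logodds[b[i], i], 0))
}

test_that("JASPAR matrices parse exactly and build valid PWMs", {
  path <- tempfile(fileext = ".pfm")
  writeLines(c(">TEST1 test_motif",
               "A [ 0 8 0 2 1 ]",
               "C [ 10 0 1 2 1 ]",
               "G [ 0 1 9 2 1 ]",
               "T [ 0 1 0 4 7 ]"), path)
  p <- load_jaspar(path)[[1]]
  expect_identical(p$counts, make_test_pwm()$counts)
  expect_identical(pwm_consensus(p), "CAGTT")
  expect_lt(max(abs(colSums(p$probs) - 1)), 1e-9)

  # a pure column with zero pseudocount gives probability 1
  p0 <- pwm(make_test_pwm()$counts, pseudocount = 0)
  expect_equal(unname(p0$probs[, 1]), c(0, 1, 0, 0))

  # uniform counts give all-zero log-odds
  pu <- pwm(matrix(5, 4, 4))
  expect_equal(max(abs(pu$logodds)), 0)

  writeLines(c(">BAD x", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 3 ]",
               "T [ 1 2 ]"), path)
  expect_error(load_jaspar(path), "ragged")
  writeLines(c(">BAD x", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), path)
  expect_error(load_jaspar(path), "missing base row")
})

test_that("fixture RELA matrix has the expected consensus", {
  fix <- get_fixture(42)
  p <- load_jaspar(file.path(fix$dir, "rela_motif.pfm"))[[1]]
  expect_identical(pwm_consensus(p), "GGGACTTTCC")
})

test_that("scanning agrees with brute-force window rescoring", {
  p <- make_test_pwm()
  set.seed(41)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  res <- scan_sequence(seq, p, threshold = -Inf)
  expect_identical(nrow(res$hits), 2L * (nchar(seq) - p$length + 1L))
  for (i in seq_len(nrow(res$hits))) {
    expect_equal(res$hits$score[i],
                 brute_score(seq, p, res$hits$position[i],
                             res$hits$strand[i]),
                 tolerance = 1e-12)
  }

  # the consensus scores the column-max sum at position 0
  cons <- pwm_consensus(p)
  best <- scan_sequence(cons, p)$best
  expect_identical(best$position, 0L)
  expect_equal(best$score, sum(apply(p$logodds, 2, max)), tolerance = 1e-12)

  # windows with N are skipped; too-short sequences are empty, not errors
  resN <- scan_sequence("NNNNN", p)
  expect_null(resN$best)
  expect_null(scan_sequence("ACG", p)$best)
})

test_that("best scores are strand-symmetric", {
  p <- make_test_pwm()
  set.seed(43)
  for (i in 1:50) {
    seq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
                collapse = "")
    expect_equal(scan_sequence(seq, p)$best$score,
                 scan_sequence(rc, p)$best$score, tolerance = 1e-12)
  }
})

test_that("pseudocount shrinks log-odds toward zero everywhere", {
  lo_small <- make_test_pwm(pseudocount = 0.1)$logodds
  lo_big <- make_test_pwm(pseudocount = 1)$logodds
  expect_true(all(abs(lo_big) <= abs(lo_small) + 1e-12))
})

test_that("allele delta isolates variant-covering windows", {
  fix <- get_fixture(42)
  p <- load_jaspar(file.path(fix$dir, "rela_motif.pfm"))[[1]]
  ctx <- "GAGGGGACTTTCCCTCCCCAAAC"

  # the enhancer-context risk allele weakens the RELA-like motif
  res <- allele_delta(ctx, 11, "C", "A", p)
  expect_gt(res$delta, 0)

  # no change, no delta
  expect_equal(allele_delta(ctx, 11, "C", "C", p)$delta, 0)

  # brute-force window enumeration over both alleles and strands
  brute_best <- function(allele) {
    s <- ctx
    substr(s, 12, 12) <- allele
    starts <- (11 - p$length + 1):11
    starts <- starts[starts >= 0 & starts <= nchar(s) - p$length]
    max(vapply(starts, function(st) {
      max(brute_score(s, p, st, "+"), brute_score(s, p, st, "-"))
    }, 0))
  }
  expect_equal(res$best_ref_score, brute_best("C"), tolerance = 1e-12)
  expect_equal(res$best_alt_score, brute_best("A"), tolerance = 1e-12)
  expect_equal(res$delta, brute_best("C") - brute_best("A"),
               tolerance = 1e-12)

  expect_error(allele_delta(ctx, 11, "G", "A", p), "mismatch")
})
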