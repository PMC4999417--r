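# Synthetic locus generator: LD structure, disease model, uncertainty,
# expression and 4C read simulation.

test_that("haplotype simulation hits target allele frequencies and r2", {
  # perfect LD with equal frequencies gives identical columns
  H <- simulate_haplotypes(c(0.4, 0.4), c(1, 1), 5000, seed = 7)
  expect_identical(H[, 1], H[, 2])

  # empirical r2 converges to the target (high-LD regime)
  H <- simulate_haplotypes(c(0.35, 0.35), c(1, 0.91), 1e5, seed = 11)
  hf <- r2_from_haplotypes(H[, 1], H[, 2])
  expect_lt(abs(hf$r2 - 0.91), 0.02)
  expect_lt(abs(mean(H[, 1]) - 0.35), 0.01)
  expect_lt(abs(mean(H[, 2]) - 0.35), 0.01)

  # counting oracle: r2 from the tabulated 2x2 haplotype counts
  n_AB <- sum(H[, 1] == 1 & H[, 2] == 1)
  n_Ab <- sum(H[, 1] == 1 & H[, 2] == 0)
  n_aB <- sum(H[, 1] == 0 & H[, 2] == 1)
  n_ab <- sum(H[, 1] == 0 & H[, 2] == 0)
  expect_equal(hf$r2, r2_from_counts_oracle(n_AB, n_Ab, n_aB, n_ab),
               tolerance = 1e-12)
})

test_that("infeasible r2 targets are rejected with the attainable maximum", {
  # pA = 0.5, pB = 0.05: r2max = min(pA qB, qA pB)^2/(pA qA pB qB) ~ 0.0526
  expect_error(simulate_haplotypes(c(0.5, 0.05), c(1, 0.5), 100, seed = 1),
               "maximum achievable r2 = 0.05", fixed = TRUE)
})

test_that("case-control simulation follows the logistic disease model", {
  H <- simulate_haplotypes(0.35, 1, 8000, seed = 3)

  # null odds ratio: case and control risk-allele frequencies agree
  cc0 <- simulate_case_control(H, 1, 1.0, 800, 800, seed = 5)
  raf <- function(cc, status) {
    mean(cc$table$dosages[cc$phenotype == status, 1]) / 2
  }
  expect_lt(abs(raf(cc0, 1) - raf(cc0, 0)), 0.03)

  # rare-disease closed form: case RAF ~ p*OR / (1 - p + p*OR)
  cc1 <- simulate_case_control(H, 1, 1.35, 2000, 2000,
                               baseline_risk = 0.001, seed = 6)
  p <- 0.35
  expected_case_raf <- p * 1.35 / (1 - p + p * 1.35)
  expect_lt(abs(raf(cc1, 1) - expected_case_raf), 0.02)
  # effect direction: risk allele enriched in cases for OR > 1
  expect_gt(raf(cc1, 1), raf(cc1, 0))

  # determinism and exact quotas
  cc2 <- simulate_case_control(H, 1, 1.35, 2000, 2000,
                               baseline_risk = 0.001, seed = 6)
  expect_identical(cc1$table$dosages, cc2$table$dosages)
  expect_identical(sum(cc1$phenotype), 2000L)
  expect_identical(length(cc1$phenotype), 4000L)
})

test_that("unreachable case quota errors with attained counts", {
  H <- simulate_haplotypes(0.35, 1, 100, seed = 3)
  expect_error(
    simulate_case_control(H, 1, 1.0, 5000, 10, baseline_risk = 0.001,
                          seed = 1, max_draw_factor = 0.01),
    "attained")
})

test_that("genotype uncertainty produces valid probability triples", {
  g <- matrix(sample(0:2, 200, replace = TRUE), ncol = 2)
  pr <- add_genotype_uncertainty(g, 0.9)
  sums <- pr[, , 1] + pr[, , 2] + pr[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-12)
  # certainty mass sits on the true genotype
  maxp <- apply(pr, c(1, 2), max)
  expect_equal(mean(maxp), 0.9, tolerance = 1e-12)
  # hard calls at certainty 1 give info score 1
  pr1 <- add_genotype_uncertainty(g, 1)
  expect_equal(impute_info_score(pr1[, 1, ])$info, 1.0)
  expect_error(add_genotype_uncertainty(g, 1 / 3), "certainty")
})

test_that("expression simulation recovers its generating slope", {
  dose <- stats::setNames(sample(0:2, 426, replace = TRUE,
                                 prob = c(0.42, 0.46, 0.12)),
                          sprintf("s%03d", 1:426))
  expr <- simulate_expression(dose, beta_per_allele = -0.5, noise_sd = 1,
                              n_samples = 426, seed = 9)
  fit <- stats::lm(expr$values[1, ] ~ dose)
  expect_lt(abs(unname(coef(fit)[2]) - (-0.5)), 0.15)
  expect_error(simulate_expression(dose, -0.5, noise_sd = 0,
                                   n_samples = 10, seed = 1),
               "noise_sd")
  # determinism
  expr2 <- simulate_expression(dose, beta_per_allele = -0.5, noise_sd = 1,
                               n_samples = 426, seed = 9)
  expect_identical(expr$values, expr2$values)
})

test_that("4C read simulation respects decay, enrichment and masking", {
  set.seed(21)
  seq <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
               collapse = "")
  fmap <- build_fragment_map(seq, chrom = "chrT")
  vp <- which.min(abs((fmap$fragments$start + fmap$fragments$end) / 2 -
                        30000))

  # pure decay: binned counts decrease away from the viewpoint
  reads <- simulate_4c_reads(fmap, vp, 40000, seed = 4, frac_low_mapq = 0)
  counts <- assign_reads(reads, fmap, viewpoint = NULL)
  prof <- smooth_profile(binned_profile(counts, fmap), window = 5000)
  mid <- (prof$bins$start + prof$bins$end) / 2
  vp_mid <- (fmap$fragments$start[vp] + fmap$fragments$end[vp]) / 2
  d <- abs(mid - vp_mid)
  near <- mean(prof$bins$smoothed[d > 2000 & d < 6000], na.rm = TRUE)
  far <- mean(prof$bins$smoothed[d > 20000], na.rm = TRUE)
  expect_gt(near, far)

  # enriched interval: smoothed max away from the viewpoint falls inside
  enr <- data.frame(start = 45000, end = 50000, fold = 5)
  reads_e <- simulate_4c_reads(fmap, vp, 40000, seed = 4,
                               enriched_intervals = enr, frac_low_mapq = 0)
  counts_e <- assign_reads(reads_e, fmap, viewpoint = NULL)
  prof_e <- smooth_profile(binned_profile(counts_e, fmap), window = 5000)
  away <- d > 10000 & !is.na(prof_e$bins$smoothed)
  best <- which(away)[which.max(prof_e$bins$smoothed[away])]
  expect_gte(prof_e$bins$start[best], 45000 - 2500)
  expect_lte(prof_e$bins$end[best], 50000 + 2500)

  # masked interval receives zero reads
  reads_m <- simulate_4c_reads(fmap, vp, 20000, seed = 4,
                               masked_interval = c(10000, 20000))
  fp <- ifelse(reads_m$strand == "+", reads_m$start, reads_m$end - 1)
  expect_identical(sum(fp >= 10000 & fp < 20000), 0L)
})

test_that("fixture file set is deterministic and matches its design", {
  fix <- get_fixture(42)
  dir2 <- file.path(tempdir(), "finelocus_fixture_rebuild")
  man2 <- write_fixture_locus(fix$design, dir2, overwrite = TRUE)
  md5 <- function(man) vapply(man$files, function(f) f$md5, "")
  expect_identical(md5(fix$manifest), md5(man2))

  # conservation lookups at the causal base
  phast <- read_bedgraph(file.path(fix$dir, "conservation",
                                   "phastcons.bedgraph"))
  gerp <- read_bedgraph(file.path(fix$dir, "conservation", "gerp.bedgraph"))
  pos0 <- fix$design$causal_pos - 1
  expect_equal(phast$value[phast$start <= pos0 & phast$end > pos0], 1.00)
  expect_equal(gerp$value[gerp$start <= pos0 & gerp$end > pos0], 4.81)

  # the enhancer context around the causal base carries the non-risk allele
  fa <- Biostrings::readDNAStringSet(file.path(fix$dir, "genome.fa"))
  ci <- fix$design$causal_pos - fix$design$locus_span[1] + 1
  expect_identical(substr(as.character(fa[[1]]), ci - 11, ci + 11),
                   "GAGGGGACTTTCCCTCCCCAAAC")

  # refusing to clobber an existing fixture
  expect_error(write_fixture_locus(fix$design, fix$dir), "overwrite")
})
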