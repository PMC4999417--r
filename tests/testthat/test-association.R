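# Trend test, logistic regression, info score, QC filter and conditional
# scan.

test_that("trend test matches textbook and score-test oracles", {
  # identical case/control distributions carry no trend
  flat <- cochran_armitage_trend(rbind(c(25, 50, 25), c(25, 50, 25)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  tab <- rbind(c(10, 40, 50), c(50, 40, 10))
  expect_equal(cochran_armitage_trend(tab)$chi2, trend_chi2_oracle(tab),
               tolerance = 1e-9)

  # equivalence with the logistic score statistic, on random tables
  set.seed(31)
  for (i in 1:20) {
    counts <- matrix(rpois(6, lambda = sample(10:80, 6, replace = TRUE)),
                     nrow = 2) + 1
    res <- cochran_armitage_trend(counts)
    x <- rep(c(0, 1, 2, 0, 1, 2), as.vector(t(counts)))
    y <- rep(c(1, 1, 1, 0, 0, 0), as.vector(t(counts)))
    expect_equal(res$chi2, score_chi2_oracle(x, y),
                 tolerance = 1e-6 * max(1, res$chi2))
    # invariance under swapping case/control labels
    expect_equal(res$chi2, cochran_armitage_trend(counts[2:1, ])$chi2,
                 tolerance = 1e-12)
    expect_gte(res$chi2, 0)
  }

  # monomorphic table is degenerate, not an error
  mono <- cochran_armitage_trend(rbind(c(30, 0, 0), c(60, 0, 0)))
  expect_true(mono$degenerate)
  expect_equal(mono$p, 1)
})

test_that("logistic regression maximises the Bernoulli likelihood", {
  # perfectly balanced 2x2 cells: beta is exactly 0 by symmetry
  x <- c(0, 0, 1, 1, 0, 0, 1, 1)
  y <- c(0, 1, 0, 1, 1, 0, 1, 0)
  fit <- logistic_fit(x, y)
  expect_equal(unname(fit$beta["dosage"]), 0, tolerance = 1e-10)

  # 20-observation fixture against a coarse-to-fine grid search
  set.seed(5)
  x <- rbinom(20, 2, 0.4)
  y <- rbinom(20, 1, plogis(-0.5 + 0.8 * x))
  fit <- logistic_fit(x, y)
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  # coarse-to-fine 2D grid search of the same likelihood
  c0 <- 0; c1 <- 0; h <- 4
  for (pass in 1:14) {
    g0 <- seq(c0 - h, c0 + h, length.out = 21)
    g1 <- seq(c1 - h, c1 + h, length.out = 21)
    ll <- outer(g0, g1, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    c0 <- g0[best[1]]; c1 <- g1[best[2]]
    h <- h / 4
  }
  expect_equal(unname(fit$beta["dosage"]), c1, tolerance = 1e-4)

  # intercept-only: fitted probability equals the case fraction
  fit0 <- logistic_fit(NULL, y)
  expect_equal(plogis(unname(fit0$beta["(Intercept)"])), mean(y),
               tolerance = 1e-9)

  # complete separation is flagged, not silently reported
  xs <- c(rep(0, 10), rep(2, 10))
  ys <- c(rep(0, 10), rep(1, 10))
  expect_false(logistic_fit(xs, ys)$converged)
})

test_that("info score follows the ratio-of-variances definition", {
  hard <- matrix(0, nrow = 50, ncol = 3)
  hard[cbind(1:50, sample(1:3, 50, replace = TRUE))] <- 1
  expect_equal(impute_info_score(hard)$info, 1.0)

  # HWE-prior triples carry no information: unclamped value is exactly 0
  prior <- matrix(rep(c(0.25, 0.5, 0.25), each = 100), ncol = 3)
  expect_equal(impute_info_score(prior)$info, 0)

  # info decreases as certainty drops, staying inside (0, 1) until the
  # uncertainty is extreme enough to clamp at 0
  g <- matrix(sample(0:2, 500, replace = TRUE, prob = c(.4, .45, .15)))
  infos <- vapply(c(1, 0.95, 0.9, 0.85, 0.8), function(cert) {
    impute_info_score(add_genotype_uncertainty(g, cert)[, 1, ])$info
  }, 0)
  expect_true(all(diff(infos) < 0))
  expect_true(all(infos[-1] > 0 & infos[-1] < 1))
  expect_equal(impute_info_score(add_genotype_uncertainty(g, 0.4)[, 1, ])$info,
               0)
  expect_error(impute_info_score(matrix(c(0.5, 0.2, 0.2), 1)), "sum to 1")
})

test_that("variant filter applies the documented strict thresholds", {
  res <- data.frame(variant_id = c("a", "b", "c", "d"),
                    maf = c(0.01, 0.30, 0.30, 0.30),
                    info = c(0.99, 0.79, 0.80, 0.99),
                    p_trend = c(1e-9, 1e-9, 1e-9, 5e-7))
  kept <- filter_variants(res)
  # maf must exceed 0.01; info 0.80 is retained; p must be below 5e-7
  expect_identical(kept$variant_id, "c")
  # identity thresholds pass everything through, order preserved
  all_through <- filter_variants(res, maf_min = 0, info_min = 0, p_max = Inf)
  expect_identical(all_through$variant_id, res$variant_id)
})

test_that("association scan recovers the generating odds ratio", {
  cc <- small_cohort(seed = 17, or = 1.6, n_cases = 600, n_controls = 1200)
  res <- associate_variants(cc$table, cc$phenotype)
  expect_s3_class(res, "association_result")
  expect_equal(res$or_, exp(res$beta), tolerance = 1e-12)
  causal <- res[1, ]
  expect_lt(abs(causal$or_ - 1.6), 0.25)
  expect_true(all(res$maf <= 0.5))
  expect_true(all(res$p_trend > 0 & res$p_trend <= 1))
  # trend and Wald p agree within an order of magnitude when well-powered
  expect_lt(abs(log10(causal$p_trend) - log10(causal$p_wald)), 1)
})

test_that("conditional scan excludes collinear copies and absorbs the signal", {
  cc <- small_cohort(seed = 23, or = 1.8, n_cases = 500, n_controls = 1000,
                     proxy_r2 = c(0.9, 0.3))
  tab <- cc$table
  # append an exact copy of the lead
  v2 <- rbind(tab$variants,
              data.frame(id = "copy", chrom = "chr15",
                         pos = max(tab$variants$pos) + 1000,
                         ref = "C", alt = "A"))
  tab2 <- genotype_table(v2, cbind(tab$dosages, tab$dosages[, 1]),
                         tab$sample_ids)
  cond <- conditional_scan(tab2, cc$phenotype, "snp_001")
  expect_true(cond$collinear[cond$variant_id == "copy"])
  expect_true(is.na(cond$p_conditional[cond$variant_id == "copy"]))
  expect_false(any(cond$collinear[cond$variant_id != "copy"]))
  expect_error(conditional_scan(tab2, cc$phenotype, "absent"), "not found")
})
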