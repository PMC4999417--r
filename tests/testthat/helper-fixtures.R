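# Shared fixtures, built once per test run and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

# The full synthetic locus at its default design (written to tempdir).
get_fixture <- function(seed = 42) {
  key <- paste0("fix_", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("finelocus_fixture_", seed))
    design <- locus_design(seed = seed)
    manifest <- write_fixture_locus(design, dir, overwrite = TRUE)
    .fixture_cache[[key]] <- list(dir = dir, design = design,
                                  manifest = manifest)
  }
  .fixture_cache[[key]]
}

# A small case-control cohort over causal + proxies, cheap enough for
# repeated use in unit tests.
small_cohort <- function(seed = 1, or = 1.35, n_cases = 400,
                         n_controls = 800, proxy_r2 = c(0.95, 0.5)) {
  H <- simulate_haplotypes(rep(0.35, 1 + length(proxy_r2)),
                           c(1, proxy_r2), n_haplotypes = 8000, seed = seed)
  simulate_case_control(H, 1, or, n_cases, n_controls, seed = seed + 100)
}

# Independent brute-force trend chi-square: direct textbook summation,
# written without reference to the package implementation.
trend_chi2_oracle <- function(counts) {
  r <- counts[1, ]; n <- colSums(counts)
  R <- sum(r); N <- sum(n)
  w <- 0:2
  pbar <- R / N
  U <- sum(w * (r - pbar * n))
  V <- pbar * (1 - pbar) * (sum(w^2 * n) - sum(w * n)^2 / N)
  U^2 / V
}

# Logistic score-test statistic under the intercept-only null.
score_chi2_oracle <- function(x, y) {
  ybar <- mean(y)
  U <- sum(x * (y - ybar))
  V <- ybar * (1 - ybar) * sum((x - mean(x))^2)
  U^2 / V
}

# r2 computed straight from a 2x2 haplotype count table.
r2_from_counts_oracle <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  fAB <- n_AB / n
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  D <- fAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}
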