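# Synthetic replica of a fine-mapped disease risk locus: every input the
# pipeline consumes, generated with the statistical structure the analyses
# assume (single causal SNP with high-LD proxies, imputation uncertainty,
# enhancer/conservation/motif context, 4C distance-decay reads, and an
# allelic dose effect on one gene's expression).

# The 23-bp enhancer context planted around the causal SNP, non-risk (C)
# allele at the centre; the RELA-like motif occupies offsets 3..12.
CAUSAL_CONTEXT <- "GAGGGGACTTTCCCTCCCCAAAC"
CAUSAL_CONTEXT_OFFSET <- 11L  # 0-based offset of the variant base

#' Design of the synthetic locus
#'
#' Bundles every knob of the synthetic locus replica. Defaults mirror the
#' modelled study: a ~153-kb interval on chr15, a causal SNP with
#' risk-allele frequency 0.35 and per-allele odds ratio 1.35, three proxies
#' in high LD with it, 1,920 cases and 5,199 controls (the two combined
#' GWAS scans), and 426 expression samples.
#'
#' @param locus_span 1-based inclusive interval `c(start, end)`.
#' @param chrom Chromosome name.
#' @param causal_pos 1-based position of the causal SNP.
#' @param causal_raf Risk (alt) allele frequency in the population.
#' @param causal_or Per-allele odds ratio of the causal SNP.
#' @param n_proxy_high Number of high-LD proxies.
#' @param proxy_r2 Target `r2` of each proxy with the causal SNP.
#' @param n_background Number of null background SNPs.
#' @param n_cases,n_controls Case/control quotas.
#' @param baseline_risk Disease probability for dose 0 (rare-disease
#'   regime; keeps the per-allele odds ratio close to the sampling
#'   enrichment).
#' @param genotype_certainty Probability mass placed on the true genotype
#'   when imputation-style uncertainty is added.
#' @param n_low_info Number of background SNPs written with poor
#'   imputation certainty (0.45), to exercise the info-score filter.
#' @param n_expr_samples Expression cohort size (cases only).
#' @param expr_beta Expression change per risk allele for the target gene
#'   (negative: risk allele lowers expression).
#' @param expr_noise_sd Residual SD of expression values.
#' @param n_null_genes Null genes in the cis window.
#' @param n_reads_4c Total simulated 4C reads.
#' @param decay_exponent Distance-decay exponent of 4C contact frequency.
#' @param enrich_fold Fold-enrichment of the distal contact interval.
#' @param seed Integer seed; identical designs give byte-identical output.
#' @return Object of class `locus_design`.
#' @export
locus_design <- function(locus_span = c(40379030, 40532514),
                         chrom = "chr15",
                         causal_pos = 40450000,
                         causal_raf = 0.35,
                         causal_or = 1.35,
                         n_proxy_high = 3,
                         proxy_r2 = c(0.98, 0.95, 0.91),
                         n_background = 20,
                         n_cases = 1920,
                         n_controls = 5199,
                         baseline_risk = 0.001,
                         genotype_certainty = 0.98,
                         n_low_info = 2,
                         n_expr_samples = 426,
                         expr_beta = -0.3,
                         expr_noise_sd = 1,
                         n_null_genes = 9,
                         n_reads_4c = 50000,
                         decay_exponent = 1,
                         enrich_fold = 5,
                         seed = 42) {
  assert_that(is_fraction(causal_raf), "causal_raf must be in (0,1)")
  assert_that(causal_or > 0, "causal_or must be positive")
  assert_that(is_count(n_cases) && is_count(n_controls),
              "sample counts must be positive integers")
  assert_that(length(proxy_r2) == n_proxy_high,
              "proxy_r2 must have one entry per proxy")
  assert_that(all(proxy_r2 > 0 & proxy_r2 < 1), "proxy_r2 must be in (0,1)")
  assert_that(locus_span[1] < locus_span[2], "locus_span must be increasing")
  assert_that(causal_pos > locus_span[1] && causal_pos < locus_span[2],
              "causal_pos must lie inside the locus span")
  assert_that(is_fraction(baseline_risk), "baseline_risk must be in (0,1)")
  assert_that(genotype_certainty > 1 / 3 && genotype_certainty <= 1,
              "genotype_certainty must be in (1/3, 1]")
  structure(as.list(environment()), class = "locus_design")
}

#' @export
print.locus_design <- function(x, ...) {
  cat(sprintf(
    "locus_design: %s:%d-%d, causal @%d (RAF %.2f, OR %.2f), %d proxies, %d background\n",
    x$chrom, x$locus_span[1], x$locus_span[2], x$causal_pos, x$causal_raf,
    x$causal_or, x$n_proxy_high, x$n_background))
  cat(sprintf("  %d cases / %d controls, seed %d\n", x$n_cases, x$n_controls,
              x$seed))
  invisible(x)
}

# Solve two-locus haplotype frequencies for allele frequencies pA, pB and a
# target r2, taking the positive root of D. Errors when the target exceeds
# the maximum achievable r2 for this frequency pair.
solve_two_locus_freqs <- function(pA, pB, r2) {
  qA <- 1 - pA; qB <- 1 - pB
  if (r2 == 0) {
    return(c(pA * pB, pA * qB, qA * pB, qA * qB))
  }
  d_max <- min(pA * qB, qA * pB)
  r2_max <- d_max^2 / (pA * qA * pB * qB)
  if (r2 > r2_max + 1e-9) {
    stopf("target r2 = %.4f infeasible for frequencies (%.3f, %.3f); maximum achievable r2 = %.4f",
          r2, pA, pB, r2_max)
  }
  D <- sqrt(min(r2, r2_max) * pA * qA * pB * qB)
  c(pA * pB + D, pA * qB - D, qA * pB - D, qA * qB + D)
}

#' Simulate haplotypes with target pairwise LD against a causal SNP
#'
#' Draws binary haplotypes for a set of SNPs such that each column's allele
#' frequency converges to `raf_per_snp` and each non-causal column's `r2`
#' with the causal column converges to `target_r2`. Two-locus haplotype
#' frequencies are solved analytically (positive D); non-causal columns are
#' conditionally independent given the causal allele, so proxies correlate
#' with each other only through the causal SNP.
#'
#' @param raf_per_snp Allele frequencies, one per SNP, each in (0,1).
#' @param target_r2 Target `r2` of each SNP with the causal column; the
#'   entry at `causal_index` is ignored.
#' @param n_haplotypes Number of haplotypes to draw.
#' @param seed Integer seed.
#' @param causal_index Column index of the causal SNP (default 1).
#' @return 0/1 matrix, `n_haplotypes` x SNPs.
#' @export
simulate_haplotypes <- function(raf_per_snp, target_r2, n_haplotypes, seed,
                                causal_index = 1L) {
  m <- length(raf_per_snp)
  assert_that(length(target_r2) == m, "target_r2 must match raf_per_snp")
  assert_that(all(raf_per_snp > 0 & raf_per_snp < 1),
              "allele frequencies must be in (0,1)")
  assert_that(is_count(n_haplotypes), "n_haplotypes must be a positive count")
  # feasibility checked up front so the error precedes any drawing
  freqs <- vector("list", m)
  pC <- raf_per_snp[causal_index]
  for (j in seq_len(m)) {
    if (j == causal_index) next
    freqs[[j]] <- solve_two_locus_freqs(pC, raf_per_snp[j], target_r2[j])
  }
  with_seed(seed, {
    H <- matrix(0L, nrow = n_haplotypes, ncol = m)
    causal <- stats::rbinom(n_haplotypes, 1, pC)
    H[, causal_index] <- causal
    on_risk <- causal == 1L
    for (j in seq_len(m)) {
      if (j == causal_index) next
      f <- freqs[[j]]
      pB_given_A <- f[1] / pC          # P(B=1 | causal allele)
      pB_given_a <- f[3] / (1 - pC)    # P(B=1 | other allele)
      col <- integer(n_haplotypes)
      col[on_risk] <- stats::rbinom(sum(on_risk), 1, pB_given_A)
      col[!on_risk] <- stats::rbinom(sum(!on_risk), 1, pB_given_a)
      H[, j] <- col
    }
    H
  })
}

#' Simulate a case-control cohort from a haplotype pool
#'
#' Forms diploid genotypes by random pairing (with replacement) from the
#' haplotype pool and assigns disease by the logistic model
#' `logit P(case) = logit(baseline_risk) + log(or_per_allele) * dose`,
#' where dose counts the risk allele at the causal column. Sampling batches
#' repeat until both quotas are met exactly; an unreachable quota within
#' the draw cap raises an error reporting the attained counts. With a small
#' `baseline_risk` (rare-disease regime) the per-allele odds ratio matches
#' the case-enrichment closed forms used in the tests.
#'
#' @param haplotypes 0/1 matrix from [simulate_haplotypes()].
#' @param causal_column Column holding the causal SNP.
#' @param or_per_allele Per-allele odds ratio.
#' @param n_cases,n_controls Exact quotas.
#' @param baseline_risk Disease probability at dose 0 (default 0.001).
#' @param seed Integer seed.
#' @param variants Optional variant metadata (`id`, `chrom`, `pos`, `ref`,
#'   `alt`); autogenerated when NULL.
#' @param max_draw_factor Cap on total individuals drawn, as a multiple of
#'   the expected number needed (default 10).
#' @return List: `table` (a [genotype_table()] of hard-called doses, cases
#'   first), `phenotype` (named 0/1 vector), `n_drawn`.
#' @export
simulate_case_control <- function(haplotypes, causal_column, or_per_allele,
                                  n_cases, n_controls,
                                  baseline_risk = 0.001, seed,
                                  variants = NULL, max_draw_factor = 10) {
  H <- haplotypes
  nh <- nrow(H)
  assert_that(nh >= 2, "need at least two haplotypes")
  assert_that(causal_column >= 1 && causal_column <= ncol(H),
              "causal_column out of range")
  pC <- mean(H[, causal_column])
  b0 <- stats::qlogis(baseline_risk)
  lor <- log(or_per_allele)
  p_case_by_dose <- stats::plogis(b0 + lor * (0:2))
  dose_probs <- c((1 - pC)^2, 2 * pC * (1 - pC), pC^2)
  p_case <- sum(dose_probs * p_case_by_dose)
  expected_need <- n_cases / p_case + n_controls / (1 - p_case)
  cap <- ceiling(max_draw_factor * expected_need)
  batch <- ceiling(expected_need * 1.25)
  with_seed(seed, {
    case_idx1 <- integer(0); case_idx2 <- integer(0)
    ctrl_idx1 <- integer(0); ctrl_idx2 <- integer(0)
    drawn <- 0L
    while ((length(case_idx1) < n_cases || length(ctrl_idx1) < n_controls) &&
           drawn < cap) {
      nb <- min(batch, cap - drawn)
      i1 <- sample.int(nh, nb, replace = TRUE)
      i2 <- sample.int(nh, nb, replace = TRUE)
      dose <- H[i1, causal_column] + H[i2, causal_column]
      y <- stats::rbinom(nb, 1, p_case_by_dose[dose + 1L])
      drawn <- drawn + nb
      need_ca <- n_cases - length(case_idx1)
      if (need_ca > 0) {
        ca <- which(y == 1L)[seq_len(min(need_ca, sum(y)))]
        case_idx1 <- c(case_idx1, i1[ca]); case_idx2 <- c(case_idx2, i2[ca])
      }
      need_co <- n_controls - length(ctrl_idx1)
      if (need_co > 0) {
        co <- which(y == 0L)[seq_len(min(need_co, sum(1 - y)))]
        ctrl_idx1 <- c(ctrl_idx1, i1[co]); ctrl_idx2 <- c(ctrl_idx2, i2[co])
      }
    }
    if (length(case_idx1) < n_cases || length(ctrl_idx1) < n_controls) {
      stopf("case/control quotas unreachable within the draw cap: attained %d/%d cases, %d/%d controls",
            length(case_idx1), n_cases, length(ctrl_idx1), n_controls)
    }
    i1 <- c(case_idx1, ctrl_idx1)
    i2 <- c(case_idx2, ctrl_idx2)
    dosages <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
    sample_ids <- c(sprintf("case_%05d", seq_len(n_cases)),
                    sprintf("ctrl_%05d", seq_len(n_controls)))
    phenotype <- stats::setNames(rep(c(1L, 0L), c(n_cases, n_controls)),
                                 sample_ids)
    if (is.null(variants)) {
      m <- ncol(H)
      pos <- round(seq(40379030 + 1000, 40532514 - 1000, length.out = m))
      variants <- data.frame(id = sprintf("snp_%03d", seq_len(m)),
                             chrom = "chr15", pos = pos,
                             ref = "C", alt = "A",
                             stringsAsFactors = FALSE)
    }
    list(table = genotype_table(variants, dosages, sample_ids),
         phenotype = phenotype, n_drawn = drawn)
  })
}

#' Add imputation-style genotype uncertainty
#'
#' Replaces hard genotype calls with probability triples placing
#' `certainty` on the true genotype and splitting the remainder equally
#' between the other two classes. `certainty = 1` reproduces hard calls;
#' values at or below 1/3 are rejected (the true genotype would no longer
#' be the mode).
#'
#' @param genotypes Matrix of integer doses (0/1/2), samples x variants.
#' @param certainty Per-variant certainty; a scalar is recycled.
#' @return `samples x variants x 3` array of `(p_AA, p_AB, p_BB)` triples.
#' @export
add_genotype_uncertainty <- function(genotypes, certainty) {
  g <- as.matrix(genotypes)
  assert_that(all(g %in% 0:2), "genotypes must be hard 0/1/2 calls")
  certainty <- rep(certainty, length.out = ncol(g))
  assert_that(all(certainty > 1 / 3 & certainty <= 1),
              "certainty must be in (1/3, 1]")
  ns <- nrow(g); nv <- ncol(g)
  probs <- array(0, dim = c(ns, nv, 3))
  for (j in seq_len(nv)) {
    cj <- certainty[j]
    off <- (1 - cj) / 2
    pj <- matrix(off, nrow = ns, ncol = 3)
    pj[cbind(seq_len(ns), g[, j] + 1L)] <- cj
    probs[, j, ] <- pj
  }
  probs
}

#' Simulate an expression matrix with one dose-responsive gene
#'
#' The target gene's expression is `intercept + beta * dose + noise`; null
#' genes are intercept plus noise only. Gene TSS coordinates are placed
#' inside the cis window around `center_pos` so the eQTL scan covers them.
#'
#' @param genotypes Named dose vector (names = sample ids).
#' @param beta_per_allele Slope for the target gene; negative means the
#'   risk allele lowers expression.
#' @param noise_sd Residual standard deviation (> 0).
#' @param n_samples Number of samples used (first `n_samples` entries).
#' @param seed Integer seed.
#' @param target_gene Target gene id (default "BMF").
#' @param n_null_genes Number of null genes.
#' @param chrom Chromosome name.
#' @param center_pos SNP position the cis window is anchored on.
#' @param intercept Baseline expression level (default 8, log2-array scale).
#' @return An [expression_matrix()]; the target gene is the first row.
#' @export
simulate_expression <- function(genotypes, beta_per_allele, noise_sd,
                                n_samples, seed, target_gene = "BMF",
                                n_null_genes = 9, chrom = "chr15",
                                center_pos = 40450000, intercept = 8) {
  assert_that(noise_sd > 0, "noise_sd must be positive")
  assert_that(!is.null(names(genotypes)), "genotypes must be a named vector")
  assert_that(n_samples <= length(genotypes),
              "n_samples exceeds available genotypes")
  dose <- genotypes[seq_len(n_samples)]
  with_seed(seed, {
    tss <- c(center_pos - 15000,
             round(center_pos + stats::runif(n_null_genes, -450000, 450000)))
    genes <- data.frame(
      id = c(target_gene, sprintf("null_gene_%02d", seq_len(n_null_genes))),
      chrom = chrom, tss = tss, stringsAsFactors = FALSE)
    vals <- matrix(intercept + stats::rnorm((n_null_genes + 1) * n_samples,
                                            sd = noise_sd),
                   nrow = n_null_genes + 1)
    vals[1, ] <- vals[1, ] + beta_per_allele * dose
    expression_matrix(genes, vals, names(dose))
  })
}

#' Simulate mapped 4C-seq reads over a fragment map
#'
#' Per-fragment expected read counts follow a distance-decay law,
#' `(distance of fragment midpoint to the viewpoint)^-decay_exponent`,
#' multiplied by the fold-enrichment of any enriched interval containing
#' the midpoint. The viewpoint fragment itself and fragments inside the
#' masked interval get zero weight. Read 5' ends are placed near fragment
#' boundaries (uniform within 75 bp of either end), mimicking
#' restriction-site-anchored 4C reads while keeping 5' positions mostly
#' distinct.
#'
#' @param fmap A [build_fragment_map()].
#' @param viewpoint_fragment Index of the viewpoint fragment.
#' @param n_reads Total reads to draw.
#' @param seed Integer seed.
#' @param decay_exponent Positive decay exponent (default 1).
#' @param enriched_intervals Optional data frame `start`, `end`, `fold`
#'   (0-based half-open).
#' @param masked_interval Optional `c(start, end)` interval receiving no
#'   reads.
#' @param read_length Reported read length (default 50).
#' @param frac_low_mapq Fraction of reads emitted with mapping quality 10
#'   (below the default filter), the rest mapq 60.
#' @return BED6 data frame: `chrom`, `start`, `end`, `name`,
#'   `score` (mapping quality), `strand`.
#' @export
simulate_4c_reads <- function(fmap, viewpoint_fragment, n_reads, seed,
                              decay_exponent = 1, enriched_intervals = NULL,
                              masked_interval = NULL, read_length = 50,
                              frac_low_mapq = 0.02) {
  stopifnot(inherits(fmap, "fragment_map"))
  frags <- fmap$fragments
  assert_that(nrow(frags) >= 2, "fragment map is empty or trivial")
  assert_that(decay_exponent > 0, "decay_exponent must be positive")
  assert_that(viewpoint_fragment >= 1 && viewpoint_fragment <= nrow(frags),
              "viewpoint fragment outside the fragment map")
  mid <- (frags$start + frags$end) / 2
  vp <- mid[viewpoint_fragment]
  w <- pmax(abs(mid - vp), 1)^(-decay_exponent)
  w[viewpoint_fragment] <- 0
  if (!is.null(enriched_intervals) && nrow(enriched_intervals)) {
    for (i in seq_len(nrow(enriched_intervals))) {
      inside <- mid >= enriched_intervals$start[i] &
        mid < enriched_intervals$end[i]
      w[inside] <- w[inside] * enriched_intervals$fold[i]
    }
  }
  if (!is.null(masked_interval)) {
    w[mid >= masked_interval[1] & mid < masked_interval[2]] <- 0
  }
  assert_that(sum(w) > 0, "all fragment weights are zero")
  with_seed(seed, {
    fi <- sample.int(nrow(frags), n_reads, replace = TRUE, prob = w)
    len <- frags$end[fi] - frags$start[fi]
    jit_w <- pmin(75, pmax(1, floor(len / 2)))
    left_end <- stats::runif(n_reads) < 0.5
    off <- floor(stats::runif(n_reads) * jit_w)
    fp <- ifelse(left_end, frags$start[fi] + off, frags$end[fi] - 1 - off)
    strand <- ifelse(left_end, "+", "-")
    start <- ifelse(left_end, fp, pmax(fp + 1 - read_length, frags$start[fi]))
    end <- ifelse(left_end, pmin(fp + read_length, frags$end[fi]), fp + 1)
    mapq <- ifelse(stats::runif(n_reads) < frac_low_mapq, 10, 60)
    bed <- data.frame(chrom = frags$chrom[1], start = start, end = end,
                      name = sprintf("read_%06d", seq_len(n_reads)),
                      score = mapq, strand = strand,
                      stringsAsFactors = FALSE)
    if (!is.null(masked_interval)) {
      fp_emit <- ifelse(strand == "+", bed$start, bed$end - 1)
      bed <- bed[!(fp_emit >= masked_interval[1] &
                     fp_emit < masked_interval[2]), , drop = FALSE]
    }
    rownames(bed) <- NULL
    bed
  })
}

# Random locus sequence with the causal-context 23-mer planted around the
# causal position (non-risk allele).
synth_locus_sequence <- function(design, variants = NULL) {
  len <- design$locus_span[2] - design$locus_span[1] + 1
  seq <- paste(sample(BASES, len, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  # every variant's reference base must be present in the genome
  if (!is.null(variants)) {
    for (i in seq_len(nrow(variants))) {
      vi <- variants$pos[i] - design$locus_span[1] + 1
      substr(seq, vi, vi) <- variants$ref[i]
    }
  }
  # 1-based index of the causal base within the sequence
  ci <- design$causal_pos - design$locus_span[1] + 1
  ctx_start <- ci - CAUSAL_CONTEXT_OFFSET
  substr(seq, ctx_start, ctx_start + nchar(CAUSAL_CONTEXT) - 1) <-
    CAUSAL_CONTEXT
  seq
}

# The RELA-like PFM whose consensus is GGGACTTTCC (risk base alters
# position 9 from C to A).
rela_like_pfm <- function() {
  counts <- rbind(
    A = c(1, 0, 0, 16, 2, 1, 2, 1, 0, 2),
    C = c(1, 0, 1, 1, 15, 2, 1, 2, 18, 14),
    G = c(17, 20, 18, 2, 1, 1, 2, 2, 1, 2),
    T = c(1, 0, 1, 1, 2, 16, 15, 15, 1, 2)
  )
  pwm(counts, id = "MSYN0001", name = "RELA_synthetic")
}

non_overlapping_background <- function(design, n, width, avoid,
                                       value_range) {
  # deterministic because callers run inside with_seed; candidate starts
  # are spaced > width apart so the sampled intervals cannot overlap
  span <- design$locus_span
  starts <- sort(sample(seq(span[1], span[2] - width - 1, by = 2 * width), n))
  iv <- data.frame(chrom = design$chrom, start = starts,
                   end = starts + width,
                   value = round(stats::runif(n, value_range[1],
                                              value_range[2]), 3))
  # drop any interval touching the avoided interval
  iv[iv$end <= avoid[1] | iv$start >= avoid[2], , drop = FALSE]
}

#' Write the complete synthetic locus fixture
#'
#' Generates and writes every pipeline input for a [locus_design()]:
#' genotypes with imputation-style probabilities, phenotypes, enhancer-mark
#' and super-enhancer/contact-domain BED tracks, phastCons and GERP
#' conservation bedGraphs (1.00 over the 10-bp motif and 4.81 at the causal
#' base), the locus FASTA carrying the enhancer context with the non-risk
#' allele, a JASPAR-format RELA-like PFM, simulated 4C reads, an expression
#' matrix, a ready-to-run pipeline config and a checksum manifest.
#' Identical designs produce byte-identical file sets.
#'
#' @param design A [locus_design()].
#' @param outdir Output directory; an existing non-empty directory is an
#'   error unless `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the manifest (paths, checksums and the
#'   generating truth: causal/proxy ids, viewpoint, enriched interval).
#' @export
write_fixture_locus <- function(design, outdir, overwrite = FALSE) {
  stopifnot(inherits(design, "locus_design"))
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !overwrite) {
    stopf("output directory %s exists and is not empty (use overwrite = TRUE)",
          outdir)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(outdir, "conservation"), showWarnings = FALSE)
  d <- design
  span <- d$locus_span

  # --- genotypes ----------------------------------------------------------
  # variant placement: causal + proxies at fixed offsets, background spread
  proxy_pos <- round(d$causal_pos +
                       c(-21000, -5000, 18000))[seq_len(d$n_proxy_high)]
  bg_pos <- round(seq(span[1] + 2000, span[2] - 2000,
                      length.out = d$n_background))
  bg_pos <- setdiff(bg_pos, c(d$causal_pos, proxy_pos))
  pos <- c(d$causal_pos, proxy_pos, bg_pos)
  ids <- c("sim_causal", sprintf("sim_proxy_%d", seq_len(d$n_proxy_high)),
           sprintf("sim_bg_%02d", seq_along(bg_pos)))
  bg_rafs <- with_seed(d$seed + 1L,
                       round(stats::runif(length(bg_pos), 0.05, 0.45), 3))
  raf <- c(d$causal_raf, rep(d$causal_raf, d$n_proxy_high), bg_rafs)
  r2t <- c(1, d$proxy_r2, rep(0, length(bg_pos)))
  ord <- order(pos)
  variants <- data.frame(id = ids[ord], chrom = d$chrom, pos = pos[ord],
                         ref = "C", alt = "A", stringsAsFactors = FALSE)
  causal_col <- match("sim_causal", variants$id)
  raf <- raf[ord]
  r2t <- r2t[ord]
  m <- length(pos)
  H <- simulate_haplotypes(raf, r2t, n_haplotypes = 20000,
                           seed = d$seed + 2L, causal_index = causal_col)
  cc <- simulate_case_control(H, causal_col, d$causal_or, d$n_cases,
                              d$n_controls, d$baseline_risk,
                              seed = d$seed + 3L, variants = variants)
  certainty <- rep(d$genotype_certainty, m)
  if (d$n_low_info > 0) {
    low <- which(grepl("^sim_bg", variants$id))[seq_len(d$n_low_info)]
    certainty[low] <- 0.45
  }
  probs <- add_genotype_uncertainty(cc$table$dosages, certainty)
  table <- genotype_table(variants, probs[, , 2] + 2 * probs[, , 3],
                          cc$table$sample_ids, probabilities = probs)
  write_genotype_table(table, file.path(outdir, "genotypes.tsv"),
                       prob_path = file.path(outdir, "genotype_probs.tsv"))
  write_phenotypes(cc$phenotype, file.path(outdir, "phenotypes.tsv"))

  # --- interval tracks ----------------------------------------------------
  se <- c(40400000, 40480000)        # ~80-kb super-enhancer over the locus
  cd <- c(40390000, 40520000)        # chromatin contact domain
  c0 <- d$causal_pos - 1             # causal base, 0-based
  with_seed(d$seed + 4L, {
    # active-enhancer marks over the causal SNP in all three channels;
    # proxies get DNase only, so only the causal variant is "active"
    proxy_iv <- data.frame(chrom = d$chrom, start = proxy_pos - 200,
                           end = proxy_pos + 200)
    dnase <- rbind(
      data.frame(chrom = d$chrom, start = c0 - 400, end = c0 + 400),
      proxy_iv)
    mark_bg <- function(n) {
      s <- sort(sample(seq(span[1], span[2] - 1200, by = 500), n))
      data.frame(chrom = d$chrom, start = s, end = s + 1000)
    }
    add_name <- function(df, nm) { df$name <- nm; df }
    write_bed(add_name(dnase[order(dnase$start), ], "dnase"),
              file.path(outdir, "tracks", "dnase.bed"))
    write_bed(add_name(data.frame(chrom = d$chrom, start = c0 - 1500,
                                  end = c0 + 1500), "h3k4me1"),
              file.path(outdir, "tracks", "h3k4me1.bed"))
    write_bed(add_name(data.frame(chrom = d$chrom, start = c0 - 2000,
                                  end = c0 + 2000), "h3k27ac"),
              file.path(outdir, "tracks", "h3k27ac.bed"))
    write_bed(add_name(mark_bg(3), "h3k4me3"),
              file.path(outdir, "tracks", "h3k4me3.bed"))
    write_bed(data.frame(chrom = d$chrom, start = se[1], end = se[2],
                         name = "super_enhancer"),
              file.path(outdir, "tracks", "super_enhancer.bed"))
    write_bed(data.frame(chrom = d$chrom, start = cd[1], end = cd[2],
                         name = "contact_domain"),
              file.path(outdir, "tracks", "contact_domain.bed"))

    # conservation: phastCons 1.00 over the 10-bp motif, GERP 4.81 at the
    # causal base, low scattered background elsewhere
    motif_iv <- c(c0 - 8, c0 + 2)  # 0-based half-open, motif pos 1..10
    phast_bg <- non_overlapping_background(d, 15, 300, motif_iv,
                                           c(0.02, 0.4))
    phast <- rbind(data.frame(chrom = d$chrom, start = motif_iv[1],
                              end = motif_iv[2], value = 1.00), phast_bg)
    write_bedgraph(phast[order(phast$start), ],
                   file.path(outdir, "conservation", "phastcons.bedgraph"))
    gerp_bg <- non_overlapping_background(d, 15, 300, c(c0, c0 + 1),
                                          c(-1, 1))
    gerp <- rbind(data.frame(chrom = d$chrom, start = c0, end = c0 + 1,
                             value = 4.81), gerp_bg)
    write_bedgraph(gerp[order(gerp$start), ],
                   file.path(outdir, "conservation", "gerp.bedgraph"))
  })

  # --- genome FASTA -------------------------------------------------------
  seq <- with_seed(d$seed + 5L, synth_locus_sequence(d, variants))
  fa <- Biostrings::DNAStringSet(seq)
  names(fa) <- d$chrom
  Biostrings::writeXStringSet(fa, file.path(outdir, "genome.fa"), width = 80)

  # --- motif PFM ----------------------------------------------------------
  write_jaspar(rela_like_pfm(), file.path(outdir, "rela_motif.pfm"))

  # --- 4C reads -----------------------------------------------------------
  offset <- span[1] - 1
  fmap <- build_fragment_map(file.path(outdir, "genome.fa"),
                             chrom = d$chrom, offset = offset)
  vp_frag <- which(fmap$fragments$start <= c0 & fmap$fragments$end > c0)
  enriched <- data.frame(start = 40472000, end = 40480000,
                         fold = d$enrich_fold)
  masked <- c(d$causal_pos - 13000, d$causal_pos - 3000)
  reads <- simulate_4c_reads(fmap, vp_frag, d$n_reads_4c, seed = d$seed + 6L,
                             decay_exponent = d$decay_exponent,
                             enriched_intervals = enriched,
                             masked_interval = masked)
  write_bed(reads, file.path(outdir, "reads_4c.bed"))

  # --- expression ---------------------------------------------------------
  case_ids <- names(cc$phenotype)[cc$phenotype == 1]
  dose <- stats::setNames(table$dosages[match(case_ids, table$sample_ids),
                                        causal_col], case_ids)
  expr <- simulate_expression(dose, d$expr_beta, d$expr_noise_sd,
                              d$n_expr_samples, seed = d$seed + 7L,
                              n_null_genes = d$n_null_genes,
                              chrom = d$chrom, center_pos = d$causal_pos)
  write_expression_matrix(expr, file.path(outdir, "expression.tsv"))

  # --- config + manifest --------------------------------------------------
  # outdir "." keeps the config relocatable (and the fixture byte-identical
  # across output directories); readers anchor it at the config's location
  config <- pipeline_config(
    outdir = ".",
    genotypes = "genotypes.tsv", probabilities = "genotype_probs.tsv",
    phenotypes = "phenotypes.tsv",
    tracks = list(dnase = "tracks/dnase.bed",
                  h3k4me1 = "tracks/h3k4me1.bed",
                  h3k27ac = "tracks/h3k27ac.bed",
                  h3k4me3 = "tracks/h3k4me3.bed",
                  super_enhancer = "tracks/super_enhancer.bed",
                  contact_domain = "tracks/contact_domain.bed"),
    conservation = list(phastcons = "conservation/phastcons.bedgraph",
                        gerp = "conservation/gerp.bedgraph"),
    genome_fasta = "genome.fa", genome_offset = offset,
    pfm = "rela_motif.pfm", reads_4c = "reads_4c.bed",
    expression = "expression.tsv",
    region = span, viewpoint_pos = c0,
    fourc_mask = masked, seed = d$seed
  )
  write_pipeline_config(config, file.path(outdir, "config.json"))

  rel <- c("genotypes.tsv", "genotype_probs.tsv", "phenotypes.tsv",
           "tracks/dnase.bed", "tracks/h3k4me1.bed", "tracks/h3k27ac.bed",
           "tracks/h3k4me3.bed", "tracks/super_enhancer.bed",
           "tracks/contact_domain.bed", "conservation/phastcons.bedgraph",
           "conservation/gerp.bedgraph", "genome.fa", "rela_motif.pfm",
           "reads_4c.bed", "expression.tsv", "config.json")
  sums <- tools::md5sum(file.path(outdir, rel))
  manifest <- list(
    design = unclass(d),
    files = lapply(seq_along(rel), function(i)
      list(path = rel[i], md5 = unname(sums[i]))),
    truth = list(causal_id = "sim_causal",
                 proxy_ids = sprintf("sim_proxy_%d", seq_len(d$n_proxy_high)),
                 viewpoint_fragment = vp_frag,
                 enriched_interval = c(enriched$start, enriched$end),
                 masked_interval = masked)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
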