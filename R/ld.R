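# Two-locus linkage disequilibrium: haplotype-frequency estimation and
# proxy selection.

new_haplotype_freqs <- function(f_AB, f_Ab, f_aB, f_ab,
                                loglik = NA_real_, converged = TRUE,
                                n_iter = 0L) {
  f <- c(f_AB, f_Ab, f_aB, f_ab)
  assert_that(abs(sum(f) - 1) < 1e-9, "haplotype frequencies must sum to 1")
  p_A <- f_AB + f_Ab
  p_B <- f_AB + f_aB
  D <- f_AB - p_A * p_B
  denom <- p_A * (1 - p_A) * p_B * (1 - p_B)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  dmax <- if (D >= 0) {
    min(p_A * (1 - p_B), (1 - p_A) * p_B)
  } else {
    min(p_A * p_B, (1 - p_A) * (1 - p_B))
  }
  dprime <- if (D == 0) 0 else if (dmax > 0) abs(D) / dmax else NA_real_
  structure(
    list(f_AB = f_AB, f_Ab = f_Ab, f_aB = f_aB, f_ab = f_ab,
         p_A = p_A, p_B = p_B, D = D, r2 = r2, dprime = dprime,
         loglik = loglik, converged = converged, n_iter = n_iter),
    class = "haplotype_freqs"
  )
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat("Two-locus haplotype frequencies\n")
  cat(sprintf("  f(AB)=%.4f f(Ab)=%.4f f(aB)=%.4f f(ab)=%.4f\n",
              x$f_AB, x$f_Ab, x$f_aB, x$f_ab))
  cat(sprintf("  D=%.5f  r2=%.4f  D'=%.4f  (converged: %s)\n",
              x$D, x$r2, x$dprime, x$converged))
  invisible(x)
}

#' Linkage disequilibrium from phased haplotypes
#'
#' Computes two-locus haplotype frequencies and the derived LD summaries
#' (`D`, `r2`, `D'`) by direct counting of phased binary haplotype vectors.
#' The "A"/"B" alleles are the 1-coded alleles of the two input vectors.
#'
#' @param hapA,hapB Binary (0/1) vectors of equal length, one entry per
#'   haplotype, coding the allele carried at each of the two loci.
#' @return A `haplotype_freqs` object with the four haplotype frequencies,
#'   `D`, `r2` and `dprime`.
#' @examples
#' h <- cbind(c(1, 1, 0, 0, 1, 0), c(1, 1, 0, 0, 1, 0))
#' r2_from_haplotypes(h[, 1], h[, 2])$r2  # identical loci -> 1
#' @export
r2_from_haplotypes <- function(hapA, hapB) {
  assert_that(length(hapA) == length(hapB), "haplotype vectors differ in length")
  assert_that(length(hapA) >= 2, "need at least two haplotypes")
  assert_that(all(hapA %in% c(0, 1)) && all(hapB %in% c(0, 1)),
              "haplotypes must be 0/1")
  if (length(unique(hapA)) < 2 || length(unique(hapB)) < 2) {
    stopf("r2 is undefined for a monomorphic locus")
  }
  n <- length(hapA)
  f_AB <- sum(hapA == 1 & hapB == 1) / n
  f_Ab <- sum(hapA == 1 & hapB == 0) / n
  f_aB <- sum(hapA == 0 & hapB == 1) / n
  f_ab <- sum(hapA == 0 & hapB == 0) / n
  new_haplotype_freqs(f_AB, f_Ab, f_aB, f_ab)
}

# Multinomial log-likelihood of the 3x3 genotype table under haplotype
# frequencies f = (fAB, fAb, faB, fab), random mating.
geno_pair_loglik <- function(tab, f) {
  fAB <- f[1]; fAb <- f[2]; faB <- f[3]; fab <- f[4]
  p <- matrix(0, 3, 3) # [doseA+1, doseB+1]
  p[3, 3] <- fAB^2
  p[3, 2] <- 2 * fAB * fAb
  p[3, 1] <- fAb^2
  p[2, 3] <- 2 * fAB * faB
  p[2, 2] <- 2 * fAB * fab + 2 * fAb * faB
  p[2, 1] <- 2 * fAb * fab
  p[1, 3] <- faB^2
  p[1, 2] <- 2 * faB * fab
  p[1, 1] <- fab^2
  keep <- tab > 0
  sum(tab[keep] * log(pmax(p[keep], .Machine$double.xmin)))
}

#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Estimates two-locus haplotype frequencies from unphased 0/1/2 genotype
#' dose vectors with the Excoffier-Slatkin EM algorithm, which resolves the
#' phase ambiguity of double heterozygotes. The EM is initialised at linkage
#' equilibrium; the observed-data log-likelihood is non-decreasing across
#' iterations.
#'
#' @param genoA,genoB Integer vectors of allele doses (0, 1 or 2) at the two
#'   loci, one entry per individual.
#' @param tol Convergence tolerance on the maximum absolute change in
#'   haplotype frequency between iterations.
#' @param max_iter Iteration cap; exceeding it returns `converged = FALSE`.
#' @return A `haplotype_freqs` object; `loglik` holds the per-iteration
#'   log-likelihood trace and `converged` the convergence flag.
#' @export
em_haplotype_freqs <- function(genoA, genoB, tol = 1e-8, max_iter = 1000L) {
  assert_that(length(genoA) == length(genoB), "genotype vectors differ in length")
  assert_that(all(genoA %in% 0:2) && all(genoB %in% 0:2),
              "genotypes must be 0/1/2 doses")
  if (length(unique(genoA)) < 2 || length(unique(genoB)) < 2) {
    stopf("LD is undefined for a monomorphic locus")
  }
  n <- length(genoA)
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[genoA[i] + 1L, genoB[i] + 1L] <-
      tab[genoA[i] + 1L, genoB[i] + 1L] + 1
  p_A <- mean(genoA) / 2
  p_B <- mean(genoB) / 2
  f <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B, (1 - p_A) * (1 - p_B))
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  # Unambiguous haplotype counts contributed by the eight phase-known cells.
  base_counts <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  n_dh <- tab[2, 2]
  while (it < max_iter) {
    it <- it + 1L
    ll_trace <- c(ll_trace, geno_pair_loglik(tab, f))
    # E-step: expected phase of double heterozygotes (cis = AB/ab).
    cis <- f[1] * f[4]
    trans <- f[2] * f[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- base_counts + n_dh * c(w, 1 - w, 1 - w, w)
    f_new <- unname(cnt) / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  ll_trace <- c(ll_trace, geno_pair_loglik(tab, f))
  out <- new_haplotype_freqs(f[1], f[2], f[3], f[4],
                             loglik = ll_trace, converged = converged,
                             n_iter = it)
  out
}

#' Select LD proxies of a lead variant
#'
#' Estimates `r2` between the lead variant and every other polymorphic
#' variant in a genotype table (EM on hard-called doses) and returns those
#' exceeding a threshold, strongest first.
#'
#' @param table A [genotype_table()].
#' @param lead_id Variant id of the lead SNP.
#' @param r2_min Retain variants with `r2` strictly greater than this
#'   (default 0.2, the conventional proxy cut-off).
#' @return A data frame with columns `variant_id`, `r2`, `dprime`, sorted by
#'   decreasing `r2` (ties broken by ascending genomic position); the lead
#'   itself is excluded.
#' @export
ld_proxies <- function(table, lead_id, r2_min = 0.2) {
  stopifnot(inherits(table, "genotype_table"))
  idx <- match(lead_id, table$variants$id)
  assert_that(!is.na(idx), "lead variant '%s' not found", lead_id)
  lead_geno <- round(table$dosages[, idx])
  if (length(unique(lead_geno)) < 2) stopf("lead variant is monomorphic")
  others <- setdiff(seq_len(nrow(table$variants)), idx)
  rows <- lapply(others, function(j) {
    g <- round(table$dosages[, j])
    if (length(unique(g)) < 2) return(NULL)
    hf <- em_haplotype_freqs(lead_geno, g)
    data.frame(variant_id = table$variants$id[j],
               pos = table$variants$pos[j],
               r2 = hf$r2, dprime = hf$dprime,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(variant_id = character(0), r2 = numeric(0),
                      dprime = numeric(0)))
  }
  res <- res[res$r2 > r2_min, , drop = FALSE]
  res <- res[order(-res$r2, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("variant_id", "r2", "dprime")]
}
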