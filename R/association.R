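# Case-control single-variant association, imputation QC and conditional
# analysis.

#' Cochran-Armitage trend test
#'
#' One-degree-of-freedom chi-square test for a linear trend in case
#' proportion across the three genotype classes, with the additive scores
#' (0, 1, 2). Counts may be non-integer (expected counts accumulated from
#' genotype probabilities are accepted).
#'
#' @param counts 2 x 3 matrix; rows = cases then controls, columns =
#'   genotype dose 0, 1, 2.
#' @return List with `chi2`, `p` and a `degenerate` flag; a table whose
#'   score variance is zero (e.g. a monomorphic variant) returns
#'   `chi2 = 0, p = 1, degenerate = TRUE`.
#' @examples
#' cochran_armitage_trend(rbind(c(10, 40, 50), c(50, 40, 10)))
#' @export
cochran_armitage_trend <- function(counts) {
  counts <- as.matrix(counts)
  assert_that(all(dim(counts) == c(2, 3)), "counts must be a 2x3 table")
  assert_that(all(counts >= 0), "counts must be non-negative")
  r <- counts[1, ]            # cases per genotype
  n <- colSums(counts)        # totals per genotype
  R <- sum(r)
  N <- sum(n)
  assert_that(R > 0 && (N - R) > 0, "both case and control rows must be non-empty")
  w <- c(0, 1, 2)
  num <- N * sum(w * r) - R * sum(w * n)
  var_term <- R * (N - R) * (N * sum(w^2 * n) - sum(w * n)^2)
  if (var_term <= 0) {
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  }
  chi2 <- N * num^2 / var_term
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Logistic regression by Newton-Raphson
#'
#' Maximum-likelihood logistic regression of a binary phenotype on an allele
#' dose plus optional covariates, fitted by Newton-Raphson on the Bernoulli
#' log-likelihood. Convergence requires the maximum absolute score component
#' to fall below `tol` within `max_iter` iterations; separation or a
#' singular information matrix yields `converged = FALSE` rather than a
#' silent estimate.
#'
#' @param dosage Numeric predictor of interest (allele dose per sample), or
#'   NULL for an intercept-only model.
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional numeric matrix/data frame of extra columns.
#' @param tol,max_iter Newton-Raphson controls.
#' @return List with vectors `beta`, `se`, `wald_p` (named
#'   `(Intercept)`, `dosage`, covariate names) and a `converged` flag.
#' @export
logistic_fit <- function(dosage, phenotype, covariates = NULL,
                         tol = 1e-8, max_iter = 25L) {
  y <- as.numeric(phenotype)
  assert_that(all(y %in% c(0, 1)), "phenotype must be binary 0/1")
  X <- if (is.null(dosage)) {
    cbind(`(Intercept)` = rep(1, length(y)))
  } else {
    cbind(`(Intercept)` = 1, dosage = as.numeric(dosage))
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  assert_that(nrow(X) == length(y), "predictor/phenotype length mismatch")
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    wt <- mu * (1 - mu)
    info <- crossprod(X * wt, X)
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(beta = stats::setNames(rep(NA_real_, p), colnames(X)),
                  se = stats::setNames(rep(NA_real_, p), colnames(X)),
                  wald_p = stats::setNames(rep(NA_real_, p), colnames(X)),
                  converged = FALSE))
    }
    # Step-halving keeps the likelihood finite under near-separation.
    ll_old <- sum(y * eta - log1p(exp(eta)))
    for (h in 0:5) {
      beta_new <- beta + step / 2^h
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(y * eta_new - log1p(exp(eta_new)))
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    beta <- beta_new
  }
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  # separation: fitted probabilities saturate and the estimate diverges
  mu <- stats::plogis(drop(X %*% beta))
  if (any(!is.finite(se)) || max(abs(beta)) > 15 ||
      any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    converged <- FALSE
  }
  z <- beta / se
  list(beta = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       wald_p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
       converged = converged)
}

#' IMPUTE-style imputation information score
#'
#' Ratio-of-variances information measure for one variant's imputed
#' genotype-probability triples: `Is = 1 - sum(f_i - e_i^2) /
#' (2N * theta(1-theta))`, where `e_i = p_AB + 2 p_BB` and
#' `f_i = p_AB + 4 p_BB` and `theta` is the estimated allele frequency.
#' Hard calls give 1; values are clamped to `[0, 1]`. A monomorphic
#' estimate (`theta` 0 or 1) is returned as 0 with `degenerate = TRUE`.
#'
#' @param triples N x 3 matrix of `(p_AA, p_AB, p_BB)` rows summing to 1.
#' @return List with `info` and `degenerate`.
#' @export
impute_info_score <- function(triples) {
  triples <- as.matrix(triples)
  assert_that(ncol(triples) == 3, "triples must have 3 columns")
  assert_that(all(triples >= -1e-12), "probabilities must be non-negative")
  assert_that(max(abs(rowSums(triples) - 1)) < 1e-6,
              "probability triples must sum to 1")
  e <- triples[, 2] + 2 * triples[, 3]
  f <- triples[, 2] + 4 * triples[, 3]
  N <- nrow(triples)
  theta <- sum(e) / (2 * N)
  if (theta <= 0 || theta >= 1) {
    return(list(info = 0, degenerate = TRUE))
  }
  info <- 1 - sum(f - e^2) / (2 * N * theta * (1 - theta))
  list(info = min(1, max(0, info)), degenerate = FALSE)
}

# Expected 2x3 genotype-class counts by phenotype, from probability triples
# when available, otherwise from rounded hard calls.
expected_counts_2x3 <- function(table, j, phenotype) {
  case <- phenotype == 1
  if (!is.null(table$probabilities)) {
    pr <- table$probabilities[, j, ]
    rbind(cases = colSums(pr[case, , drop = FALSE]),
          controls = colSums(pr[!case, , drop = FALSE]))
  } else {
    g <- factor(round(table$dosages[, j]), levels = 0:2)
    rbind(cases = table(g[case]), controls = table(g[!case]))
  }
}

#' Single-variant case-control association scan
#'
#' For every variant: pooled minor-allele frequency from doses, imputation
#' info score (1 when hard calls), Cochran-Armitage trend test on the 2 x 3
#' genotype-class table (expected counts when probabilities are present),
#' and a logistic-regression Wald test on dose giving the per-allele
#' log-odds, standard error and odds ratio.
#'
#' @param table A [genotype_table()].
#' @param phenotype Named or positional 0/1 vector (1 = case), aligned with
#'   `table$sample_ids` by name when named.
#' @param covariates Optional covariate matrix passed to [logistic_fit()].
#' @return Data frame of class `association_result`, one row per variant:
#'   `variant_id, chrom, pos, beta, se, or_, chi2_trend, p_trend, p_wald,
#'   maf, info, converged`.
#' @export
associate_variants <- function(table, phenotype, covariates = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (!is.null(names(phenotype))) {
    assert_that(all(table$sample_ids %in% names(phenotype)),
                "phenotype missing some samples")
    phenotype <- phenotype[table$sample_ids]
  }
  assert_that(length(phenotype) == nrow(table$dosages),
              "phenotype length mismatch")
  nv <- ncol(table$dosages)
  out <- vector("list", nv)
  for (j in seq_len(nv)) {
    dose <- table$dosages[, j]
    af <- mean(dose) / 2
    maf <- min(af, 1 - af)
    info <- if (is.null(table$probabilities)) 1 else
      impute_info_score(table$probabilities[, j, ])$info
    tr <- cochran_armitage_trend(expected_counts_2x3(table, j, phenotype))
    if (stats::var(dose) > 0) {
      fit <- logistic_fit(dose, phenotype, covariates)
      beta <- unname(fit$beta["dosage"])
      se <- unname(fit$se["dosage"])
      p_wald <- unname(fit$wald_p["dosage"])
      conv <- fit$converged
    } else {
      beta <- NA_real_; se <- NA_real_; p_wald <- NA_real_; conv <- FALSE
    }
    out[[j]] <- data.frame(
      variant_id = table$variants$id[j], chrom = table$variants$chrom[j],
      pos = table$variants$pos[j],
      beta = beta, se = se, or_ = exp(beta),
      chi2_trend = tr$chi2, p_trend = tr$p, p_wald = p_wald,
      maf = maf, info = info, converged = conv,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("association_result", "data.frame")
  res
}

#' QC and significance filter on association results
#'
#' Retains variants with minor allele frequency strictly above `maf_min`,
#' imputation info at least `info_min`, and trend p-value strictly below
#' `p_max`, preserving input order.
#'
#' @param results An `association_result` data frame.
#' @param maf_min,info_min,p_max Thresholds; defaults are the conventional
#'   post-imputation fine-mapping cut-offs (MAF > 0.01, info >= 0.80,
#'   p < 5e-7).
#' @return The surviving rows, order preserved.
#' @export
filter_variants <- function(results, maf_min = 0.01, info_min = 0.80,
                            p_max = 5.0e-7) {
  keep <- results$maf > maf_min & results$info >= info_min &
    results$p_trend < p_max
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conditional association scan given a lead variant
#'
#' Re-tests each variant in a region with the lead variant's dose included
#' as a covariate; residual significance would indicate a second independent
#' signal. The lead itself is excluded, and variants whose dose is
#' (near-)collinear with the lead are flagged and excluded from testing.
#'
#' @param table A [genotype_table()].
#' @param phenotype 0/1 phenotype vector (1 = case).
#' @param lead_id Variant id to condition on; must be polymorphic.
#' @param region Optional numeric `c(start, end)` (1-based, inclusive)
#'   restricting the scan; default spans all variants.
#' @return Data frame: `variant_id, pos, beta, se, p_conditional, collinear,
#'   converged`; collinear variants carry NA estimates.
#' @export
conditional_scan <- function(table, phenotype, lead_id, region = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  idx <- match(lead_id, table$variants$id)
  assert_that(!is.na(idx), "lead variant '%s' not found", lead_id)
  lead <- table$dosages[, idx]
  if (stats::var(lead) == 0) stopf("lead variant is monomorphic")
  if (!is.null(names(phenotype))) phenotype <- phenotype[table$sample_ids]
  in_region <- if (is.null(region)) rep(TRUE, nrow(table$variants)) else
    table$variants$pos >= region[1] & table$variants$pos <= region[2]
  assert_that(any(in_region & seq_along(in_region) != idx),
              "region contains no variant other than the lead")
  js <- setdiff(which(in_region), idx)
  rows <- lapply(js, function(j) {
    dose <- table$dosages[, j]
    r <- suppressWarnings(stats::cor(dose, lead))
    if (is.na(r) || abs(r) > 0.999) {
      return(data.frame(variant_id = table$variants$id[j],
                        pos = table$variants$pos[j],
                        beta = NA_real_, se = NA_real_,
                        p_conditional = NA_real_,
                        collinear = TRUE, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    fit <- logistic_fit(dose, phenotype, covariates = cbind(lead = lead))
    data.frame(variant_id = table$variants$id[j],
               pos = table$variants$pos[j],
               beta = unname(fit$beta["dosage"]),
               se = unname(fit$se["dosage"]),
               p_conditional = unname(fit$wald_p["dosage"]),
               collinear = FALSE, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write association results as tab-delimited text
#'
#' @param results An `association_result` data frame.
#' @param path Output path.
#' @param header_lines Optional character vector of `#`-prefixed comment
#'   lines written before the column header.
#' @export
write_association_results <- function(results, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("#", header_lines), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
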