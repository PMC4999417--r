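# cis-eQTL dose testing with BH FDR, expression correlation, and junction
# k-mer splicing counts.

#' Construct an expression matrix container
#'
#' @param genes Data frame `id`, `chrom`, `tss` (1-based bp).
#' @param values Numeric matrix, genes x samples.
#' @param sample_ids Character vector, one per column of `values`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(genes, values, sample_ids) {
  values <- as.matrix(values)
  assert_that(nrow(genes) == nrow(values), "one row of values per gene")
  assert_that(length(sample_ids) == ncol(values),
              "one sample id per value column")
  assert_that(all(is.finite(values)), "expression values must be finite")
  structure(list(genes = as.data.frame(genes, stringsAsFactors = FALSE),
                 values = values, sample_ids = as.character(sample_ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @param path Tab-delimited file: `gene_id chrom tss` then one column per
#'   sample.
#' @export
write_expression_matrix <- function(x, path) {
  df <- cbind(data.frame(gene_id = x$genes$id, chrom = x$genes$chrom,
                         tss = x$genes$tss, stringsAsFactors = FALSE),
              as.data.frame(x$values))
  names(df)[-(1:3)] <- x$sample_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "tss")
  assert_that(all(need %in% names(df)), "malformed expression matrix: %s", path)
  ids <- setdiff(names(df), need)
  expression_matrix(
    genes = data.frame(id = df$gene_id, chrom = df$chrom, tss = df$tss,
                       stringsAsFactors = FALSE),
    values = as.matrix(df[, ids, drop = FALSE]),
    sample_ids = ids
  )
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment with monotonicity enforcement, input order
#' preserved (delegates to [stats::p.adjust()] after validation).
#'
#' @param pvals P-values in `(0, 1]`.
#' @return Q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  assert_that(length(pvals) >= 1, "no p-values supplied")
  assert_that(all(is.finite(pvals)) && all(pvals > 0) && all(pvals <= 1),
              "p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' cis-eQTL scan: expression dose response to a single SNP
#'
#' For every gene whose TSS lies within `window_bp` of the SNP, regresses
#' expression on allele dose (ordinary least squares), reports the
#' two-sided t-test p-value, and adjusts across the tested genes by
#' Benjamini-Hochberg.
#'
#' @param expr An [expression_matrix()].
#' @param genotypes A [genotype_table()] or a named dose vector.
#' @param snp_id Variant id (ignored when `genotypes` is a bare vector, in
#'   which case `snp_pos` must be given).
#' @param snp_pos 1-based SNP position; defaults to the table's record.
#' @param window_bp cis window half-width (default 1 Mb).
#' @param exclude_samples Optional sample ids dropped before the join (e.g.
#'   carriers of somatic copy-number loss over the locus).
#' @return Data frame `gene_id`, `tss`, `n`, `beta`, `se`, `p`, `q`,
#'   ordered as the genes appear in `expr`.
#' @export
eqtl_scan <- function(expr, genotypes, snp_id = NULL, snp_pos = NULL,
                      window_bp = 1e6, exclude_samples = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (inherits(genotypes, "genotype_table")) {
    j <- match(snp_id, genotypes$variants$id)
    assert_that(!is.na(j), "variant '%s' not found", snp_id %||% "<NULL>")
    dose <- stats::setNames(genotypes$dosages[, j], genotypes$sample_ids)
    snp_pos <- snp_pos %||% genotypes$variants$pos[j]
  } else {
    dose <- genotypes
    assert_that(!is.null(names(dose)), "a bare dose vector must be named")
    assert_that(!is.null(snp_pos), "snp_pos required with a bare dose vector")
  }
  common <- intersect(expr$sample_ids, names(dose))
  common <- setdiff(common, exclude_samples)
  assert_that(length(common) >= 3, "need at least 3 joined samples")
  g <- dose[common]
  if (stats::var(g) == 0) stopf("SNP is monomorphic in the joined samples")
  tested <- which(abs(expr$genes$tss - snp_pos) <= window_bp)
  assert_that(length(tested) >= 1, "no gene TSS within the cis window")
  ecol <- match(common, expr$sample_ids)
  X <- cbind(1, g)
  rows <- lapply(tested, function(i) {
    y <- expr$values[i, ecol]
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    dfres <- length(y) - 2
    sigma2 <- rss / dfres
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    beta <- fit$coefficients[2]
    tval <- beta / se
    data.frame(gene_id = expr$genes$id[i], tss = expr$genes$tss[i],
               n = length(y), beta = beta, se = se,
               p = 2 * stats::pt(-abs(tval), dfres),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and the large-sample
#' t-approximation for the p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 5).
#' @return List `rho`, `p`.
#' @export
spearman_corr <- function(x, y) {
  assert_that(length(x) == length(y), "x and y differ in length")
  assert_that(length(x) >= 5, "need at least 5 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stopf("rank correlation undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# All k-mers (forward and reverse complement) of a set of sequences.
kmer_set <- function(seqs, k) {
  out <- character(0)
  for (s in c(seqs, revcomp_chr(seqs))) {
    n <- nchar(s)
    if (n < k) next
    out <- c(out, substring(s, 1:(n - k + 1), k:n))
  }
  unique(out)
}

#' Count reads supporting splice-junction events by unique k-mers
#'
#' Each event is represented by its junction sequence; a read supports an
#' event when it contains at least one k-mer unique to that event's
#' junction (k-mers shared between events are discarded; reverse-complement
#' k-mers count, since reads are strand-unaware).
#'
#' @param reads Character vector of read sequences.
#' @param event_junction_seqs Named character vector, one junction sequence
#'   per event; all must be at least `k` long.
#' @param k k-mer length (default 31).
#' @return Named integer vector of per-event read counts.
#' @export
count_junction_kmers <- function(reads, event_junction_seqs, k = 31) {
  assert_that(!is.null(names(event_junction_seqs)),
              "junction sequences must be named by event")
  if (any(nchar(event_junction_seqs) < k)) {
    stopf("k = %d exceeds a junction sequence length", k)
  }
  sets <- lapply(event_junction_seqs, kmer_set, k = k)
  all_k <- unlist(sets, use.names = FALSE)
  shared <- unique(all_k[duplicated(all_k)])
  sets <- lapply(sets, setdiff, y = shared)
  counts <- stats::setNames(integer(length(sets)), names(sets))
  if (length(reads) == 0) return(counts)
  read_kmers <- lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    unique(c(substring(r, 1:(n - k + 1), k:n),
             substring(revcomp_chr(r), 1:(n - k + 1), k:n)))
  })
  for (ev in names(sets)) {
    counts[ev] <- sum(vapply(read_kmers,
                             function(km) any(km %in% sets[[ev]]),
                             logical(1)))
  }
  counts
}

#' Compare per-sample junction k-mer counts between homozygote groups
#'
#' Student's t-test (equal variances) of per-sample event-support counts
#' between the two homozygous genotype classes.
#'
#' @param sample_counts Numeric vector of per-sample counts for one event.
#' @param genotype Per-sample dose vector (0/1/2); only doses 0 and 2 enter
#'   the comparison.
#' @return List `t`, `p`, `mean_ref_hom`, `mean_alt_hom`, `n_ref_hom`,
#'   `n_alt_hom`.
#' @export
junction_kmer_test <- function(sample_counts, genotype) {
  assert_that(length(sample_counts) == length(genotype),
              "counts and genotypes differ in length")
  a <- sample_counts[genotype == 0]
  b <- sample_counts[genotype == 2]
  assert_that(length(a) >= 2 && length(b) >= 2,
              "need at least two samples per homozygote class")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_ref_hom = mean(a), mean_alt_hom = mean(b),
       n_ref_hom = length(a), n_alt_hom = length(b))
}
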