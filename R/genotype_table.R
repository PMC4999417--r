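# GenotypeTable container and its tab-delimited on-disk format.

#' Construct a genotype table
#'
#' Container for a locus-scale genotype matrix: per-variant metadata, a
#' samples x variants allele-dose matrix in `[0, 2]` and, optionally, the
#' genotype-probability triples the doses were derived from (one
#' `(p_AA, p_AB, p_BB)` triple per sample and variant, as produced by
#' imputation).
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; positions must be strictly increasing within a chromosome.
#' @param dosages Numeric matrix, samples in rows, variants in columns,
#'   values in `[0, 2]` counting the `alt` allele.
#' @param sample_ids Character vector, one id per row of `dosages`.
#' @param probabilities Optional 3-dimensional array
#'   `samples x variants x 3` of genotype probabilities; each triple must
#'   sum to 1 and reproduce the dose as `p_AB + 2 p_BB` (tolerance 1e-9).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(variants, dosages, sample_ids,
                           probabilities = NULL) {
  need <- c("id", "chrom", "pos", "ref", "alt")
  assert_that(all(need %in% names(variants)),
              "variants must have columns %s", paste(need, collapse = ", "))
  dosages <- as.matrix(dosages)
  assert_that(nrow(variants) == ncol(dosages),
              "dosage columns (%d) != variants (%d)",
              ncol(dosages), nrow(variants))
  assert_that(length(sample_ids) == nrow(dosages),
              "sample_ids length != dosage rows")
  assert_that(all(dosages >= -1e-9 & dosages <= 2 + 1e-9),
              "dosages must lie in [0, 2]")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    assert_that(all(diff(p) > 0),
                "positions must be strictly increasing within chromosome %s", ch)
  }
  if (!is.null(probabilities)) {
    assert_that(length(dim(probabilities)) == 3 &&
                  all(dim(probabilities) == c(nrow(dosages), ncol(dosages), 3)),
                "probabilities must be a samples x variants x 3 array")
    sums <- probabilities[, , 1] + probabilities[, , 2] + probabilities[, , 3]
    assert_that(max(abs(sums - 1)) < 1e-9,
                "genotype probability triples must sum to 1")
    implied <- probabilities[, , 2] + 2 * probabilities[, , 3]
    assert_that(max(abs(implied - dosages)) < 1e-9,
                "dosages must equal p_AB + 2*p_BB")
  }
  structure(
    list(variants = as.data.frame(variants, stringsAsFactors = FALSE),
         dosages = dosages,
         probabilities = probabilities,
         sample_ids = as.character(sample_ids)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d variants (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              if (is.null(x$probabilities)) "hard doses" else "with probabilities"))
  cat(sprintf("  %s:%d-%d\n", x$variants$chrom[1], min(x$variants$pos),
              max(x$variants$pos)))
  invisible(x)
}

#' @rdname genotype_table
#' @param x A `genotype_table`.
#' @param path,prob_path Output paths; `prob_path = NULL` skips the
#'   probability companion file.
#' @details The on-disk format is tab-delimited with one row per variant:
#'   `variant_id chrom pos ref alt` followed by one dosage column per sample.
#'   The probability companion file is long-format:
#'   `variant_id sample_id p_aa p_ab p_bb`.
#' @export
write_genotype_table <- function(x, path, prob_path = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  df <- cbind(
    data.frame(variant_id = x$variants$id, chrom = x$variants$chrom,
               pos = x$variants$pos, ref = x$variants$ref,
               alt = x$variants$alt, stringsAsFactors = FALSE),
    as.data.frame(t(x$dosages))
  )
  names(df)[-(1:5)] <- x$sample_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(prob_path) && !is.null(x$probabilities)) {
    nv <- ncol(x$dosages); ns <- nrow(x$dosages)
    long <- data.frame(
      variant_id = rep(x$variants$id, each = ns),
      sample_id = rep(x$sample_ids, times = nv),
      p_aa = as.vector(x$probabilities[, , 1]),
      p_ab = as.vector(x$probabilities[, , 2]),
      p_bb = as.vector(x$probabilities[, , 3]),
      stringsAsFactors = FALSE
    )
    utils::write.table(long, prob_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname genotype_table
#' @export
read_genotype_table <- function(path, prob_path = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  assert_that(all(need %in% names(df)), "malformed genotype table: %s", path)
  sample_ids <- setdiff(names(df), need)
  dos <- t(as.matrix(df[, sample_ids, drop = FALSE]))
  colnames(dos) <- NULL
  probs <- NULL
  if (!is.null(prob_path)) {
    long <- utils::read.table(prob_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    nv <- nrow(df); ns <- length(sample_ids)
    assert_that(nrow(long) == nv * ns, "probability file size mismatch")
    ord <- order(match(long$variant_id, df$variant_id),
                 match(long$sample_id, sample_ids))
    long <- long[ord, ]
    probs <- array(c(long$p_aa, long$p_ab, long$p_bb), dim = c(ns, nv, 3))
  }
  genotype_table(
    variants = data.frame(id = df$variant_id, chrom = df$chrom, pos = df$pos,
                          ref = df$ref, alt = df$alt,
                          stringsAsFactors = FALSE),
    dosages = dos, sample_ids = sample_ids, probabilities = probs
  )
}

#' Read or write a phenotype file
#'
#' Tab-delimited, two columns: `sample_id` and case/control `status`
#' (1 = case, 0 = control).
#'
#' @param phenotype Named integer vector of 0/1 status, names = sample ids.
#' @param path File path.
#' @export
write_phenotypes <- function(phenotype, path) {
  utils::write.table(
    data.frame(sample_id = names(phenotype), status = as.integer(phenotype)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(all(c("sample_id", "status") %in% names(df)),
              "malformed phenotype file: %s", path)
  assert_that(all(df$status %in% 0:1), "phenotype status must be 0/1")
  stats::setNames(as.integer(df$status), df$sample_id)
}
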