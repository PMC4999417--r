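# PWM construction from JASPAR-format counts, bidirectional scanning and
# allele-specific motif-disruption scoring.

BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Converts a 4 x L count matrix into pseudocount-regularised base
#' probabilities and log2 odds against a uniform 0.25 background.
#'
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param id,name Motif identifiers.
#' @param pseudocount Added to every cell before normalising (default 0.25).
#' @param background Background base probabilities (default uniform).
#' @return Object of class `pwm` with elements `counts`, `probs`,
#'   `logodds`, `length`.
#' @export
pwm <- function(counts, id = "motif", name = id, pseudocount = 0.25,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) == 4, "counts must have 4 rows (A, C, G, T)")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(ncol(counts) >= 4, "motif length must be >= 4")
  rownames(counts) <- BASES
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts) + 4 * pseudocount, "/")
  logodds <- log2(probs / background)
  structure(list(id = id, name = name, counts = counts, probs = probs,
                 logodds = logodds, length = ncol(counts),
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), length %d, consensus %s\n",
              x$id, x$name, x$length, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param x A [pwm()] object.
#' @return Character string of the most probable base at each position.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$probs, 2, which.max)], collapse = "")
}

# Reverse-complemented PWM: reverse positions, swap complementary rows.
pwm_revcomp <- function(x) {
  flip <- function(m) m[c(4, 3, 2, 1), rev(seq_len(ncol(m))), drop = FALSE]
  y <- x
  y$counts <- flip(x$counts)
  y$probs <- flip(x$probs)
  y$logodds <- flip(x$logodds)
  rownames(y$counts) <- rownames(y$probs) <- rownames(y$logodds) <- BASES
  y
}

#' Load position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR 2016 PFM dialect: a `>ID name` header followed by four
#' rows `A [ n n ... ]`, `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path File path (may contain several matrices).
#' @param pseudocount Passed to [pwm()].
#' @return List of [pwm()] objects named by matrix id.
#' @export
load_jaspar <- function(path, pseudocount = 0.25) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  assert_that(length(heads) >= 1, "no JASPAR header ('>') found in %s", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    hdr <- strsplit(sub("^>", "", lines[heads[k]]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else id
    rows <- stats::setNames(vector("list", 4), BASES)
    for (b in block) {
      base <- sub("^([ACGT]).*", "\\1", b)
      if (!base %in% BASES || !grepl("^[ACGT]\\s", b)) {
        stopf("unrecognised JASPAR row in %s: '%s'", id, b)
      }
      nums <- regmatches(b, gregexpr("[0-9.]+", b))[[1]]
      rows[[base]] <- as.numeric(nums)
    }
    missing <- BASES[vapply(rows, is.null, TRUE)]
    if (length(missing)) stopf("matrix %s missing base row(s): %s", id,
                               paste(missing, collapse = ", "))
    lens <- lengths(rows)
    if (length(unique(lens)) != 1) {
      stopf("matrix %s has ragged row lengths", id)
    }
    out[[id]] <- pwm(do.call(rbind, rows), id = id, name = name,
                     pseudocount = pseudocount)
  }
  out
}

#' Write a PWM's counts in JASPAR text format
#'
#' @param x A [pwm()] object.
#' @param path Output path.
#' @export
write_jaspar <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">%s %s", x$id, x$name), con)
  for (b in BASES) {
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(x$counts[b, ], trim = TRUE),
                             collapse = " ")), con)
  }
  invisible(path)
}

# Score all windows of an integer-coded sequence against a log-odds matrix.
# Windows containing N (NA codes) score NA.
score_windows <- function(codes, logodds) {
  L <- ncol(logodds)
  n <- length(codes)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (l in seq_len(L)) {
    sc <- sc + logodds[cbind(codes[l:(nw + l - 1L)], l)]
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every length-L window as the sum of per-position log2 odds
#' (uniform background); with `both_strands` the reverse complement of each
#' window is scored as well. Windows containing `N` are skipped. The best
#' hit breaks ties in favour of the plus strand, then the leftmost window.
#'
#' @param seq Character DNA sequence over `A, C, G, T, N`.
#' @param x A [pwm()] object.
#' @param both_strands Score the minus strand too (default TRUE).
#' @param threshold Report all hits scoring at least this (default none).
#' @return List with `best` (list `position` 0-based window start on the
#'   forward sequence, `strand`, `score`; NULL if no scorable window) and
#'   `hits` (data frame of all windows at or above `threshold`).
#' @export
scan_sequence <- function(seq, x, both_strands = TRUE, threshold = Inf) {
  stopifnot(inherits(x, "pwm"))
  codes <- dna_to_int(seq)
  L <- x$length
  plus <- score_windows(codes, x$logodds)
  minus <- if (both_strands) score_windows(codes, pwm_revcomp(x)$logodds)
           else rep(NA_real_, length(plus))
  nw <- length(plus)
  if (nw == 0) {
    return(list(best = NULL,
                hits = data.frame(position = integer(0), strand = character(0),
                                  score = numeric(0))))
  }
  hits <- data.frame(
    position = c(seq_len(nw), seq_len(nw)) - 1L,
    strand = rep(c("+", "-"), each = nw),
    score = c(plus, minus),
    stringsAsFactors = FALSE
  )
  hits <- hits[!is.na(hits$score), , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(best = NULL,
                hits = data.frame(position = integer(0), strand = character(0),
                                  score = numeric(0))))
  }
  # plus strand first, then leftmost
  hits <- hits[order(hits$strand, hits$position), , drop = FALSE]
  best_i <- which.max(hits$score)
  best <- list(position = hits$position[best_i], strand = hits$strand[best_i],
               score = hits$score[best_i])
  keep <- hits[hits$score >= threshold, , drop = FALSE]
  rownames(keep) <- NULL
  list(best = best, hits = keep)
}

#' Allele-specific motif-disruption score
#'
#' Scores only the PWM windows that cover the variant base, on both
#' strands, for the reference and the alternate allele, and reports
#' `delta = best_ref - best_alt`: a positive delta means the alternate
#' allele weakens the motif.
#'
#' @param context_seq DNA context sequence containing the variant.
#' @param variant_offset 0-based offset of the variant base in
#'   `context_seq`.
#' @param ref_allele,alt_allele Single bases; `ref_allele` must match the
#'   context at the offset.
#' @param x A [pwm()] object.
#' @return List `best_ref_score`, `best_alt_score`, `delta`.
#' @export
allele_delta <- function(context_seq, variant_offset, ref_allele, alt_allele,
                         x) {
  stopifnot(inherits(x, "pwm"))
  context_seq <- toupper(context_seq)
  n <- nchar(context_seq)
  assert_that(variant_offset >= 0 && variant_offset < n,
              "variant_offset outside context")
  assert_that(nchar(ref_allele) == 1 && nchar(alt_allele) == 1,
              "alleles must be single bases")
  at <- substr(context_seq, variant_offset + 1, variant_offset + 1)
  if (at != toupper(ref_allele)) {
    stopf("reference allele mismatch at offset %d: context has %s, not %s",
          variant_offset, at, ref_allele)
  }
  L <- x$length
  lo <- max(0L, variant_offset - L + 1L)
  hi <- min(variant_offset, n - L)
  if (hi < lo) {
    return(list(best_ref_score = NA_real_, best_alt_score = NA_real_,
                delta = NA_real_))
  }
  sub_start <- lo
  sub_end <- min(n - 1L, variant_offset + L - 1L)
  best_over <- function(allele) {
    s <- context_seq
    substr(s, variant_offset + 1, variant_offset + 1) <- toupper(allele)
    window_region <- substr(s, sub_start + 1, sub_end + 1)
    codes <- dna_to_int(window_region)
    plus <- score_windows(codes, x$logodds)
    minus <- score_windows(codes, pwm_revcomp(x)$logodds)
    # window starts (in region coords) that cover the variant
    cover <- (lo:hi) - sub_start + 1L
    vals <- c(plus[cover], minus[cover])
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }
  ref_best <- best_over(ref_allele)
  alt_best <- best_over(alt_allele)
  list(best_ref_score = ref_best, best_alt_score = alt_best,
       delta = ref_best - alt_best)
}

#' Motif-disruption report for a variant set
#'
#' Applies [allele_delta()] to each variant using its sequence context
#' extracted from a genome sequence.
#'
#' @param variants Data frame `id`, `pos` (1-based), `ref`, `alt`.
#' @param genome_seq Character genome/locus sequence.
#' @param offset 0-based genomic coordinate of the first base of
#'   `genome_seq` (so sequence index = pos - offset).
#' @param x A [pwm()] object.
#' @param flank Context half-width in bp (default `2 * motif length`).
#' @return Data frame `variant_id`, `best_ref_score`, `best_alt_score`,
#'   `delta`. Variants whose reference allele does not match the genome are
#'   reported with NA scores and a warning.
#' @export
motif_disruption_scan <- function(variants, genome_seq, offset, x,
                                  flank = NULL) {
  flank <- flank %||% (2L * x$length)
  n <- nchar(genome_seq)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1 - offset  # 0-based index in genome_seq
    lo <- max(0, p0 - flank)
    hi <- min(n - 1, p0 + flank)
    ctx <- substr(genome_seq, lo + 1, hi + 1)
    res <- tryCatch(
      allele_delta(ctx, p0 - lo, variants$ref[i], variants$alt[i], x),
      error = function(e) {
        warnf("variant %s: %s", variants$id[i], conditionMessage(e))
        list(best_ref_score = NA_real_, best_alt_score = NA_real_,
             delta = NA_real_)
      })
    data.frame(variant_id = variants$id[i],
               best_ref_score = res$best_ref_score,
               best_alt_score = res$best_alt_score,
               delta = res$delta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
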