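# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_fraction <- function(x, open = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
}

#' @importFrom stats runif
with_seed <- function(seed, expr) {
  assert_that(is_count(seed + 1), "seed must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Reverse complement for plain character DNA (ACGTN).
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Encode a DNA string as integers A=1 C=2 G=3 T=4, anything else NA.
dna_to_int <- function(seq) {
  m <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  v <- m[strsplit(toupper(seq), "")[[1]]]
  unname(v)
}
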