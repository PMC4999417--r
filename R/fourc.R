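# 4C-seq: restriction-fragment map, read allocation to blind/non-blind
# fragments, binned contact profiles and running-window smoothing.

#' Build a restriction-fragment map from a genome sequence
#'
#' Cuts the sequence at every occurrence of the primary recognition site
#' (cut placed at the first base of the site, matching a DpnII-style enzyme
#' that cleaves 5' of GATC) and classifies each fragment as *blind* when it
#' contains no occurrence of the secondary site.
#'
#' @param genome A file path to a FASTA with a single sequence, a
#'   `Biostrings::DNAString`, or a plain character sequence.
#' @param primary,secondary Recognition sequences (defaults GATC = DpnII
#'   and AAGCTT = HindIII).
#' @param chrom Chromosome name attached to the fragments (default taken
#'   from the FASTA header, else "seq").
#' @param offset 0-based genomic coordinate of the sequence's first base;
#'   fragment coordinates are reported as `offset +` sequence-local
#'   coordinates, 0-based half-open.
#' @return Object of class `fragment_map`: data frame `fragments`
#'   (`chrom`, `start`, `end`, `blind`) tiling the sequence without gaps,
#'   plus the recognition sites and offset.
#' @export
build_fragment_map <- function(genome, primary = "GATC",
                               secondary = "AAGCTT", chrom = NULL,
                               offset = 0) {
  assert_that(grepl("^[ACGT]+$", primary) && grepl("^[ACGT]+$", secondary),
              "recognition sequences must be over A/C/G/T")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    assert_that(length(ss) >= 1, "empty FASTA: %s", genome)
    if (length(ss) > 1) warnf("using first of %d FASTA records", length(ss))
    chrom <- chrom %||% sub("\\s.*", "", names(ss)[1])
    seq <- ss[[1]]
  } else if (inherits(genome, "DNAString")) {
    seq <- genome
  } else {
    seq <- Biostrings::DNAString(toupper(as.character(genome)))
  }
  chrom <- chrom %||% "seq"
  len <- length(seq)
  prim_hits <- Biostrings::start(Biostrings::matchPattern(primary, seq))
  if (length(prim_hits) == 0) {
    warnf("no %s site found; returning a single fragment", primary)
  }
  # cut at the first base of each site; drop a cut at position 1 (no
  # zero-length fragment)
  cuts <- sort(unique(prim_hits[prim_hits > 1])) - 1L  # 0-based cut coords
  starts <- c(0L, cuts)
  ends <- c(cuts, len)
  sec_hits <- Biostrings::matchPattern(secondary, seq)
  sec_start <- Biostrings::start(sec_hits) - 1L       # 0-based
  sec_end <- Biostrings::end(sec_hits)                # exclusive
  blind <- vapply(seq_along(starts), function(i) {
    !any(sec_start >= starts[i] & sec_end <= ends[i])
  }, logical(1))
  frags <- data.frame(
    chrom = chrom,
    start = starts + offset,
    end = ends + offset,
    blind = blind,
    stringsAsFactors = FALSE
  )
  structure(list(fragments = frags, primary_site = primary,
                 secondary_site = secondary, offset = offset,
                 seq_length = len),
            class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("fragment_map: %d fragments (%d blind) on %s:%d-%d [%s/%s]\n",
              nrow(x$fragments), sum(x$fragments$blind),
              x$fragments$chrom[1], min(x$fragments$start),
              max(x$fragments$end), x$primary_site, x$secondary_site))
  invisible(x)
}

# 0-based 5' position of each read in a BED6 data frame.
read_five_prime <- function(reads) {
  fp <- reads$start
  if ("strand" %in% names(reads)) {
    minus <- reads$strand == "-"
    fp[minus] <- reads$end[minus] - 1
  }
  fp
}

#' Allocate mapped 4C reads to restriction fragments
#'
#' Filters reads by mapping quality, collapses duplicate 5' positions to
#' unique events, drops reads inside masked intervals or within the
#' viewpoint exclusion zone, and assigns each surviving read to the
#' fragment containing its 5' position.
#'
#' @param reads BED6-style data frame (`chrom`, `start`, `end`, `name`,
#'   `score` = mapping quality, `strand`).
#' @param fmap A [build_fragment_map()] result.
#' @param min_mapq Reads with quality below this are dropped (default 30).
#' @param viewpoint 0-based genomic position of the viewpoint (e.g. the
#'   midpoint of the viewpoint fragment), or NULL to skip exclusion.
#' @param exclusion_radius Half-width of the viewpoint exclusion zone in bp
#'   (default 1500).
#' @param masked Optional data frame `start`, `end` (0-based half-open) of
#'   masked intervals.
#' @return List: `counts` (per-fragment unique-read counts, one entry per
#'   fragment of `fmap`), `blind` (per-fragment class), `n_outside`
#'   (reads falling outside the fragment map, reported not fatal),
#'   `n_input`, `n_used`.
#' @export
assign_reads <- function(reads, fmap, min_mapq = 30, viewpoint = NULL,
                         exclusion_radius = 1500, masked = NULL) {
  stopifnot(inherits(fmap, "fragment_map"))
  frags <- fmap$fragments
  n_input <- nrow(reads)
  if ("score" %in% names(reads)) {
    reads <- reads[!is.na(reads$score) & reads$score >= min_mapq, ,
                   drop = FALSE]
  }
  fp <- read_five_prime(reads)
  strand <- if ("strand" %in% names(reads)) reads$strand else
    rep("+", nrow(reads))
  keep <- !duplicated(data.frame(reads$chrom, fp, strand))
  reads <- reads[keep, , drop = FALSE]
  fp <- fp[keep]
  if (!is.null(masked) && nrow(masked)) {
    in_mask <- rep(FALSE, length(fp))
    for (i in seq_len(nrow(masked))) {
      in_mask <- in_mask | (fp >= masked$start[i] & fp < masked$end[i])
    }
    reads <- reads[!in_mask, , drop = FALSE]
    fp <- fp[!in_mask]
  }
  if (!is.null(viewpoint)) {
    excl <- abs(fp - viewpoint) <= exclusion_radius
    reads <- reads[!excl, , drop = FALSE]
    fp <- fp[!excl]
  }
  on_chrom <- reads$chrom == frags$chrom[1]
  inside <- on_chrom & fp >= frags$start[1] & fp < frags$end[nrow(frags)]
  n_outside <- sum(!inside)
  fp <- fp[inside]
  idx <- findInterval(fp, frags$start)
  counts <- tabulate(idx, nbins = nrow(frags))
  list(counts = counts, blind = frags$blind, n_outside = n_outside,
       n_input = n_input, n_used = length(fp))
}

#' Binned 4C contact profile
#'
#' Distributes each fragment's read count over the fixed-resolution bins it
#' overlaps, proportionally to the overlap fraction, keeping blind and
#' non-blind fragments as separate channels (plus their sum). Total signal
#' is conserved.
#'
#' @param fragment_counts Per-fragment counts as returned by
#'   [assign_reads()] (`$counts`), or a bare numeric vector.
#' @param fmap The matching [build_fragment_map()].
#' @param resolution Bin width in bp (default 100).
#' @param masked Optional masked intervals (`start`, `end`, 0-based
#'   half-open); overlapping bins are flagged and excluded from smoothing.
#' @return Object of class `contact_profile`: data frame `bins` with
#'   `chrom`, `start`, `end`, `blind`, `nonblind`, `combined`, `masked`,
#'   plus the resolution.
#' @export
binned_profile <- function(fragment_counts, fmap, resolution = 100,
                           masked = NULL) {
  stopifnot(inherits(fmap, "fragment_map"))
  if (is.list(fragment_counts)) fragment_counts <- fragment_counts$counts
  frags <- fmap$fragments
  assert_that(length(fragment_counts) == nrow(frags),
              "one count per fragment required")
  assert_that(resolution > 0, "resolution must be positive")
  lo <- min(frags$start)
  hi <- max(frags$end)
  nb <- ceiling((hi - lo) / resolution)
  bin_start <- lo + (seq_len(nb) - 1) * resolution
  bin_end <- pmin(bin_start + resolution, hi)
  chan <- matrix(0, nrow = nb, ncol = 2,
                 dimnames = list(NULL, c("blind", "nonblind")))
  nonzero <- which(fragment_counts > 0)
  for (i in nonzero) {
    fs <- frags$start[i]; fe <- frags$end[i]
    b0 <- floor((fs - lo) / resolution) + 1
    b1 <- floor((fe - 1 - lo) / resolution) + 1
    ov <- pmin(bin_end[b0:b1], fe) - pmax(bin_start[b0:b1], fs)
    w <- ov / (fe - fs)
    col <- if (frags$blind[i]) 1L else 2L
    chan[b0:b1, col] <- chan[b0:b1, col] + fragment_counts[i] * w
  }
  masked_flag <- rep(FALSE, nb)
  if (!is.null(masked) && nrow(masked)) {
    for (i in seq_len(nrow(masked))) {
      masked_flag <- masked_flag |
        (bin_start < masked$end[i] & bin_end > masked$start[i])
    }
  }
  bins <- data.frame(chrom = frags$chrom[1], start = bin_start,
                     end = bin_end, blind = chan[, "blind"],
                     nonblind = chan[, "nonblind"],
                     combined = chan[, "blind"] + chan[, "nonblind"],
                     masked = masked_flag, stringsAsFactors = FALSE)
  structure(list(bins = bins, resolution = resolution),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("contact_profile: %d bins @ %d bp, total signal %.1f%s\n",
              nrow(x$bins), x$resolution, sum(x$bins$combined),
              if (!is.null(x$bins$smoothed)) ", smoothed" else ""))
  invisible(x)
}

#' Running-window smoothing of a contact profile
#'
#' Centred running mean of the combined channel over unmasked bins: masked
#' bins contribute neither to the numerator nor the denominator, and a bin
#' whose whole window is masked gets NA.
#'
#' @param profile A [binned_profile()] result.
#' @param window Window width in bp; must be a positive multiple of the
#'   profile resolution (default 5000).
#' @param channel Channel to smooth (default "combined").
#' @return The profile with an added `smoothed` column.
#' @export
smooth_profile <- function(profile, window = 5000, channel = "combined") {
  stopifnot(inherits(profile, "contact_profile"))
  res <- profile$resolution
  if (window < res) stopf("window (%s bp) smaller than resolution (%s bp)",
                          window, res)
  assert_that(window %% res == 0, "window must be a multiple of the resolution")
  k <- window / res
  half <- floor(k / 2)
  x <- profile$bins[[channel]]
  ok <- !profile$bins$masked
  n <- length(x)
  num <- cumsum(c(0, ifelse(ok, x, 0)))
  den <- cumsum(c(0, as.numeric(ok)))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- max(1, i - half)
    b <- min(n, i + half)
    m <- den[b + 1] - den[a]
    if (m > 0) out[i] <- (num[b + 1] - num[a]) / m
  }
  profile$bins$smoothed <- out
  profile
}

#' Write contact-profile channels as bedGraph
#'
#' Writes the raw per-bin channels and, when present, the smoothed channel,
#' with values rounded to 6 decimal places.
#'
#' @param profile A `contact_profile`.
#' @param prefix Output path prefix; files `<prefix>.<channel>.bedgraph`
#'   are created.
#' @param channels Channels to write.
#' @return Invisibly, the paths written.
#' @export
write_profile_bedgraph <- function(profile, prefix,
                                   channels = c("blind", "nonblind",
                                                "combined", "smoothed")) {
  paths <- character(0)
  for (ch in channels) {
    if (is.null(profile$bins[[ch]])) next
    df <- data.frame(chrom = profile$bins$chrom,
                     start = profile$bins$start, end = profile$bins$end,
                     value = profile$bins[[ch]])
    df <- df[!is.na(df$value), , drop = FALSE]
    p <- paste0(prefix, ".", ch, ".bedgraph")
    write_bedgraph(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
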