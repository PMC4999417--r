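# Interval-track and conservation annotation of candidate variants, and
# evidence integration into a ranked candidate report.
#
# Coordinate dialects: variant positions are 1-based (VCF convention);
# BED/bedGraph intervals are 0-based half-open. A variant at 1-based
# position P overlaps [s, e) iff s <= P-1 < e.

#' Read a BED file
#'
#' Minimal BED3/BED4/BED6 reader returning a data frame with 0-based
#' half-open intervals, sorted by start within each chromosome. Malformed
#' lines (start >= end, non-numeric coordinates) raise an error naming the
#' offending line.
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  assert_that(all(nf >= 3), "BED line %d has fewer than 3 fields",
              which(nf < 3)[1])
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stopf("BED line %d: non-numeric coordinates", bad[1])
  bad <- which(start >= end)
  if (length(bad)) stopf("BED line %d: start >= end", bad[1])
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  }
  if (all(nf >= 6)) out$strand <- vapply(fields, `[[`, "", 6)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (columns written in BED order, stopping at
#'   the first absent one).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(intervals)) cols <- c(cols, extra) else break
  }
  df <- intervals[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' Four columns: `chrom start end value`, 0-based half-open. Overlapping
#' intervals on the same chromosome are a dialect violation and rejected.
#'
#' @param path File path.
#' @return Data frame `chrom`, `start`, `end`, `value`, sorted by start
#'   within chromosome.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) stopf("bedGraph line %d: expected 4 fields", which(nf != 4)[1])
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) stopf("bedGraph line %d: non-numeric field", bad[1])
  bad <- which(start >= end)
  if (length(bad)) stopf("bedGraph line %d: start >= end", bad[1])
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1),
                    start = start, end = end, value = value,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  for (ch in unique(out$chrom)) {
    sub <- out[out$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stopf("bedGraph intervals overlap on %s", ch)
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a bedGraph file
#'
#' @param intervals Data frame `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @param digits Values are rounded to this many decimal places (default 6).
#' @export
write_bedgraph <- function(intervals, path, digits = 6) {
  df <- intervals[, c("chrom", "start", "end", "value")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  df$value <- formatC(round(df$value, digits), format = "fg",
                      digits = 15, flag = "-")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Annotate variants with interval tracks and conservation scores
#'
#' Overlays 1-based variant positions on 0-based half-open interval tracks
#' (one logical flag per track) and looks up per-base conservation values
#' from bedGraph channels (NA where uncovered).
#'
#' @param variants Data frame with `id`, `chrom`, `pos` (1-based).
#' @param tracks Named list of BED data frames (see [read_bed()]); names
#'   must be unique.
#' @param conservation Named list of bedGraph data frames.
#' @return Data frame: `variant_id`, one logical column per track, one
#'   numeric column per conservation channel.
#' @export
annotate_variants <- function(variants, tracks = list(),
                              conservation = list()) {
  assert_that(!anyDuplicated(names(tracks)) && !anyDuplicated(names(conservation)),
              "duplicated track names")
  vg <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1)
  )
  out <- data.frame(variant_id = variants$id, stringsAsFactors = FALSE)
  for (nm in names(tracks)) {
    tg <- intervals_to_granges(tracks[[nm]])
    out[[nm]] <- IRanges::overlapsAny(vg, tg)
  }
  for (nm in names(conservation)) {
    cg <- intervals_to_granges(conservation[[nm]])
    hit <- GenomicRanges::findOverlaps(vg, cg, select = "first")
    val <- rep(NA_real_, length(vg))
    cov <- !is.na(hit)
    val[cov] <- conservation[[nm]]$value[hit[cov]]
    out[[nm]] <- val
  }
  out
}

#' Integrate evidence into a ranked candidate report
#'
#' Scores each variant on three binary criteria -- evolutionary conservation
#' (`phastcons >= cons_phastcons_min` or `gerp >= cons_gerp_min`), active
#' enhancer context (DNase AND H3K27ac AND H3K4me1 flags all set), and
#' motif disruption (`|motif_delta| >= motif_delta_min` log2 units) -- and
#' ranks variants by evidence count (descending), association p-value
#' (ascending), then genomic position.
#'
#' @param assoc_results `association_result` data frame (needs
#'   `variant_id`, `pos`, `p_trend`).
#' @param annotations Output of [annotate_variants()]; track columns named
#'   `dnase`, `h3k27ac`, `h3k4me1` feed the enhancer criterion and
#'   conservation channels `phastcons`, `gerp` the conservation criterion.
#' @param motif_deltas Data frame `variant_id`, `delta` (absent variants
#'   score no motif evidence).
#' @param cons_phastcons_min,cons_gerp_min,motif_delta_min Criterion
#'   thresholds (defaults 0.9, 2 and 3).
#' @return Data frame of class `candidate_report`: per-variant criterion
#'   flags, `evidence_count`, association p and `rank` (1 = best).
#' @export
prioritize <- function(assoc_results, annotations, motif_deltas = NULL,
                       cons_phastcons_min = 0.9, cons_gerp_min = 2,
                       motif_delta_min = 3) {
  df <- merge(assoc_results[, c("variant_id", "pos", "p_trend")],
              annotations, by = "variant_id", sort = FALSE)
  getcol <- function(nm, default) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  phast <- getcol("phastcons", NA_real_)
  gerp <- getcol("gerp", NA_real_)
  conserved <- (!is.na(phast) & phast >= cons_phastcons_min) |
    (!is.na(gerp) & gerp >= cons_gerp_min)
  enhancer <- getcol("dnase", FALSE) & getcol("h3k27ac", FALSE) &
    getcol("h3k4me1", FALSE)
  delta <- rep(NA_real_, nrow(df))
  if (!is.null(motif_deltas) && nrow(motif_deltas)) {
    m <- match(df$variant_id, motif_deltas$variant_id)
    delta[!is.na(m)] <- motif_deltas$delta[m[!is.na(m)]]
  }
  motif <- !is.na(delta) & abs(delta) >= motif_delta_min
  report <- data.frame(
    variant_id = df$variant_id, pos = df$pos, p = df$p_trend,
    conserved = conserved, active_enhancer = enhancer,
    motif_disrupting = motif, motif_delta = delta,
    evidence_count = as.integer(conserved) + as.integer(enhancer) +
      as.integer(motif),
    stringsAsFactors = FALSE
  )
  ord <- order(-report$evidence_count, report$p, report$pos)
  report <- report[ord, , drop = FALSE]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  class(report) <- c("candidate_report", "data.frame")
  report
}
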