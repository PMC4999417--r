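# End-to-end orchestration: config handling and the staged pipeline
# (associate -> filter -> proxies -> conditional -> annotate -> motif ->
# eQTL -> prioritize -> 4C profile).

#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]: input paths (relative to
#' `outdir` unless absolute), analysis thresholds and the seed. Threshold
#' defaults mirror the fine-mapping conventions used throughout the
#' package: MAF > 0.01, info >= 0.80, p < 5e-7, proxy r2 > 0.2, FDR 0.05.
#'
#' @param outdir Directory the relative paths are resolved against and the
#'   stage outputs are written to.
#' @param genotypes,probabilities,phenotypes Genotype/phenotype inputs.
#' @param tracks Named list of BED paths.
#' @param conservation Named list of bedGraph paths.
#' @param genome_fasta Locus FASTA; `genome_offset` is the 0-based genomic
#'   coordinate of its first base.
#' @param pfm JASPAR-format motif file.
#' @param reads_4c Mapped 4C reads BED (optional; NULL skips the 4C stage).
#' @param expression Expression matrix path (optional; NULL skips eQTL).
#' @param region 1-based inclusive interval for the conditional scan.
#' @param viewpoint_pos 0-based 4C viewpoint position.
#' @param fourc_mask `c(start, end)` masked interval for the 4C profile.
#' @param maf_min,info_min,p_max,r2_min,fdr,motif_delta_min,cons_phastcons_min,cons_gerp_min
#'   Analysis thresholds.
#' @param fourc_resolution,fourc_window,fourc_exclusion_radius,fourc_min_mapq
#'   4C profiling parameters (bp / quality).
#' @param eqtl_window_bp cis window half-width.
#' @param genome_offset See `genome_fasta`.
#' @param seed Integer seed recorded in output metadata.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            genotypes, phenotypes,
                            probabilities = NULL,
                            tracks = list(), conservation = list(),
                            genome_fasta = NULL, genome_offset = 0,
                            pfm = NULL, reads_4c = NULL, expression = NULL,
                            region = NULL, viewpoint_pos = NULL,
                            fourc_mask = NULL,
                            maf_min = 0.01, info_min = 0.80, p_max = 5.0e-7,
                            r2_min = 0.2, fdr = 0.05,
                            motif_delta_min = 3,
                            cons_phastcons_min = 0.9, cons_gerp_min = 2,
                            fourc_resolution = 100, fourc_window = 5000,
                            fourc_exclusion_radius = 1500,
                            fourc_min_mapq = 30,
                            eqtl_window_bp = 1e6,
                            seed = 1) {
  assert_that(maf_min >= 0 && maf_min < 0.5, "maf_min out of range")
  assert_that(info_min >= 0 && info_min <= 1, "info_min out of range")
  assert_that(p_max > 0 && p_max <= 1, "p_max out of range")
  assert_that(r2_min >= 0 && r2_min <= 1, "r2_min out of range")
  assert_that(fdr > 0 && fdr < 1, "fdr out of range")
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @details A relative `outdir` in a config file (typically `"."`) is
#'   resolved against the config file's own directory on read, so fixture
#'   directories are relocatable.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$tracks <- as.list(raw$tracks)
  raw$conservation <- as.list(raw$conservation)
  cfg <- do.call(pipeline_config, raw)
  if (!grepl("^(/|[A-Za-z]:)", cfg$outdir)) {
    cfg$outdir <- normalizePath(file.path(dirname(path), cfg$outdir))
  }
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

resolve_path <- function(p, outdir) {
  if (is.null(p)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(outdir, p)
}

#' Run the fine-mapping pipeline end-to-end
#'
#' Executes the stages in order -- association scan, QC/significance
#' filter, lead-SNP selection and LD proxies, conditional scan, interval
#' and conservation annotation, motif-disruption scoring, cis-eQTL scan
#' (when expression is configured), evidence prioritization, and the 4C
#' contact profile (when reads are configured). Each stage's output is
#' written under `config$outdir/results` before the next stage begins; a
#' `#config_hash`/`#seed` header line makes every output traceable to its
#' configuration. A stage failure aborts with the stage name; the partial
#' output of the failed stage is kept with a `.partial` suffix.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress the per-stage log lines.
#' @return Invisibly, a list with the `candidate_report`, per-stage results
#'   and the run log.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  hash <- config_hash(cfg)
  resdir <- file.path(cfg$outdir, "results")
  dir.create(resdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("config_hash=%s", hash), sprintf("seed=%d", cfg$seed))
  log <- character(0)
  note <- function(stage, n_in, n_out, t0) {
    line <- sprintf("stage=%s n_in=%d n_out=%d seconds=%.2f", stage, n_in,
                    n_out, as.numeric(Sys.time()) - t0)
    if (!quiet) message(line)
    log <<- c(log, line)
  }
  stage <- function(name, out_file, fun) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fun(), error = function(e) {
      partial <- file.path(resdir, paste0(out_file, ".partial"))
      writeLines(c(paste0("#", hdr),
                   sprintf("#stage %s failed: %s", name,
                           conditionMessage(e))), partial)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    list(result = res, t0 = t0)
  }
  wtsv <- function(df, fname) {
    path <- file.path(resdir, fname)
    con <- file(path, "w")
    writeLines(paste0("#", hdr), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }

  # -- load inputs ---------------------------------------------------------
  table <- read_genotype_table(
    resolve_path(cfg$genotypes, cfg$outdir),
    prob_path = resolve_path(cfg$probabilities, cfg$outdir))
  phenotype <- read_phenotypes(resolve_path(cfg$phenotypes, cfg$outdir))

  # -- association + filter ------------------------------------------------
  st <- stage("associate", "association.tsv",
              function() associate_variants(table, phenotype))
  assoc <- st$result
  wtsv(assoc, "association.tsv")
  note("associate", ncol(table$dosages), nrow(assoc), st$t0)

  st <- stage("filter", "association_filtered.tsv", function()
    filter_variants(assoc, cfg$maf_min, cfg$info_min, cfg$p_max))
  survivors <- st$result
  wtsv(survivors, "association_filtered.tsv")
  note("filter", nrow(assoc), nrow(survivors), st$t0)

  # -- lead + proxies ------------------------------------------------------
  lead_id <- assoc$variant_id[which.min(assoc$p_trend)]
  st <- stage("proxies", "ld_proxies.tsv",
              function() ld_proxies(table, lead_id, cfg$r2_min))
  proxies <- st$result
  wtsv(proxies, "ld_proxies.tsv")
  note("proxies", nrow(assoc) - 1L, nrow(proxies), st$t0)

  # -- conditional scan ----------------------------------------------------
  region <- cfg$region %||% range(table$variants$pos)
  st <- stage("conditional", "conditional.tsv", function()
    conditional_scan(table, phenotype, lead_id, region))
  conditional <- st$result
  wtsv(conditional, "conditional.tsv")
  note("conditional", nrow(assoc) - 1L, nrow(conditional), st$t0)

  # -- annotation ----------------------------------------------------------
  st <- stage("annotate", "annotations.tsv", function() {
    tracks <- lapply(cfg$tracks,
                     function(p) read_bed(resolve_path(p, cfg$outdir)))
    cons <- lapply(cfg$conservation,
                   function(p) read_bedgraph(resolve_path(p, cfg$outdir)))
    annotate_variants(table$variants, tracks, cons)
  })
  annotations <- st$result
  wtsv(annotations, "annotations.tsv")
  note("annotate", nrow(table$variants), nrow(annotations), st$t0)

  # -- motif disruption ----------------------------------------------------
  motif <- NULL
  if (!is.null(cfg$pfm) && !is.null(cfg$genome_fasta)) {
    st <- stage("motif", "motif_disruption.tsv", function() {
      pwms <- load_jaspar(resolve_path(cfg$pfm, cfg$outdir))
      fa <- Biostrings::readDNAStringSet(
        resolve_path(cfg$genome_fasta, cfg$outdir))
      motif_disruption_scan(table$variants, as.character(fa[[1]]),
                            cfg$genome_offset, pwms[[1]])
    })
    motif <- st$result
    wtsv(motif, "motif_disruption.tsv")
    note("motif", nrow(table$variants), nrow(motif), st$t0)
  }

  # -- eQTL ----------------------------------------------------------------
  eqtl <- NULL
  if (!is.null(cfg$expression)) {
    st <- stage("eqtl", "eqtl.tsv", function() {
      expr <- read_expression_matrix(resolve_path(cfg$expression, cfg$outdir))
      eqtl_scan(expr, table, snp_id = lead_id,
                window_bp = cfg$eqtl_window_bp)
    })
    eqtl <- st$result
    wtsv(eqtl, "eqtl.tsv")
    note("eqtl", length(table$sample_ids), nrow(eqtl), st$t0)
  }

  # -- prioritization ------------------------------------------------------
  st <- stage("prioritize", "candidate_report.tsv", function() {
    cand_ids <- unique(c(survivors$variant_id, lead_id, proxies$variant_id))
    prioritize(assoc[assoc$variant_id %in% cand_ids, , drop = FALSE],
               annotations[annotations$variant_id %in% cand_ids, ,
                           drop = FALSE],
               if (is.null(motif)) NULL else
                 data.frame(variant_id = motif$variant_id,
                            delta = motif$delta),
               cons_phastcons_min = cfg$cons_phastcons_min,
               cons_gerp_min = cfg$cons_gerp_min,
               motif_delta_min = cfg$motif_delta_min)
  })
  report <- st$result
  # join conditional p and r2-to-lead into the report
  report$p_conditional <-
    conditional$p_conditional[match(report$variant_id,
                                    conditional$variant_id)]
  report$r2_lead <- ifelse(report$variant_id == lead_id, 1,
                           proxies$r2[match(report$variant_id,
                                            proxies$variant_id)])
  if (!is.null(eqtl)) {
    top_gene <- eqtl[which.min(eqtl$q), ]
    report$eqtl_top_gene <- top_gene$gene_id
    report$eqtl_top_q <- top_gene$q
  }
  wtsv(report, "candidate_report.tsv")
  jsonlite::write_json(
    list(config_hash = hash, seed = cfg$seed, lead = lead_id,
         report = report),
    file.path(resdir, "candidate_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  note("prioritize", nrow(assoc), nrow(report), st$t0)

  # -- 4C profile ----------------------------------------------------------
  profile <- NULL
  if (!is.null(cfg$reads_4c) && !is.null(cfg$genome_fasta)) {
    st <- stage("fourc", "profile_4c", function() {
      fmap <- build_fragment_map(resolve_path(cfg$genome_fasta, cfg$outdir),
                                 offset = cfg$genome_offset)
      reads <- read_bed(resolve_path(cfg$reads_4c, cfg$outdir))
      masked <- if (is.null(cfg$fourc_mask)) NULL else
        data.frame(start = cfg$fourc_mask[1], end = cfg$fourc_mask[2])
      counts <- assign_reads(reads, fmap, min_mapq = cfg$fourc_min_mapq,
                             viewpoint = cfg$viewpoint_pos,
                             exclusion_radius = cfg$fourc_exclusion_radius,
                             masked = masked)
      prof <- binned_profile(counts, fmap,
                             resolution = cfg$fourc_resolution,
                             masked = masked)
      smooth_profile(prof, window = cfg$fourc_window)
    })
    profile <- st$result
    write_profile_bedgraph(profile, file.path(resdir, "profile_4c"))
    note("fourc", 1L, nrow(profile$bins), st$t0)
  }

  invisible(list(report = report, association = assoc,
                 survivors = survivors, lead_id = lead_id,
                 proxies = proxies, conditional = conditional,
                 annotations = annotations, motif = motif, eqtl = eqtl,
                 profile = profile, config_hash = hash, log = log))
}
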