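#' Pipeline configuration
#'
#' Bundles a [simulation_config()] (or paths to pre-written fixtures)
#' with the analysis thresholds and batch definitions used by
#' [run_pipeline()]. All thresholds default to the values used throughout
#' the package: QC at MAF >= 0.005 and R2 >= 0.8, low-correlation
#' flagging below 0.9, high-correlation controls above 0.97, annotation
#' proximity 0.5 Mb.
#'
#' @param simulation a [simulation_config()], or a list of arguments for
#'   one. A seed is mandatory whenever simulation is requested.
#' @param thresholds named list overriding `low_r`, `high_r`,
#'   `proximity_bp`, `maf_min`, `r2_min`, `alpha`.
#' @param ancestries ancestries tested in the admixture-mapping scan.
#' @param replication_n size of the replication batch (0 disables the
#'   second batch); the replication cohort shares all genetic parameters
#'   and differs only in its sample draw (seed substream).
#' @param threshold_method multiple-testing method for
#'   [significance_threshold()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            thresholds = list(),
                            ancestries = c("African", "Amerindian"),
                            replication_n = 0L,
                            threshold_method = "bonferroni_effective") {
  if (is.list(simulation) && !inherits(simulation, "simulation_config"))
    simulation <- do.call(simulation_config, simulation)
  stopifnot(inherits(simulation, "simulation_config"))
  if (is.null(simulation$seed) || is.na(simulation$seed))
    abort_config("a seed is mandatory when simulation is requested")
  th <- utils::modifyList(list(low_r = 0.9, high_r = 0.97,
                               proximity_bp = 500000, maf_min = 0.005,
                               r2_min = 0.8, alpha = 0.05), thresholds)
  stopifnot(th$low_r > 0, th$low_r < 1, th$high_r > 0, th$high_r < 1,
            th$proximity_bp >= 0)
  structure(list(simulation = simulation, thresholds = th,
                 ancestries = ancestries,
                 replication_n = as.integer(replication_n),
                 threshold_method = threshold_method),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a declarative YAML file
#'
#' The file holds a `simulation` block (arguments of
#' [simulation_config()]; `problem_regions` and `leak_matrix` as lists of
#' rows), optional `thresholds`, `ancestries`, `replication_n` and
#' `threshold_method` entries. Every threshold defaults as in
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulation %||% list()
  for (f in c("chrom_lengths_bp", "base_miscall_rate", "group_weights"))
    if (!is.null(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
  if (!is.null(sim$leak_matrix))
    sim$leak_matrix <- do.call(rbind, sim$leak_matrix)
  if (!is.null(sim$problem_regions))
    sim$problem_regions <- do.call(rbind, lapply(sim$problem_regions,
                                                 as.data.frame))
  if (!is.null(sim$phenotype_spec)) {
    ps <- sim$phenotype_spec
    for (f in c("variances", "household_size_probs", "beta"))
      if (!is.null(ps[[f]])) ps[[f]] <- unlist(ps[[f]])
    sim$phenotype_spec <- ps
  }
  pipeline_config(
    simulation = do.call(simulation_config, sim),
    thresholds = y$thresholds %||% list(),
    ancestries = unlist(y$ancestries) %||% c("African", "Amerindian"),
    replication_n = y$replication_n %||% 0L,
    threshold_method = y$threshold_method %||% "bonferroni_effective")
}

#' Run the full concordance and mapping pipeline
#'
#' Executes the stages in dependency order on a synthetic cohort:
#' simulate tracts and both observation channels, write the fixture set,
#' QC-filter the SNP channel, lift the interval channel to the SNP build,
#' match SNPs to intervals, profile per-pair correlations, flag and merge
#' low-correlation regions, run the annotation enrichment contrast, fit
#' the null mixed model, scan both channels for the tested ancestries,
#' estimate the significance threshold, and build the top-hit comparison
#' table (with a replication batch when configured). Every stage output
#' is written as TSV/BED/VCF under `outdir`, and a JSON manifest records
#' the config hash, seed and per-file checksums; identical config and
#' seed reproduce identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param force rerun even if a manifest with the same config hash exists.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, outdir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$simulation
  th <- config$thresholds
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  cfg_hash <- config_hash(config)
  man_path <- file.path(outdir, "pipeline_manifest.json")
  if (!force && file.exists(man_path)) {
    old <- jsonlite::read_json(man_path)
    if (identical(old$config_hash, cfg_hash)) {
      message("pipeline outputs up to date (matching config hash); skipping")
      return(invisible(list(manifest = old, skipped = TRUE)))
    }
  }
  log_stage <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                                  format(Sys.time(), "%H:%M:%S"),
                                                  ...))
  log_stage("simulate: %d individuals, %d chromosome(s)",
            sim$n_individuals, length(sim$chrom_lengths_bp))
  panel <- simulate_tracts(sim)
  intervals <- observe_intervals(panel, sim)
  snps <- observe_snps(panel, sim)
  pheno <- simulate_phenotype(panel, snps, sim)
  map <- make_liftover_map(sim)
  annot <- annotations_from_config(sim)
  fixdir <- file.path(outdir, "fixtures")
  write_fixture_set(fixdir, intervals, snps, pheno, map,
                    if (length(annot) > 0) annot, sim)
  log_stage("qc: filtering SNPs at MAF >= %g, R2 >= %g", th$maf_min,
            th$r2_min)
  snps_qc <- filter_snps(snps, th$maf_min, th$r2_min)
  qc <- qc_report(snps_qc)
  log_stage("qc: kept %d / %d SNPs (%.2f%%)", qc$n_kept, qc$n_input,
            100 * qc$kept_fraction)
  lift <- apply_liftover(intervals, map)
  log_stage("liftover: converted %d / %d intervals (%.2f%%)",
            lift$report$n_converted, lift$report$n_input,
            lift$report$conversion_pct)
  match <- match_snps_to_intervals(snps_qc, lift$calls)
  log_stage("match: %d / %d SNPs matched (%.2f%%)", match$n_matched,
            match$n_snps, 100 * match$match_rate)
  cors <- pair_correlations(match, snps_qc, lift$calls)
  summ <- genome_summary(cors)
  flagged <- flag_low_pairs(cors, th$low_r)
  regions <- merge_regions(flagged)
  log_stage("concordance: %d pairs flagged below r = %g (%.2f%%), %d merged regions",
            nrow(flagged), th$low_r,
            100 * attr(flagged, "flagged_fraction"), nrow(regions))
  enrich <- NULL
  if (length(annot) > 0 && nrow(flagged) > 0) {
    low_asn <- map_pairs_to_annotations(flagged, annot, th$proximity_bp)
    ctrl <- try(sample_matched_high_pairs(cors, nrow(flagged), th$high_r,
                                          seed = stage_seed(sim$seed,
                                                            "controls")),
                silent = TRUE)
    if (!inherits(ctrl, "try-error")) {
      ctrl_asn <- map_pairs_to_annotations(ctrl, annot, th$proximity_bp)
      enrich <- enrichment_summary(low_asn, ctrl_asn)
    }
  }
  log_stage("mapping: fitting null mixed model (n = %d)", nrow(pheno$data))
  null <- fit_null_model(pheno)
  scans <- list(interval = scan_ancestry(null, lift$calls, config$ancestries),
                snp = scan_ancestry(null, snps_qc, config$ancestries))
  thr <- significance_threshold(snps_qc, null,
                                method = config$threshold_method,
                                alpha = th$alpha,
                                ancestries = config$ancestries,
                                seed = stage_seed(sim$seed, "permutation"))
  top_regions <- top_scan_regions(scans$interval, thr$threshold)
  comparison <- NULL
  if (config$replication_n > 0L) {
    sim2 <- sim
    sim2$n_individuals <- config$replication_n
    sim2$seed <- stage_seed(sim$seed, "batch2")
    panel2 <- simulate_tracts(sim2)
    snps2 <- filter_snps(observe_snps(panel2, sim2), th$maf_min, th$r2_min)
    int2 <- apply_liftover(observe_intervals(panel2, sim2), map)$calls
    pheno2 <- simulate_phenotype(panel2, snps2, sim2)
    null2 <- fit_null_model(pheno2)
    scans$interval_b2 <- scan_ancestry(null2, int2, config$ancestries)
    scans$snp_b2 <- scan_ancestry(null2, snps2, config$ancestries)
  }
  if (nrow(top_regions) > 0) comparison <- compare_top_hits(scans, top_regions)
  write_outputs(outdir, summ, flagged, regions, enrich, scans, thr,
                comparison, cors)
  manifest <- list(config_hash = cfg_hash, seed = sim$seed,
                   package_version = as.character(utils::packageVersion("laconcord")),
                   qc = qc[c("n_input", "n_kept")],
                   liftover = lift$report[c("n_input", "n_converted")],
                   match = match[c("n_snps", "n_matched")],
                   files = output_checksums(outdir))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(panel = panel, intervals = intervals, snps = snps_qc,
                 phenotype = pheno, liftover = lift, match = match,
                 correlations = cors, summary = summ, flagged = flagged,
                 regions = regions, enrichment = enrich, null = null,
                 scans = scans, threshold = thr, comparison = comparison,
                 manifest = manifest, outdir = outdir))
}

## regions around the most significant scan loci: significant loci padded
## by 1 Mb and merged; falls back to the single top locus when nothing
## clears the threshold
top_scan_regions <- function(scan, threshold, pad = 1e6) {
  ok <- scan[!scan$untestable & !is.na(scan$p), , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  sig <- ok[ok$p <= threshold, , drop = FALSE]
  if (nrow(sig) == 0L) sig <- ok[which.min(ok$p), , drop = FALSE]
  merge_regions(data.frame(chrom = sig$chrom,
                           start = pmax(1, sig$pos - pad),
                           end = sig$end + pad))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.matrix(x)) apply(x, 1, identity, simplify = FALSE)
  else unclass(x)
}

write_outputs <- function(outdir, summ, flagged, regions, enrich, scans,
                          thr, comparison, cors) {
  write_tsv(summ$overall, file.path(outdir, "genome_summary.tsv"))
  write_tsv(summ$by_chrom, file.path(outdir, "genome_summary_by_chrom.tsv"))
  write_tsv(as.data.frame(cors), file.path(outdir, "pair_correlations.tsv"))
  write_tsv(flagged, file.path(outdir, "flagged_pairs.tsv"))
  write_tsv(regions, file.path(outdir, "low_correlation_regions.tsv"))
  for (nm in names(scans))
    write_tsv(as.data.frame(scans[[nm]]),
              file.path(outdir, sprintf("scan_%s.tsv", nm)))
  thr_df <- data.frame(method = thr$method, alpha = thr$alpha,
                       threshold = thr$threshold,
                       m_eff = thr$m_eff_total %||% NA_integer_,
                       B = thr$B %||% NA_integer_)
  write_tsv(thr_df, file.path(outdir, "significance_threshold.tsv"))
  if (!is.null(enrich)) {
    classes <- enrich$class_labels
    edf <- do.call(rbind, lapply(c("low", "control"), function(gr) {
      g <- enrich[[gr]]
      row <- data.frame(group = gr, n_pairs = g$n_pairs,
                        n_mapped = g$n_mapped, pct_mapped = g$pct_mapped,
                        unique_regions = g$unique_regions_hit)
      for (cl in classes) {
        row[[paste0("n_", cl)]] <- g$classes[[cl]]$n
        row[[paste0("pct_", cl)]] <- g$classes[[cl]]$pct_of_mapped
      }
      row
    }))
    write_tsv(edf, file.path(outdir, "enrichment_report.tsv"))
  }
  if (!is.null(comparison))
    write_tsv(as.data.frame(comparison),
              file.path(outdir, "top_hit_comparison.tsv"))
}

output_checksums <- function(outdir) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "pipeline_manifest.json"))
  data.frame(file = files,
             md5 = unname(tools::md5sum(file.path(outdir, files))))
}

#' Human-readable pipeline report
#'
#' Renders the genome summary, enrichment contrast, threshold and top-hit
#' comparison of a completed [run_pipeline()] run as aligned text.
#' Regenerating the report from the saved outputs reproduces it exactly.
#'
#' @param outdir the pipeline output directory.
#' @return The report lines, invisibly; printed to the console.
#' @export
pipeline_report <- function(outdir) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  man <- jsonlite::read_json(file.path(outdir, "pipeline_manifest.json"))
  add("laconcord pipeline report (seed %s, config %s)", man$seed,
      substr(man$config_hash, 1, 8))
  add("QC: kept %s / %s SNPs; liftover: %s / %s intervals; match: %s / %s SNPs",
      man$qc$n_kept, man$qc$n_input, man$liftover$n_converted,
      man$liftover$n_input, man$match$n_matched, man$match$n_snps)
  gs <- read_tsv(file.path(outdir, "genome_summary.tsv"))
  add("per-ancestry pair correlations:")
  for (i in seq_len(nrow(gs)))
    add("  %-14s mean r = %.3f (SD = %.3f, %d pairs, %d undefined)",
        gs$ancestry[i], gs$mean_r[i], gs$sd_r[i], gs$n_pairs[i],
        gs$n_undefined[i])
  ep <- file.path(outdir, "enrichment_report.tsv")
  if (file.exists(ep)) {
    ed <- read_tsv(ep)
    for (i in seq_len(nrow(ed)))
      add("enrichment [%s]: %d pairs, %d mapped (%.2f%%)", ed$group[i],
          ed$n_pairs[i], ed$n_mapped[i], ed$pct_mapped[i])
  }
  td <- read_tsv(file.path(outdir, "significance_threshold.tsv"))
  add("significance threshold (%s): %.3g", td$method[1], td$threshold[1])
  cp <- file.path(outdir, "top_hit_comparison.tsv")
  if (file.exists(cp)) {
    cd <- read_tsv(cp)
    if (nrow(cd) == 0) add("no testable loci in any comparison region")
    for (i in seq_len(nrow(cd)))
      add("top hit [%s | %s | %s]: %s at %s (p = %.3g)", cd$region_id[i],
          cd$channel[i], cd$ancestry[i],
          ifelse(cd$all_untestable[i], "untestable", cd$id[i]),
          ifelse(cd$all_untestable[i], "-", format(cd$pos[i])), cd$p[i])
  } else add("no testable loci in any comparison region")
  cat(lines, sep = "\n")
  invisible(lines)
}
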