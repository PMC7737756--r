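#' Run the full ctDNA monitoring pipeline on a cohort directory
#'
#' End-to-end orchestration from raw tables to a cohort report: build the
#' background error model from the healthy pool, denoise every sample
#' against the WBC database and the model, extract per-sample features,
#' call molecular progression and lead times, detect alterations emerging at
#' progression relative to baseline, and compute the stratified outcome
#' analysis. Every filtering step logs counts; patients failing timeline
#' invariants are excluded and logged, never silently dropped. Given the
#' same inputs the report is byte-identical (no randomness is involved).
#'
#' The expected input layout is the one [emit_cohort()] writes:
#' `samples/<sample_id>.tsv` variant tables, `copy_ratios.tsv`,
#' `clinical.csv`, `wbc_database.tsv`, `healthy/*.tsv`, and optionally
#' `driver_catalogue.tsv`.
#'
#' @param input_dir Cohort directory.
#' @param out_dir Optional output directory; when given, writes
#'   `features.tsv`, `denoise_log.tsv`, `progression_calls.tsv`,
#'   `ratio_trajectories.tsv`, `outcomes.json` and `summary.txt`.
#' @param panel A [panel_definition()]; its driver catalogue is replaced by
#'   `driver_catalogue.tsv` when that file exists in `input_dir`.
#' @param thresholds A [threshold_config()]; echoed into the report.
#' @param consecutive,min_samples Monitoring rule options, see
#'   [call_ctdna_pd()].
#' @param verbose Log stage counts to stderr via [message()].
#' @return List of class `ctdna_report` with `features`, `removal_log`,
#'   `monitor`, `outcomes`, `emerging`, `thresholds`, `counts`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL,
                         panel = panel_definition(),
                         thresholds = threshold_config(),
                         consecutive = TRUE, min_samples = 3,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  inp <- read_cohort_inputs(input_dir)
  if (!is.null(inp$driver_catalogue))
    panel <- panel_definition(panel$genes, panel$coding_footprint_mb,
                              driver_catalogue = inp$driver_catalogue)
  say("stage=background_model healthy_samples=%d",
      length(inp$healthy_pool))
  model <- build_background_model(inp$healthy_pool)
  say("stage=denoise_features samples=%d", nrow(inp$clinical))
  cf <- cohort_features(inp$variant_tables, inp$copy_ratios, inp$clinical,
                        inp$wbc_db, model, panel, thresholds,
                        verbose = FALSE)
  n_in <- sum(vapply(inp$variant_tables, function(v)
    if (is.character(v)) nrow(read_variant_table(v)) else nrow(v),
    numeric(1)))
  say("stage=denoise variants_in=%d removed=%d", n_in,
      if (is.null(cf$removal_log)) 0L else nrow(cf$removal_log))
  mon <- monitor_cohort(cf$features, thresholds, consecutive, min_samples)
  say("stage=monitor progressors=%d excluded=%d",
      mon$summary$n_monitored,
      if (is.null(mon$excluded)) 0L else nrow(mon$excluded))
  out <- cohort_outcomes(cf$features, thresholds)
  emg <- emerging_by_patient(cf, inp$copy_ratios, mon, thresholds)
  say("stage=emerging patients_with_new_alterations=%d",
      sum(vapply(emg, function(e)
        nrow(e$variants) + nrow(e$cnv) > 0, logical(1))))
  report <- structure(list(
    features = cf$features, removal_log = cf$removal_log,
    monitor = mon, outcomes = out, emerging = emg,
    thresholds = unclass(thresholds),
    counts = list(samples = nrow(inp$clinical),
                  patients = length(unique(inp$clinical$patient_id)),
                  variants_in = n_in,
                  variants_removed = if (is.null(cf$removal_log)) 0L
                    else nrow(cf$removal_log))
  ), class = "ctdna_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Resolve the on-disk cohort layout into the tables the stages consume.
read_cohort_inputs <- function(input_dir) {
  need <- function(p) {
    if (!file.exists(p)) stop(sprintf("missing input: %s", p),
                              call. = FALSE)
    p
  }
  hfiles <- sort(list.files(file.path(input_dir, "healthy"),
                            full.names = TRUE))
  if (!length(hfiles)) stop("no healthy-pool tables found", call. = FALSE)
  vfiles <- sort(list.files(file.path(input_dir, "samples"),
                            pattern = "\\.(tsv|vcf)$", full.names = TRUE))
  variant_tables <- as.list(stats::setNames(
    vfiles, sub("\\.(tsv|vcf)$", "", basename(vfiles))))
  drv_path <- file.path(input_dir, "driver_catalogue.tsv")
  list(
    healthy_pool = lapply(hfiles, read_variant_table),
    wbc_db = read_wbc_database(need(file.path(input_dir,
                                              "wbc_database.tsv"))),
    variant_tables = variant_tables,
    copy_ratios = read_copy_ratios(need(file.path(input_dir,
                                                  "copy_ratios.tsv"))),
    clinical = read_clinical(need(file.path(input_dir, "clinical.csv"))),
    driver_catalogue = if (file.exists(drv_path))
      read_driver_catalogue(drv_path) else NULL
  )
}

# Baseline-vs-progression emerging alterations for every monitored
# progressor: the progression sample is the last draw on or after the
# earliest PD call (molecular or imaging).
emerging_by_patient <- function(cf, copy_ratios, mon, thresholds) {
  if (is.null(mon$calls) || !nrow(mon$calls)) return(list())
  out <- list()
  for (pid in unique(mon$calls$patient_id)) {
    x <- cf$features[cf$features$patient_id == pid, , drop = FALSE]
    x <- x[order(x$date), , drop = FALSE]
    bl_sid <- x$sample_id[1]
    pd_sid <- x$sample_id[nrow(x)]
    cr <- function(sid) copy_ratios[copy_ratios$sample_id == sid,
                                    c("gene", "fold")]
    out[[pid]] <- detect_emerging_alterations(
      cf$denoised[[bl_sid]], cf$denoised[[pd_sid]],
      bl_cnv = cr(bl_sid), pd_cnv = cr(pd_sid), thresholds = thresholds)
  }
  out
}

#' Write a pipeline report bundle to disk
#'
#' @param report A `ctdna_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  feats <- report$features
  feats$date <- format(as.Date(feats$date))
  wt(feats, "features.tsv")
  wt(report$removal_log, "denoise_log.tsv")
  calls <- report$monitor$calls
  if (!is.null(calls)) calls$date <- format(as.Date(calls$date))
  wt(calls, "progression_calls.tsv")
  rt <- report$monitor$ratios
  if (!is.null(rt)) rt$date <- format(as.Date(rt$date))
  wt(rt, "ratio_trajectories.tsv")
  out <- report$outcomes
  emg_summary <- lapply(report$emerging, function(e)
    list(new_variants = nrow(e$variants), new_cnv = nrow(e$cnv),
         variant_keys = if (nrow(e$variants)) variant_key(e$variants)
           else character(0)))
  jsonlite::write_json(list(
    thresholds = report$thresholds,
    counts = report$counts,
    overall = out$overall,
    lead_time = report$monitor$summary,
    excluded = report$monitor$excluded,
    by_baseline_stratum = out$by_baseline_stratum,
    by_dynamics = out$by_dynamics,
    concordance = if (!is.null(out$concordance))
      out$concordance[c("n", "agreement_pct", "kappa", "p")] else NULL,
    correlation = out$correlation,
    emerging = emg_summary
  ), file.path(out_dir, "outcomes.json"),
  auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.ctdna_report <- function(x, ...) {
  o <- x$outcomes$overall
  s <- x$monitor$summary
  cat("ctDNA monitoring report\n")
  cat(sprintf("  patients: %d, samples: %d, variants in/removed: %d/%d\n",
              x$counts$patients, x$counts$samples, x$counts$variants_in,
              x$counts$variants_removed))
  cat(sprintf("  ORR %.1f%% (%d/%d), DCR %.1f%% (%d/%d), mPFS %s\n",
              o$orr_pct, o$orr_n, o$n, o$dcr_pct, o$dcr_n, o$n,
              ifelse(is.na(o$mpfs_months), "not reached",
                     sprintf("%.2f months", o$mpfs_months))))
  cat(sprintf(
    "  ctDNA PD ahead of CT in %d/%d (%.1f%%), mean advance %.1f days\n",
    s$ctdna$ahead_n, s$n_monitored, s$ctdna$ahead_fraction_pct,
    ifelse(is.na(s$ctdna$mean_advance_days), NA,
           s$ctdna$mean_advance_days)))
  cat(sprintf(
    "  CEA PD ahead of CT in %d/%d (%.1f%%), mean advance %.1f days\n",
    s$cea$ahead_n, s$n_monitored, s$cea$ahead_fraction_pct,
    ifelse(is.na(s$cea$mean_advance_days), NA, s$cea$mean_advance_days)))
  if (!is.null(x$outcomes$concordance))
    cat(sprintf("  plasma-tissue ERBB2 concordance %.1f%% (kappa %.3f)\n",
                x$outcomes$concordance$agreement_pct,
                x$outcomes$concordance$kappa))
  invisible(x)
}
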