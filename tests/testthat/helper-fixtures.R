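# Small builders and independent brute-force oracles shared across tests.

mk_variants <- function(af, gene = "CCNE1", chrom = "chr4", pos = NULL,
                        effect = "missense", depth = 2000) {
  n <- length(af)
  if (is.null(pos)) pos <- 4000100L + 10L * seq_len(n)
  data.frame(chrom = rep_len(chrom, max(n, 1))[seq_len(n)], pos = pos,
             ref = rep_len("A", n), alt = rep_len("T", n),
             gene = rep_len(gene, max(n, 1))[seq_len(n)],
             effect = rep_len(effect, max(n, 1))[seq_len(n)], af = af,
             alt_reads = as.integer(round(af * depth)),
             depth = rep_len(as.integer(depth), n),
             stringsAsFactors = FALSE)
}

# healthy tables for an explicit per-site AF matrix (sites x individuals)
mk_healthy_pool <- function(af_matrix, sites) {
  lapply(seq_len(ncol(af_matrix)), function(j) {
    data.frame(sites, af = af_matrix[, j],
               alt_reads = as.integer(round(af_matrix[, j] * 2000)),
               depth = 2000L, stringsAsFactors = FALSE)
  })
}

mk_sites <- function(n, gene = "CCNE1", chrom = "chr4") {
  data.frame(chrom = rep_len(chrom, n), pos = 4000100L + 10L * seq_len(n),
             ref = rep_len("A", n), alt = rep_len("T", n),
             gene = rep_len(gene, n), effect = rep_len("missense", n),
             stringsAsFactors = FALSE)
}

tiny_config <- function(...) {
  simulation_config(
    n_patients = 4, n_healthy_pool = 5, n_wbc_samples = 20,
    panel = panel_definition(genes = c("ERBB2", "TP53", "KRAS", "CCNE1")),
    sites_per_gene = 4, ...)
}

mk_timeline <- function(tmb = NULL, erbb2 = NULL, tcl = NULL, cea = NULL,
                        n = NULL, start = as.Date("2018-01-01"), by = 42) {
  n <- max(length(tmb), length(erbb2), length(tcl), length(cea), n)
  data.frame(date = start + by * (seq_len(n) - 1),
             erbb2_fold = if (is.null(erbb2)) rep(1, n) else erbb2,
             tcl = if (is.null(tcl)) rep(0, n) else tcl,
             tmb = if (is.null(tmb)) rep(0, n) else tmb,
             cea_ng_ml = if (is.null(cea)) rep(1, n) else cea)
}

# Brute-force reimplementation of the two denoising rules, variant by
# variant, with explicit lookups.
oracle_denoise <- function(variants, wbc_db, model, max_rec = 0.10, k = 3) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
    occ <- 0
    j <- which(wbc_db$occurrence$key == key)
    if (length(j)) occ <- wbc_db$occurrence$count[j[1]]
    if (occ / wbc_db$total_samples > max_rec) next
    m <- which(model$sites$key == key)
    mu <- if (length(m)) model$sites$mean_af[m[1]] else model$fallback$mean_af
    s <- if (length(m)) model$sites$sd_af[m[1]] else model$fallback$sd_af
    keep[i] <- v$af > mu + k * s
  }
  variants[keep, , drop = FALSE]
}

# Brute-force scan over all candidate progression points of a ratio table
# (date + feature columns in priority order).
oracle_pd <- function(ratios, consecutive = TRUE, require_reset = TRUE) {
  feats <- setdiff(names(ratios), "date")
  best <- NULL
  for (f in feats) {
    a <- ratios[[f]] > 1
    n <- length(a)
    for (i in seq_len(n)) {
      if (i < 2) next
      qualifies <- if (consecutive) i < n && a[i] && a[i + 1]
                   else a[i] && sum(a[i:n]) >= 2
      reset <- !require_reset || any(!a[seq_len(i - 1)])
      if (qualifies && reset) {
        if (is.null(best) || i < best$i) best <- list(i = i, trigger = f)
        break
      }
    }
  }
  best
}

# In-memory pipeline over a simulated cohort (no disk round trip): the same
# stage composition run_pipeline() performs on files.
run_cohort_inmemory <- function(coh, thresholds = threshold_config()) {
  model <- build_background_model(coh$healthy_pool)
  vt <- split(coh$variants[setdiff(names(coh$variants), "sample_id")],
              coh$variants$sample_id)
  cf <- cohort_features(vt, coh$copy_ratios, coh$clinical, coh$wbc_db,
                        model, coh$analysis_panel, thresholds)
  mon <- monitor_cohort(cf$features, thresholds)
  list(features = cf$features, denoised = cf$denoised,
       removal_log = cf$removal_log, monitor = mon)
}

# Per-patient comparison of the pipeline's ctDNA-PD call with the call the
# same rule makes on the noise-free feature trajectory (the recovery truth).
recovery_table <- function(coh, mon) {
  iv <- coh$config$sampling_interval_days
  rows <- lapply(coh$patients, function(p) {
    tr <- p$truth
    if (is.na(tr$radiologic_pd_day) || length(tr$sample_days) < 3)
      return(NULL)
    tf <- truth_features(tr)
    tf$date <- as.Date(tr$enroll_date) + tf$day
    tcall <- call_ctdna_pd(tf)$call
    if (is.null(tcall)) return(NULL)
    truth_day <- as.numeric(tcall$date - as.Date(tr$enroll_date))
    row <- mon$calls[mon$calls$patient_id == tr$patient_id &
                       mon$calls$source == "ctdna", ]
    call_day <- if (!is.null(row) && nrow(row))
      as.numeric(row$date - as.Date(tr$enroll_date)) else NA_real_
    lead <- if (!is.null(row) && nrow(row)) row$lead_days else NA_real_
    data.frame(patient_id = tr$patient_id, truth_day = truth_day,
               call_day = call_day, lead_days = lead,
               within_one_interval = !is.na(call_day) &&
                 abs(call_day - truth_day) <= iv)
  })
  do.call(rbind, rows)
}
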