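rbind_all <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

#' Normalize a feature series to its cutoff
#'
#' Divides each value by the feature's cutoff so that a ratio above 1 means
#' the feature is above its cutoff (ERBB2 copy ratio / 1.4, TCL / 2,
#' TMB / 8.5, CEA / 5 under the defaults).
#'
#' @param values Numeric series.
#' @param cutoff Positive cutoff.
#' @return `values / cutoff`.
#' @export
relative_fold_series <- function(values, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  values / cutoff
}

# Earliest qualifying run start among post-baseline points. `above` is a
# logical vector over the date-ordered samples (index 1 = baseline, which can
# never be the progression point). Consecutive rule: first post-baseline
# index i with above[i] and above[i + 1]. Non-consecutive rule: first
# post-baseline point above, provided at least two post-baseline points are
# above anywhere in the series. With `require_reset` (the default), a run
# only qualifies when the feature sat at or below its cutoff at some earlier
# time point: progression is a re-elevation, so a feature that has stayed
# elevated since baseline while the patient responds carries no transition
# to call.
first_qualifying_index <- function(above, consecutive = TRUE,
                                   require_reset = TRUE) {
  n <- length(above)
  if (n < 3) return(NA_integer_)
  reset_ok <- function(i) !require_reset || any(!above[seq_len(i - 1)])
  if (consecutive) {
    for (i in 2:(n - 1))
      if (above[i] && above[i + 1] && reset_ok(i)) return(i)
    return(NA_integer_)
  }
  cand <- which(above & seq_len(n) >= 2)
  cand <- cand[vapply(cand, reset_ok, logical(1))]
  for (i in cand) if (sum(above[i:n]) >= 2) return(i)
  NA_integer_
}

#' Call ctDNA-based progression from a feature timeline
#'
#' Scans the date-ordered post-baseline samples of one patient: if any of
#' the three genomic features (ERBB2 copy ratio, TCL, TMB) is elevated
#' strictly beyond its cutoff at two or more consecutive time points, the
#' first point of the earliest such run is the ctDNA-based progression (PD)
#' date. Ties between features qualifying at the same date are broken in the
#' fixed order ERBB2 CNV, TCL, TMB. Patients with fewer than `min_samples`
#' plasma samples are excluded (matching the monitoring inclusion rule of at
#' least three specimens). The baseline itself can never be the PD point,
#' and by default a feature triggers only once it re-elevates after having
#' been at or below its cutoff (`require_reset`): a feature that remains
#' elevated from baseline onward shows no progression transition.
#'
#' @param timeline Data frame for one patient, date-ordered, with columns
#'   `date`, `erbb2_fold`, `tcl`, `tmb` (first row = baseline).
#' @param thresholds A [threshold_config()].
#' @param consecutive Require the two qualifying points to be consecutive
#'   (default `TRUE`); `FALSE` applies the any-two-points reading.
#' @param min_samples Minimum number of samples for the analysis. Default 3.
#' @param require_reset Require the feature to have been at or below its
#'   cutoff at an earlier time point before a run can qualify. Default
#'   `TRUE`.
#' @return List of class `ctdna_pd_result`: `call` (`NULL` or a one-row data
#'   frame `source, date, trigger`), `excluded`, `reason`, and `ratios`
#'   (the cutoff-normalized trajectories used).
#' @export
call_ctdna_pd <- function(timeline, thresholds = threshold_config(),
                          consecutive = TRUE, min_samples = 3,
                          require_reset = TRUE) {
  ratios <- data.frame(
    date = timeline$date,
    erbb2_cnv = relative_fold_series(timeline$erbb2_fold,
                                     thresholds$cnv_gain_fold),
    tcl = relative_fold_series(timeline$tcl, thresholds$tcl_high_cutoff),
    tmb = relative_fold_series(timeline$tmb, thresholds$tmb_high_cutoff))
  if (nrow(timeline) < min_samples)
    return(structure(list(call = NULL, excluded = TRUE,
                          reason = sprintf("fewer than %d samples",
                                           min_samples),
                          ratios = ratios),
                     class = "ctdna_pd_result"))
  feats <- c("erbb2_cnv", "tcl", "tmb")
  idx <- vapply(feats, function(f)
    first_qualifying_index(ratios[[f]] > 1, consecutive, require_reset),
    integer(1))
  call <- NULL
  if (any(!is.na(idx))) {
    best <- min(idx, na.rm = TRUE)
    trigger <- feats[which(idx == best)[1]] # fixed order tie-break
    call <- data.frame(source = "ctdna", date = timeline$date[best],
                       trigger = trigger, stringsAsFactors = FALSE)
  }
  structure(list(call = call, excluded = FALSE, reason = NA_character_,
                 ratios = ratios),
            class = "ctdna_pd_result")
}

#' Call CEA-based progression
#'
#' Applies the same sustained-elevation rule to serum CEA normalized to the
#' 5 ng/mL clinical cutoff, and also returns the log2-transformed CEA index
#' series used for display.
#'
#' @param dates Date-ordered sample dates (first = baseline).
#' @param cea Positive CEA concentrations (ng/mL), same length.
#' @param cea_cutoff Clinical cutoff, default 5 ng/mL.
#' @param consecutive,min_samples,require_reset As in [call_ctdna_pd()].
#' @return List of class `ctdna_pd_result` with `call` (source `"cea"`),
#'   `excluded`, `reason`, and `log2_index` (`log2(cea / cutoff)`).
#' @export
call_cea_pd <- function(dates, cea, cea_cutoff = 5, consecutive = TRUE,
                        min_samples = 3, require_reset = TRUE) {
  if (any(is.na(cea)) || any(cea <= 0))
    stop("CEA values must be positive", call. = FALSE)
  ratio <- relative_fold_series(cea, cea_cutoff)
  if (length(dates) < min_samples)
    return(structure(list(call = NULL, excluded = TRUE,
                          reason = sprintf("fewer than %d samples",
                                           min_samples),
                          log2_index = log2(ratio)),
                     class = "ctdna_pd_result"))
  i <- first_qualifying_index(ratio > 1, consecutive, require_reset)
  call <- if (!is.na(i))
    data.frame(source = "cea", date = dates[i], trigger = "cea",
               stringsAsFactors = FALSE) else NULL
  structure(list(call = call, excluded = FALSE, reason = NA_character_,
                 log2_index = log2(ratio)),
            class = "ctdna_pd_result")
}

#' Lead time of a molecular progression call over imaging
#'
#' @param molecular_pd_date ctDNA- or CEA-based PD date (`Date` or numeric
#'   day).
#' @param ct_pd_date CT-based PD date on the same scale.
#' @return Integer days; positive when the molecular call came earlier
#'   ("ahead").
#' @export
compute_lead_time <- function(molecular_pd_date, ct_pd_date) {
  if (is.na(molecular_pd_date) || is.na(ct_pd_date))
    stop("both progression dates must be present", call. = FALSE)
  as.integer(round(as.numeric(ct_pd_date) - as.numeric(molecular_pd_date)))
}

#' Cohort lead-time summary
#'
#' A patient counts as "ahead" only with a strictly positive lead; the mean
#' advancement is computed over ahead patients only.
#'
#' @param lead_days Integer vector of per-patient lead times.
#' @return List `n`, `ahead_n`, `ahead_fraction_pct`, `mean_advance_days`
#'   (`NA` when no patient is ahead).
#' @export
lead_time_summary <- function(lead_days) {
  lead_days <- lead_days[!is.na(lead_days)]
  ahead <- lead_days > 0
  list(n = length(lead_days), ahead_n = sum(ahead),
       ahead_fraction_pct = if (length(lead_days))
         100 * mean(ahead) else NA_real_,
       mean_advance_days = if (any(ahead))
         mean(lead_days[ahead]) else NA_real_)
}

#' Alterations emerging relative to baseline
#'
#' Variants (by allele-specific site key) present in the progression sample
#' but absent at baseline, and gene CNV calls (gain/loss) present at
#' progression but not at baseline, reported separately. Both inputs are
#' expected to be denoised.
#'
#' @param bl_variants,pd_variants Variant tables at baseline and at
#'   progression.
#' @param bl_cnv,pd_cnv Optional per-gene tables with `gene` and `fold` or
#'   `class` at the two time points.
#' @param thresholds A [threshold_config()] (used when `fold` is supplied).
#' @return List with `variants` (rows of `pd_variants` new at progression)
#'   and `cnv` (data frame `gene, class` of new gains/losses).
#' @export
detect_emerging_alterations <- function(bl_variants, pd_variants,
                                        bl_cnv = NULL, pd_cnv = NULL,
                                        thresholds = threshold_config()) {
  new_keys <- setdiff(variant_key(pd_variants), variant_key(bl_variants))
  variants <- pd_variants[variant_key(pd_variants) %in% new_keys, ,
                          drop = FALSE]
  cnv <- data.frame(gene = character(0), class = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(bl_cnv) && !is.null(pd_cnv)) {
    cls_of <- function(x) {
      cls <- if ("class" %in% names(x)) x$class
             else call_gene_cnv(x$fold, thresholds)
      stats::setNames(cls, x$gene)
    }
    bl <- cls_of(bl_cnv); pd <- cls_of(pd_cnv)
    new_g <- names(pd)[pd != "neutral" &
                         (!(names(pd) %in% names(bl)) |
                            bl[names(pd)] == "neutral")]
    new_g <- new_g[!is.na(new_g)]
    cnv <- data.frame(gene = new_g, class = unname(pd[new_g]),
                      stringsAsFactors = FALSE)
  }
  list(variants = variants, cnv = cnv)
}

#' Validate and order one patient's timeline
#'
#' Sorts a patient's feature rows by date and enforces the timeline
#' invariants: strictly increasing dates (no duplicate draws) and the `BL`
#' label on the earliest sample.
#'
#' @param patient_features Feature rows of one patient (see
#'   [cohort_features()]).
#' @return List `patient_id`, `data` (date-ordered), `n`, `valid`, `reason`.
#' @export
build_timeline <- function(patient_features) {
  pid <- patient_features$patient_id[1]
  x <- patient_features[order(patient_features$date), , drop = FALSE]
  valid <- TRUE; reason <- NA_character_
  if (anyDuplicated(x$date)) {
    valid <- FALSE; reason <- "non-increasing sample dates"
  } else if (!is.na(match("BL", x$timepoint)) &&
             match("BL", x$timepoint) != 1) {
    valid <- FALSE; reason <- "baseline is not the earliest sample"
  } else if (!"BL" %in% x$timepoint) {
    valid <- FALSE; reason <- "no baseline sample"
  }
  list(patient_id = pid, data = x, n = nrow(x), valid = valid,
       reason = reason)
}

#' Monitor a whole cohort for molecular progression
#'
#' For every patient with a CT-confirmed progression and at least
#' `min_samples` plasma samples, calls ctDNA-based and CEA-based PD, and
#' computes their lead times over the CT-based PD date (taken as the first
#' visit whose RECIST assessment is `PD`). Patients failing the timeline
#' invariants or the inclusion rule are excluded and logged, never silently
#' dropped.
#'
#' @param features Cohort feature table from [cohort_features()].
#' @param thresholds A [threshold_config()].
#' @param consecutive,min_samples,require_reset As in [call_ctdna_pd()].
#' @return List with `calls` (`patient_id, source, date, trigger,
#'   lead_days`; the `ct` row has lead 0), `excluded`
#'   (`patient_id, reason`), `summary` (per-source [lead_time_summary()]
#'   over patients with a CT PD), and `ratios` (long cutoff-normalized
#'   trajectories for plotting).
#' @export
monitor_cohort <- function(features, thresholds = threshold_config(),
                           consecutive = TRUE, min_samples = 3,
                           require_reset = TRUE) {
  calls <- list(); excl <- list(); ratio_tabs <- list()
  ctdna_leads <- c(); cea_leads <- c()
  for (pid in unique(features$patient_id)) {
    tl <- build_timeline(features[features$patient_id == pid, ,
                                  drop = FALSE])
    if (!tl$valid) {
      excl[[pid]] <- data.frame(patient_id = pid, reason = tl$reason)
      next
    }
    x <- tl$data
    ct_idx <- which(!is.na(x$response) & x$response == "PD")
    ct_date <- if (length(ct_idx)) x$date[ct_idx[1]] else NA
    res <- call_ctdna_pd(x, thresholds, consecutive, min_samples,
                         require_reset)
    rt <- res$ratios; rt$patient_id <- pid
    ratio_tabs[[pid]] <- rt
    if (is.na(ct_date)) {
      excl[[pid]] <- data.frame(patient_id = pid,
                                reason = "no CT-based PD (non-progressor)")
      next
    }
    if (res$excluded) {
      excl[[pid]] <- data.frame(patient_id = pid, reason = res$reason)
      next
    }
    rows <- data.frame(patient_id = pid, source = "ct", date = ct_date,
                       trigger = "imaging", lead_days = 0L,
                       stringsAsFactors = FALSE)
    if (!is.null(res$call)) {
      lead <- compute_lead_time(res$call$date, ct_date)
      ctdna_leads <- c(ctdna_leads, lead)
      rows <- rbind(rows, data.frame(patient_id = pid, source = "ctdna",
                                     date = res$call$date,
                                     trigger = res$call$trigger,
                                     lead_days = lead))
    }
    cea_res <- call_cea_pd(x$date, x$cea_ng_ml, thresholds$cea_cutoff,
                           consecutive, min_samples, require_reset)
    if (!is.null(cea_res$call)) {
      lead <- compute_lead_time(cea_res$call$date, ct_date)
      cea_leads <- c(cea_leads, lead)
      rows <- rbind(rows, data.frame(patient_id = pid, source = "cea",
                                     date = cea_res$call$date,
                                     trigger = "cea", lead_days = lead))
    }
    calls[[pid]] <- rows
  }
  n_prog <- length(calls)
  summary <- list(
    n_monitored = n_prog,
    ctdna = c(lead_time_summary(ctdna_leads),
              list(ahead_of_n = n_prog)),
    cea = c(lead_time_summary(cea_leads),
            list(ahead_of_n = n_prog)))
  # ahead fractions over all monitored progressors, not only called ones
  summary$ctdna$ahead_fraction_pct <- if (n_prog)
    100 * sum(ctdna_leads > 0) / n_prog else NA_real_
  summary$cea$ahead_fraction_pct <- if (n_prog)
    100 * sum(cea_leads > 0) / n_prog else NA_real_
  list(calls = rbind_all(calls), excluded = rbind_all(excl),
       summary = summary, ratios = rbind_all(ratio_tabs))
}
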