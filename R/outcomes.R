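#' Baseline ERBB2-by-TMB stratum
#'
#' Combines baseline ERBB2 amplification status (copy ratio at or above the
#' gain cutoff) with the TMB class into the four-category label used for
#' outcome stratification.
#'
#' @param erbb2_fold Baseline ERBB2 copy ratio (vectorized).
#' @param tmb Baseline TMB in mutations/Mb.
#' @param thresholds A [threshold_config()].
#' @return Data frame `erbb2, tmb, combined` with `erbb2`/`tmb` in
#'   `{high, low}` and `combined` in
#'   `{EhighThigh, EhighTlow, ElowThigh, ElowTlow}`.
#' @export
assign_baseline_stratum <- function(erbb2_fold, tmb,
                                    thresholds = threshold_config()) {
  if (any(is.na(erbb2_fold)) || any(is.na(tmb)))
    stop("missing baseline features", call. = FALSE)
  e <- ifelse(erbb2_fold >= thresholds$cnv_gain_fold, "high", "low")
  t <- ifelse(tmb >= thresholds$tmb_high_cutoff, "high", "low")
  data.frame(erbb2 = e, tmb = t,
             combined = paste0("E", e, "T", t),
             stringsAsFactors = FALSE)
}

#' Baseline-to-first-point dynamics category
#'
#' Classifies the change of a feature's high/low (or amplified/not) class
#' between baseline and the first post-treatment evaluation: `dn`
#' (high at BL to low at FP), `up` (low to high), `remainL` (low at both),
#' `remainH` (high at both).
#'
#' @param bl_class,fp_class Character vectors in `{high, low}` (or
#'   `{amplified, not_amplified}`, mapped to high/low).
#' @return Character vector in `{dn, up, remainL, remainH}`.
#' @export
assign_dynamics_category <- function(bl_class, fp_class) {
  norm <- function(x) {
    x <- ifelse(x == "amplified", "high",
                ifelse(x == "not_amplified", "low", x))
    if (any(is.na(x) | !x %in% c("high", "low")))
      stop("classes must be high/low (or amplified/not_amplified)",
           call. = FALSE)
    x
  }
  bl <- norm(bl_class); fp <- norm(fp_class)
  ifelse(bl == "high" & fp == "low", "dn",
         ifelse(bl == "low" & fp == "high", "up",
                ifelse(bl == "low", "remainL", "remainH")))
}

#' Objective response and disease control rates
#'
#' ORR is the fraction of evaluable patients with an objective response
#' (CR or PR; the motivating cohort contained no CR, but CR is accepted and
#' counted), DCR additionally counts SD. Rates are reported as percentages
#' with their numerator and denominator.
#'
#' @param responses Character vector of best responses in
#'   `{CR, PR, SD, PD}`; `NA` rows are not evaluable and are dropped.
#' @return List `n, orr_n, dcr_n, orr_pct, dcr_pct` (`NA` rates when no
#'   patient is evaluable).
#' @export
compute_orr_dcr <- function(responses) {
  responses <- responses[!is.na(responses)]
  bad <- setdiff(unique(responses), c("CR", "PR", "SD", "PD"))
  if (length(bad))
    stop(sprintf("unknown response '%s'", bad[1]), call. = FALSE)
  n <- length(responses)
  orr_n <- sum(responses %in% c("CR", "PR"))
  dcr_n <- sum(responses %in% c("CR", "PR", "SD"))
  list(n = n, orr_n = orr_n, dcr_n = dcr_n,
       orr_pct = if (n) 100 * orr_n / n else NA_real_,
       dcr_pct = if (n) 100 * dcr_n / n else NA_real_)
}

#' Kaplan-Meier survival estimate with optional two-group log-rank test
#'
#' Product-limit estimator with right censoring; the median is the earliest
#' time at which the survival function drops to 0.5 or below (`NA`, "not
#' reached", if it never does). With a grouping factor, the log-rank
#' chi-square statistic and p-value are also returned (for more than two
#' groups the k-sample statistic is reported; the package's stratified
#' analyses only ever contrast two at a time).
#'
#' @param time Positive follow-up times (e.g. PFS in months).
#' @param event 1/TRUE when progression or death was observed, 0/FALSE when
#'   censored.
#' @param group Optional factor splitting the records into strata.
#' @return List of class `ctdna_km` with `curve` (data frame `group, time,
#'   n_risk, n_event, surv`), `median` (named per group), and `logrank`
#'   (`chisq, df, p`, or `NULL` without grouping).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  if (length(time) < 1) stop("no records", call. = FALSE)
  event <- as.integer(as.logical(event))
  km_median <- function(t, s) {
    i <- which(s <= 0.5)
    if (length(i)) t[i[1]] else NA_real_
  }
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    curve <- data.frame(group = "all", time = fit$time,
                        n_risk = fit$n.risk, n_event = fit$n.event,
                        surv = fit$surv)
    med <- c(all = km_median(fit$time, fit$surv))
    logrank <- NULL
  } else {
    group <- as.factor(group)
    df <- data.frame(time = time, event = event, group = group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    gl <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    curve <- data.frame(group = gl, time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, surv = fit$surv)
    med <- vapply(split(seq_along(gl), gl), function(i)
      km_median(fit$time[i], fit$surv[i]), numeric(1))
    logrank <- NULL
    if (nlevels(droplevels(group)) >= 2) {
      sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = df)
      dfree <- length(sd$n) - 1
      logrank <- list(chisq = unname(sd$chisq), df = dfree,
                      p = stats::pchisq(sd$chisq, dfree,
                                        lower.tail = FALSE))
    }
  }
  structure(list(curve = curve, median = med, logrank = logrank),
            class = "ctdna_km")
}

#' @export
print.ctdna_km <- function(x, ...) {
  cat("Kaplan-Meier estimate\n  median:",
      paste(sprintf("%s=%s", names(x$median),
                    ifelse(is.na(x$median), "not reached",
                           format(x$median))), collapse = ", "), "\n")
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank chisq=%.3f (df=%d), p=%.4g\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p))
  invisible(x)
}

#' Agreement and Cohen's kappa for a 2x2 concordance table
#'
#' Percent agreement is the diagonal fraction; kappa is
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the row and
#' column margins (unweighted). Significance uses the large-sample
#' null-variance approximation. With degenerate margins (`p_e = 1`) kappa is
#' undefined and reported as `NA`.
#'
#' @param tab 2x2 (or k x k) matrix of counts, e.g. plasma ERBB2 status by
#'   tissue HER2 status.
#' @return List `n, agreement_pct, kappa, z, p`.
#' @export
concordance_stats <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("square table required", call. = FALSE)
  n <- sum(tab)
  if (n < 1) stop("empty table", call. = FALSE)
  p <- tab / n
  po <- sum(diag(p))
  rows <- rowSums(p); cols <- colSums(p)
  pe <- sum(rows * cols)
  if (1 - pe < .Machine$double.eps^0.5)
    return(list(n = n, agreement_pct = 100 * po, kappa = NA_real_,
                z = NA_real_, p = NA_real_))
  kappa <- (po - pe) / (1 - pe)
  # Fleiss null variance of kappa
  var0 <- (pe + pe^2 - sum(rows * cols * (rows + cols))) /
    (n * (1 - pe)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else NA_real_
  list(n = n, agreement_pct = 100 * po, kappa = kappa, z = z,
       p = if (is.na(z)) NA_real_ else
         2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Spearman correlation of genomic features with CEA
#'
#' Rank correlation, across samples, of each genomic feature with the serum
#' CEA concentration measured at the same draw.
#'
#' @param features Data frame with columns `erbb2_fold`, `tcl`, `tmb` and
#'   `cea_ng_ml` (one row per sample).
#' @return Data frame `feature, n, rho, p` (`rho` is `NA` for constant
#'   series).
#' @export
feature_cea_correlation <- function(features) {
  one <- function(x, y, label) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || length(unique(x)) < 2 || length(unique(y)) < 2)
      return(data.frame(feature = label, n = length(x), rho = NA_real_,
                        p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(feature = label, n = length(x),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }
  rbind(one(features$erbb2_fold, features$cea_ng_ml, "erbb2_cnv"),
        one(features$tcl, features$cea_ng_ml, "tcl"),
        one(features$tmb, features$cea_ng_ml, "tmb"))
}

# Best response over a patient's visit-level RECIST assessments
# (CR > PR > SD > PD) and PFS from treatment start to the first PD visit
# (event) or the last visit (censored).
patient_outcomes <- function(features) {
  out <- lapply(split(features, features$patient_id), function(x) {
    x <- x[order(x$date), , drop = FALSE]
    resp <- x$response[!is.na(x$response)]
    best <- if (!length(resp)) NA_character_
      else c("CR", "PR", "SD", "PD")[min(match(resp,
                                               c("CR", "PR", "SD", "PD")))]
    pd_i <- which(!is.na(x$response) & x$response == "PD")
    end <- if (length(pd_i)) x$date[pd_i[1]] else max(x$date)
    data.frame(patient_id = x$patient_id[1], best_response = best,
               pfs_months = as.numeric(end - min(x$date)) / 30.4375,
               pfs_event = as.integer(length(pd_i) > 0),
               stringsAsFactors = FALSE)
  })
  rbind_all(out)
}

#' Stratified cohort outcome analysis
#'
#' Derives per-patient best response and progression-free survival from the
#' visit-level records, stratifies patients by baseline ERBB2/TMB status and
#' by baseline-to-first-point dynamics of each feature, and reports ORR/DCR
#' per stratum, Kaplan-Meier medians with log-rank contrasts, the
#' plasma-tissue ERBB2 concordance, and feature-CEA correlations.
#'
#' @param features Cohort feature table from [cohort_features()].
#' @param thresholds A [threshold_config()].
#' @return List of class `ctdna_outcomes`: `patients` (per-patient response,
#'   PFS, strata, dynamics), `overall` (cohort ORR/DCR/median PFS),
#'   `by_baseline_stratum`, `by_dynamics`, `km` (per-stratification
#'   [km_estimate()] results), `concordance`, `correlation`.
#' @export
cohort_outcomes <- function(features, thresholds = threshold_config()) {
  bl <- features[features$timepoint == "BL", , drop = FALSE]
  fp <- features[features$timepoint == "FP", , drop = FALSE]
  if (!nrow(bl)) stop("no baseline samples", call. = FALSE)
  pat <- patient_outcomes(features)
  strat <- assign_baseline_stratum(bl$erbb2_fold, bl$tmb, thresholds)
  bl_strat <- data.frame(patient_id = bl$patient_id, strat,
                         stringsAsFactors = FALSE)
  pat <- merge(pat, bl_strat, by = "patient_id", all.x = TRUE)

  # dynamics BL -> FP for the three genomic features
  dyn <- merge(bl[c("patient_id", "erbb2_status", "tcl_class", "tmb_class")],
               fp[c("patient_id", "erbb2_status", "tcl_class", "tmb_class")],
               by = "patient_id", suffixes = c("_bl", "_fp"))
  if (nrow(dyn)) {
    dyn$erbb2_dyn <- assign_dynamics_category(dyn$erbb2_status_bl,
                                              dyn$erbb2_status_fp)
    dyn$tcl_dyn <- assign_dynamics_category(dyn$tcl_class_bl,
                                            dyn$tcl_class_fp)
    dyn$tmb_dyn <- assign_dynamics_category(dyn$tmb_class_bl,
                                            dyn$tmb_class_fp)
    pat <- merge(pat, dyn[c("patient_id", "erbb2_dyn", "tcl_dyn",
                            "tmb_dyn")], by = "patient_id", all.x = TRUE)
  } else {
    pat$erbb2_dyn <- pat$tcl_dyn <- pat$tmb_dyn <- NA_character_
  }

  rate_by <- function(label) {
    groups <- split(pat, pat[[label]])
    out <- lapply(names(groups), function(g) {
      r <- compute_orr_dcr(groups[[g]]$best_response)
      data.frame(stratum = g, n = r$n, orr_n = r$orr_n, dcr_n = r$dcr_n,
                 orr_pct = r$orr_pct, dcr_pct = r$dcr_pct,
                 stringsAsFactors = FALSE)
    })
    rbind_all(out)
  }
  km_by <- function(label) {
    ok <- !is.na(pat[[label]])
    if (sum(ok) < 2 || length(unique(pat[[label]][ok])) < 2) return(NULL)
    km_estimate(pat$pfs_months[ok], pat$pfs_event[ok], pat[[label]][ok])
  }

  overall_r <- compute_orr_dcr(pat$best_response)
  overall_km <- km_estimate(pat$pfs_months, pat$pfs_event)

  conc <- NULL
  has_tissue <- !is.na(bl$tissue_her2) & !is.na(bl$erbb2_status)
  if (any(has_tissue)) {
    tab <- table(factor(bl$erbb2_status[has_tissue],
                        levels = c("amplified", "not_amplified")),
                 factor(bl$tissue_her2[has_tissue],
                        levels = c("positive", "negative")))
    conc <- c(list(table = as.matrix(tab)), concordance_stats(tab))
  }

  structure(list(
    patients = pat,
    overall = list(n = overall_r$n, orr_pct = overall_r$orr_pct,
                   dcr_pct = overall_r$dcr_pct,
                   orr_n = overall_r$orr_n, dcr_n = overall_r$dcr_n,
                   mpfs_months = unname(overall_km$median["all"])),
    by_baseline_stratum = list(
      erbb2 = rate_by("erbb2"), tmb = rate_by("tmb"),
      combined = rate_by("combined")),
    by_dynamics = list(
      erbb2 = rate_by("erbb2_dyn"), tcl = rate_by("tcl_dyn"),
      tmb = rate_by("tmb_dyn")),
    km = list(overall = overall_km,
              baseline_tmb = km_by("tmb"),
              baseline_erbb2 = km_by("erbb2"),
              baseline_combined = km_by("combined"),
              tmb_dynamics = km_by("tmb_dyn")),
    concordance = conc,
    correlation = feature_cea_correlation(features)
  ), class = "ctdna_outcomes")
}
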