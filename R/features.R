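coding_effect_classes <- function(include_splice = FALSE,
                                  include_other = FALSE) {
  out <- c("missense", "nonsense", "synonymous", "frameshift_indel",
           "inframe_indel")
  if (include_splice) out <- c(out, "splice")
  if (include_other) out <- c(out, "other")
  out
}

#' Panel tumor mutation burden
#'
#' TMB is the number of base substitutions and indels in the coding regions
#' of the targeted genes, synonymous alterations included (they reduce
#' sampling noise), known driver hotspots excluded, divided by the panel's
#' coding footprint in megabases. Splice-site and unclassified (`other`)
#' variants are excluded by default. The input is expected to be already
#' denoised.
#'
#' @param variants Denoised variant-call data frame.
#' @param panel A [panel_definition()]; supplies the footprint denominator
#'   and the driver catalogue.
#' @param include_splice,include_other Count splice / unclassified effect
#'   classes as well. Defaults `FALSE`.
#' @return TMB in mutations per megabase.
#' @examples
#' p <- panel_definition(coding_footprint_mb = 1.2)
#' compute_tmb(data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "T",
#'                        gene = "ERBB2", effect = "missense",
#'                        af = 0.1, alt_reads = 200, depth = 2000), p)
#' @export
compute_tmb <- function(variants, panel, include_splice = FALSE,
                        include_other = FALSE) {
  stopifnot(inherits(panel, "ctdna_panel"))
  if (panel$coding_footprint_mb <= 0) stop("zero coding footprint")
  if (!nrow(variants)) return(0)
  counted <- variants$effect %in%
    coding_effect_classes(include_splice, include_other)
  if (length(panel$driver_keys))
    counted <- counted & !(variant_key(variants) %in% panel$driver_keys)
  sum(counted) / panel$coding_footprint_mb
}

#' Call gene-level copy-number state from a copy ratio
#'
#' A gene is called `gain` at a copy ratio at or above the amplification
#' cutoff (1.4 by default), `loss` at or below the deletion cutoff (0.65),
#' and `neutral` in between. Boundaries are inclusive.
#'
#' @param fold Numeric vector of non-negative copy ratios.
#' @param thresholds A [threshold_config()].
#' @return Character vector in `{gain, loss, neutral}`.
#' @export
call_gene_cnv <- function(fold, thresholds = threshold_config()) {
  if (any(fold < 0, na.rm = TRUE)) stop("negative copy ratio", call. = FALSE)
  ifelse(fold >= thresholds$cnv_gain_fold, "gain",
         ifelse(fold <= thresholds$cnv_loss_fold, "loss", "neutral"))
}

#' Total copy-number load
#'
#' TCL counts the genes called amplified or deleted in a sample; a sample is
#' TCL-high at a load of 2 or more.
#'
#' @param cnv_calls Data frame with one row per gene: columns `gene` and
#'   either `class` (from [call_gene_cnv()]) or `fold`.
#' @param thresholds A [threshold_config()].
#' @return List with `tcl` (count) and `tcl_class` (`"high"`/`"low"`).
#' @export
compute_tcl <- function(cnv_calls, thresholds = threshold_config()) {
  if (anyDuplicated(cnv_calls$gene))
    stop("duplicate gene entries in CNV table", call. = FALSE)
  cls <- if ("class" %in% names(cnv_calls)) cnv_calls$class
         else call_gene_cnv(cnv_calls$fold, thresholds)
  tcl <- sum(cls != "neutral")
  list(tcl = tcl,
       tcl_class = if (tcl >= thresholds$tcl_high_cutoff) "high" else "low")
}

#' Maximum variant allele frequency
#'
#' The highest allele fraction among the somatic variants detected in a
#' sample, used as a proxy for the plasma tumor fraction. Undefined
#' (`NA`) when no variant survives denoising.
#'
#' @param variants Denoised variant-call data frame.
#' @return Numeric scalar, `NA_real_` if the table is empty.
#' @export
compute_maxivaf <- function(variants) {
  if (!nrow(variants)) return(NA_real_)
  max(variants$af)
}

#' Neutrophil- and monocyte-to-lymphocyte ratios
#'
#' @param anc,amc,alc Absolute neutrophil, monocyte and lymphocyte counts
#'   (1e9/L); `alc` must be positive.
#' @return Data frame with columns `anc, amc, alc, nlr, mlr`.
#' @export
compute_blood_indexes <- function(anc, amc, alc) {
  if (any(!is.na(alc) & alc <= 0))
    stop("absolute lymphocyte count must be positive", call. = FALSE)
  data.frame(anc = anc, amc = amc, alc = alc,
             nlr = anc / alc, mlr = amc / alc)
}

#' Cohort-specific top-tertile cutoff
#'
#' Returns the smallest value of the top third of `x` (the top 33.3 percent
#' by count, ties promoted), i.e. the value at or above which a sample falls
#' in the highest tertile.
#'
#' @param x Numeric vector, length at least 3.
#' @return The tertile cutoff.
#' @export
tertile_cutoff <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("tertile mode needs at least 3 samples",
                          call. = FALSE)
  sort(x, decreasing = TRUE)[ceiling(length(x) / 3)]
}

#' Extract the per-sample genomic feature set
#'
#' Computes, for one plasma sample, the features the monitoring and
#' stratification stages consume: TMB with its high/low class, gene CNV
#' calls, TCL with its class, the ERBB2 copy ratio and amplification status,
#' and MaxiVAF.
#'
#' @param variants Denoised variant table for the sample.
#' @param copy_ratios Data frame `gene, fold` for the sample (one row per
#'   gene).
#' @param panel A [panel_definition()].
#' @param thresholds A [threshold_config()].
#' @param sample_id Identifier copied into the output.
#' @return List of class `ctdna_sample_features` with fields `sample_id,
#'   tmb, tmb_class, tcl, tcl_class, erbb2_fold, erbb2_status, maxivaf,
#'   cnv_calls`.
#' @export
extract_sample_features <- function(variants, copy_ratios, panel,
                                    thresholds = threshold_config(),
                                    sample_id = NA_character_) {
  tmb <- compute_tmb(variants, panel)
  cls <- call_gene_cnv(copy_ratios$fold, thresholds)
  cnv_calls <- data.frame(gene = copy_ratios$gene, fold = copy_ratios$fold,
                          class = cls, stringsAsFactors = FALSE)
  tclr <- compute_tcl(cnv_calls, thresholds)
  erbb2_fold <- copy_ratios$fold[copy_ratios$gene == "ERBB2"][1]
  structure(list(
    sample_id = sample_id,
    tmb = tmb,
    tmb_class = if (tmb >= thresholds$tmb_high_cutoff) "high" else "low",
    tcl = tclr$tcl, tcl_class = tclr$tcl_class,
    erbb2_fold = erbb2_fold,
    erbb2_status = if (is.na(erbb2_fold)) NA_character_
      else if (erbb2_fold >= thresholds$cnv_gain_fold) "amplified"
      else "not_amplified",
    maxivaf = compute_maxivaf(variants),
    cnv_calls = cnv_calls
  ), class = "ctdna_sample_features")
}

#' Classify a feature table at fixed or cohort-tertile cutoffs
#'
#' The primary mode applies the fixed cutoffs of the [threshold_config()]
#' (TMB at or above 8.5 mut/Mb high, TCL at or above 2 high, ERBB2 copy
#' ratio at or above 1.4 amplified). The alternative tertile mode recomputes
#' TMB/TCL cutoffs as the cohort's top-33.3-percent boundary and reports
#' them. Classification is idempotent: rerunning on its own output changes
#' nothing.
#'
#' @param features Data frame with columns `tmb`, `tcl`, `erbb2_fold`.
#' @param thresholds A [threshold_config()].
#' @param mode `"fixed"` (default) or `"tertile"`.
#' @return `features` with `tmb_class`, `tcl_class`, `erbb2_status`
#'   (re)filled; the cutoffs used are attached as attribute `cutoffs`.
#' @export
classify_features <- function(features, thresholds = threshold_config(),
                              mode = c("fixed", "tertile")) {
  mode <- match.arg(mode)
  tmb_cut <- thresholds$tmb_high_cutoff
  tcl_cut <- thresholds$tcl_high_cutoff
  if (mode == "tertile") {
    tmb_cut <- tertile_cutoff(features$tmb)
    tcl_cut <- tertile_cutoff(features$tcl)
  }
  features$tmb_class <- ifelse(features$tmb >= tmb_cut, "high", "low")
  features$tcl_class <- ifelse(features$tcl >= tcl_cut, "high", "low")
  features$erbb2_status <- ifelse(
    features$erbb2_fold >= thresholds$cnv_gain_fold,
    "amplified", "not_amplified")
  attr(features, "cutoffs") <- list(tmb = tmb_cut, tcl = tcl_cut,
                                    erbb2_fold = thresholds$cnv_gain_fold)
  features
}

#' Per-sample feature table for a whole cohort
#'
#' Runs denoising and feature extraction over every sample and returns one
#' feature row per sample, merged with the clinical record (CEA, blood
#' indexes, dates, timepoints).
#'
#' @param variant_tables Named list of variant-call data frames (names are
#'   sample ids) or named character vector of file paths.
#' @param copy_ratios Long copy-ratio table `sample_id, gene, fold`.
#' @param clinical Clinical data frame (see [read_clinical()]).
#' @param wbc_db A [wbc_database()].
#' @param model A background model from [build_background_model()].
#' @param panel A [panel_definition()].
#' @param thresholds A [threshold_config()].
#' @param verbose Log per-stage removal counts with [message()].
#' @return List with `features` (data frame `sample_id, patient_id, date,
#'   timepoint, tmb, tmb_class, tcl, tcl_class, erbb2_fold, erbb2_status,
#'   maxivaf, cea_ng_ml, nlr, mlr, response, tissue_her2`) and
#'   `removal_log`.
#' @export
cohort_features <- function(variant_tables, copy_ratios, clinical, wbc_db,
                            model, panel,
                            thresholds = threshold_config(),
                            verbose = FALSE) {
  ids <- clinical$sample_id
  rows <- vector("list", length(ids))
  logs <- vector("list", length(ids))
  denoised <- vector("list", length(ids))
  names(denoised) <- ids
  for (i in seq_along(ids)) {
    sid <- ids[i]
    v <- variant_tables[[sid]]
    if (is.null(v)) stop(sprintf("no variant table for sample %s", sid),
                         call. = FALSE)
    if (is.character(v)) v <- read_variant_table(v)
    dn <- denoise_variants(v, wbc_db, model)
    if (verbose)
      message(sprintf("denoise %s: %d in, %d retained, %d removed",
                      sid, nrow(v), nrow(dn$retained), nrow(dn$removed)))
    denoised[[sid]] <- dn$retained
    cr <- copy_ratios[copy_ratios$sample_id == sid, c("gene", "fold")]
    ft <- extract_sample_features(dn$retained, cr, panel, thresholds, sid)
    blood <- compute_blood_indexes(clinical$anc[i], clinical$amc[i],
                                   clinical$alc[i])
    rows[[i]] <- data.frame(
      sample_id = sid, patient_id = clinical$patient_id[i],
      date = clinical$date[i], timepoint = clinical$timepoint[i],
      tmb = ft$tmb, tmb_class = ft$tmb_class,
      tcl = ft$tcl, tcl_class = ft$tcl_class,
      erbb2_fold = ft$erbb2_fold, erbb2_status = ft$erbb2_status,
      maxivaf = ft$maxivaf,
      cea_ng_ml = clinical$cea_ng_ml[i],
      nlr = blood$nlr, mlr = blood$mlr,
      response = clinical$response[i],
      tissue_her2 = clinical$tissue_her2[i],
      stringsAsFactors = FALSE)
    if (nrow(dn$removed)) {
      lg <- dn$removed
      lg$sample_id <- sid
      logs[[i]] <- lg
    }
  }
  list(features = do.call(rbind, rows),
       removal_log = do.call(rbind, logs),
       denoised = denoised)
}
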