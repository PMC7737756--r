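#' Deterministic layout of the simulated panel sites
#'
#' Lays out `sites_per_gene` assayable coding positions per panel gene on a
#' fixed grid (no randomness): gene i sits on chromosome `(i - 1) %% 22 + 1`
#' at positions `i * 1e6 + 50 * (1:sites_per_gene)`, with ref/alt alleles and
#' effect classes cycling through a fixed pattern (eight coding-effect sites,
#' one of them synonymous-rich, plus one splice site per block of ten). The
#' first site of TP53, ERBB2, KRAS and PIK3CA is flagged as a known driver
#' hotspot.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns
#'   `chrom, pos, ref, alt, gene, effect, driver`.
#' @export
build_panel_sites <- function(config) {
  genes <- config$panel$genes
  spg <- config$sites_per_gene
  effs <- rep_len(c("missense", "synonymous", "missense", "missense",
                    "nonsense", "synonymous", "frameshift_indel",
                    "inframe_indel", "missense", "splice"), spg)
  refs <- rep_len(c("A", "C", "G", "T"), spg)
  alt_of <- c(A = "T", C = "G", G = "C", T = "A")
  out <- do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(
      chrom = paste0("chr", (i - 1) %% 22 + 1),
      pos = i * 1000000L + 50L * seq_len(spg),
      ref = refs, alt = unname(alt_of[refs]),
      gene = genes[i], effect = effs,
      stringsAsFactors = FALSE
    )
  }))
  driver_genes <- intersect(c("TP53", "ERBB2", "KRAS", "PIK3CA"), genes)
  out$driver <- out$gene %in% driver_genes &
    out$pos %% 1000000L == 50L
  rownames(out) <- NULL
  out
}

# Beta site-noise draw; shape1 == 0 encodes the point mass at zero
# (noise switched off).
rbeta_noise <- function(n, shape) {
  if (shape[1] <= 0) return(rep(0, n))
  stats::rbeta(n, shape[1], shape[2])
}

noise_off <- function(config) config$site_error_shape[1] <= 0

#' Generate the healthy-plasma background pool
#'
#' Simulates plasma panel sequencing of healthy individuals: at every panel
#' site each individual reports a noise allele fraction drawn from the
#' configured per-site error distribution, binomially resampled at the
#' configured depth (reported AF = alt reads / depth). The resulting tables
#' feed [build_background_model()].
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to the config seed.
#' @return A list of `n_healthy_pool` variant-table data frames.
#' @export
generate_background_pool <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ctdna_sim_config"))
  if (config$n_healthy_pool < 1) stop("n_healthy_pool must be >= 1")
  set.seed(seed)
  sites <- build_panel_sites(config)
  n_sites <- nrow(sites)
  lapply(seq_len(config$n_healthy_pool), function(i) {
    p <- rbeta_noise(n_sites, config$site_error_shape)
    if (noise_off(config)) {
      alt <- integer(n_sites)
      af <- rep(0, n_sites)
    } else {
      alt <- stats::rbinom(n_sites, config$depth, p)
      af <- alt / config$depth
    }
    data.frame(sites[c("chrom", "pos", "ref", "alt", "gene", "effect")],
               af = af, alt_reads = alt, depth = config$depth,
               stringsAsFactors = FALSE)
  })
}

#' Generate the WBC artifact occurrence database
#'
#' Simulates screening of white-blood-cell DNA from `n_wbc_samples` patients.
#' A configurable fraction of panel sites is planted as recurrent artifacts
#' (clonal-hematopoiesis-like variants present in more than 10 percent of WBC
#' samples, occurrence fraction drawn uniformly in 0.12-0.40 and converted to
#' a count by rounding); the remaining sites receive sporadic background
#' occurrences capped by construction at 10 percent of the total, so that
#' with `artifact_rate = 0` no variant ever crosses the recurrence filter.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to the config seed.
#' @return A [wbc_database()] whose `"planted"` attribute records the planted
#'   artifact keys and occurrence fractions (used by the cohort simulator to
#'   seed the same artifacts into patient plasma).
#' @export
generate_wbc_database <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ctdna_sim_config"))
  if (config$n_wbc_samples < 1) stop("n_wbc_samples must be >= 1")
  set.seed(seed)
  sites <- build_panel_sites(config)
  n_sites <- nrow(sites)
  total <- config$n_wbc_samples
  n_art <- round(config$artifact_rate * n_sites)
  art_idx <- if (n_art > 0) sample.int(n_sites, n_art) else integer(0)
  frac <- stats::runif(n_art, 0.12, 0.40)
  count <- integer(n_sites)
  count[art_idx] <- as.integer(round(frac * total))
  bg_idx <- setdiff(seq_len(n_sites), art_idx)
  bg_rate <- stats::runif(length(bg_idx), 0, 0.04)
  bg <- stats::rbinom(length(bg_idx), total, bg_rate)
  count[bg_idx] <- pmin(bg, floor(0.10 * total))
  keep <- count > 0
  occ <- data.frame(sites[keep, c("chrom", "pos", "ref", "alt", "gene")],
                    count = count[keep], stringsAsFactors = FALSE)
  rownames(occ) <- NULL
  db <- wbc_database(occ, total_samples = total)
  planted <- data.frame(key = variant_key(sites[art_idx, , drop = FALSE]),
                        sites[art_idx, c("chrom", "pos", "ref", "alt",
                                         "gene", "effect")],
                        frac = frac, stringsAsFactors = FALSE)
  rownames(planted) <- NULL
  attr(db, "planted") <- planted
  db
}

#' Tumor-fraction trajectory under therapy
#'
#' Piecewise-exponential kinetics: a responder's tumor fraction decays as
#' `f0 * exp(-k * t)` until resistance onset `t_r`, then regrows as
#' `f(t_r) * exp(g * (t - t_r))`; a non-responder (`t_r = 0`) grows from
#' baseline. Values are capped at 0.95 so the fraction stays inside (0, 1).
#'
#' @param t Days since treatment start (vectorized).
#' @param f0 Baseline tumor fraction.
#' @param k Per-day decay rate while responding.
#' @param g Per-day regrowth rate after resistance.
#' @param t_r Resistance onset in days; `Inf` for never, 0 for primary
#'   non-response.
#' @return Numeric vector of tumor fractions.
#' @export
tumor_fraction <- function(t, f0, k, g, t_r) {
  f <- ifelse(t < t_r,
              f0 * exp(-k * t),
              f0 * exp(-k * pmin(t_r, t)) * exp(g * pmax(t - t_r, 0)))
  pmin(f, 0.95)
}

# Noise-free feature values implied by the latent patient state at given
# days: ERBB2 copy ratio, TCL, and TMB counting variants whose noise-free AF
# exceeds the detection limit implied by the configured site noise.
truth_feature_series <- function(latent, config, days,
                                 thresholds = threshold_config()) {
  g <- if (!is.null(latent$growth_rate)) latent$growth_rate
       else config$regrowth_rate
  f <- tumor_fraction(days, latent$f0, config$decay_rate, g, latent$t_r)
  cn <- latent$copy_numbers
  folds <- sapply(cn, function(c_g) 1 + f * (c_g / 2 - 1)) # days x genes
  if (is.null(dim(folds))) folds <- matrix(folds, nrow = length(f))
  tcl <- rowSums(folds >= thresholds$cnv_gain_fold |
                   folds <= thresholds$cnv_loss_fold)
  det <- detection_limit_af(config)
  fp_mb <- config$panel$coding_footprint_mb
  all_var <- rbind(latent$clonal[c("key", "effect", "driver", "cfrac")],
                   latent$emergent[c("key", "effect", "driver", "cfrac")])
  countable <- all_var$effect %in% c("missense", "nonsense", "synonymous",
                                     "frameshift_indel", "inframe_indel") &
    !all_var$driver
  emergent_n <- nrow(latent$emergent)
  alive <- function(d) c(rep(TRUE, nrow(latent$clonal)),
                         rep(d >= latent$t_r, emergent_n))
  tmb <- vapply(seq_along(days), function(i) {
    af <- all_var$cfrac * f[i] / 2
    sum(countable & alive(days[i]) & af > det) / fp_mb
  }, numeric(1))
  list(f = f,
       erbb2_fold = 1 + f * (cn[["ERBB2"]] / 2 - 1),
       tcl = as.numeric(tcl), tmb = tmb,
       max_ratio = pmax((1 + f * (cn[["ERBB2"]] / 2 - 1)) /
                          thresholds$cnv_gain_fold,
                        tcl / thresholds$tcl_high_cutoff,
                        tmb / thresholds$tmb_high_cutoff))
}

# First day at which a noise-free feature ratio crosses above 1 from below
# (a re-elevation), evaluated on a daily grid. A feature that never crosses
# upward -- including one elevated from day 0 that never dips -- has no
# molecular progression transition and returns NA, mirroring the monitor's
# re-elevation requirement.
first_upcrossing_day <- function(ratio, days) {
  above <- ratio > 1
  up <- which(!above[-length(above)] & above[-1]) + 1
  if (!length(up)) return(NA_real_)
  days[up[1]]
}

# Earliest per-feature upcrossing of the noise-free trajectories: the true
# molecular progression day (NA when no feature ever re-exceeds its cutoff).
molecular_pd_truth <- function(ts, days) {
  cand <- c(first_upcrossing_day(ts$erbb2_fold / 1.4, days),
            first_upcrossing_day(ts$tcl / 2, days),
            first_upcrossing_day(ts$tmb / 8.5, days))
  if (all(is.na(cand))) NA_real_ else min(cand, na.rm = TRUE)
}

#' Noise-free feature trajectory implied by a patient's ground truth
#'
#' Reconstructs, from a truth record (as stored by [simulate_patient()] /
#' `truth.json`), the feature values an ideal noise-free assay would report
#' at given days: ERBB2 copy ratio and per-gene folds from the linear
#' dilution model, TCL from the fold cutoffs, and TMB counting coding
#' non-driver variants whose noise-free allele fraction `c_i * f(t) / 2`
#' exceeds the detection limit implied by the configured site noise.
#' Used by the recovery tests to define the true molecular progression call.
#'
#' @param truth A patient truth record (list with `f0`, `t_r`, `decay_rate`,
#'   `growth_rate`, `copy_numbers`, `clonal`, `emergent`,
#'   `detection_limit_af`, `sample_days`).
#' @param days Days since treatment start; defaults to the sample days.
#' @param coding_footprint_mb TMB denominator, default 1.2.
#' @param thresholds A [threshold_config()].
#' @return Data frame `day, f, erbb2_fold, tcl, tmb`.
#' @export
truth_features <- function(truth, days = truth$sample_days,
                           coding_footprint_mb = 1.2,
                           thresholds = threshold_config()) {
  t_r <- if (is.null(truth$t_r) || is.na(truth$t_r)) Inf else truth$t_r
  f <- tumor_fraction(days, truth$f0, truth$decay_rate, truth$growth_rate,
                      t_r)
  cn <- unlist(truth$copy_numbers)
  folds <- sapply(cn, function(c_g) 1 + f * (c_g / 2 - 1))
  if (is.null(dim(folds))) folds <- matrix(folds, nrow = length(f))
  tcl <- rowSums(folds >= thresholds$cnv_gain_fold |
                   folds <= thresholds$cnv_loss_fold)
  det <- truth$detection_limit_af
  coding <- c("missense", "nonsense", "synonymous", "frameshift_indel",
              "inframe_indel")
  all_var <- rbind(
    data.frame(cfrac = truth$clonal$cfrac, effect = truth$clonal$effect,
               driver = truth$clonal$driver, emergent = FALSE),
    if (!is.null(truth$emergent) && NROW(truth$emergent))
      data.frame(cfrac = truth$emergent$cfrac,
                 effect = truth$emergent$effect,
                 driver = truth$emergent$driver, emergent = TRUE))
  countable <- all_var$effect %in% coding & !all_var$driver
  tmb <- vapply(seq_along(days), function(i) {
    alive <- !all_var$emergent | days[i] >= t_r
    sum(countable & alive & all_var$cfrac * f[i] / 2 > det) /
      coding_footprint_mb
  }, numeric(1))
  data.frame(day = days, f = f, erbb2_fold = folds[, "ERBB2"],
             tcl = as.numeric(tcl), tmb = tmb)
}

#' Simulate one patient's latent disease course and emitted plasma samples
#'
#' Draws the latent truth (response status, baseline tumor fraction,
#' resistance time, clonal variants with clonal fractions, gene copy numbers,
#' emergent resistance variants, planted WBC artifacts carried, baseline CEA
#' and blood counts), then emits plasma samples every
#' `sampling_interval_days` from baseline until the CT scan that calls
#' imaging progression (tumor fraction at or above `ct_detection_threshold`)
#' or until `max_draws` draws. Observed values follow the generative model
#' documented in [simulation_config()]: variant AF `c_i * f(t) / 2` plus Beta
#' site noise, binomially resampled at depth; gene copy ratio
#' `1 + f(t) * (CN_g / 2 - 1)` plus Gaussian noise; CEA affine in `f(t)` with
#' log-normal noise.
#'
#' @param config A [simulation_config()].
#' @param patient_seed Integer seed for this patient.
#' @param patient_id Identifier used in emitted tables.
#' @param artifacts Data frame of planted WBC artifact variants (`key, chrom,
#'   pos, ref, alt, gene, effect, frac`) as attached to
#'   [generate_wbc_database()] output, or `NULL` for none.
#' @return A list with elements `truth` (all latent quantities, including
#'   `molecular_pd_day` and `radiologic_pd_day`), `variants` (long variant
#'   table with `sample_id`), `copy_ratios`, and `clinical` (one row per
#'   sample).
#' @export
simulate_patient <- function(config, patient_seed, patient_id = "P01",
                             artifacts = NULL) {
  stopifnot(inherits(config, "ctdna_sim_config"))
  set.seed(patient_seed)
  sites <- build_panel_sites(config)
  genes <- config$panel$genes
  interval <- config$sampling_interval_days
  horizon <- interval * (config$max_draws - 1)
  if (horizon < interval) stop("follow-up shorter than one sampling interval")

  ## ---- latent state -------------------------------------------------
  responder <- stats::runif(1) < config$responder_fraction
  f0 <- stats::runif(1, config$baseline_tumor_fraction[1],
                     config$baseline_tumor_fraction[2])
  t_r <- if (responder) {
    if (stats::runif(1) < config$nonprogressor_fraction) Inf
    else stats::runif(1, config$resistance_window[1],
                      config$resistance_window[2])
  } else 0
  # primary non-responders progress slowly from baseline; responders that
  # acquire resistance regrow faster from a low post-response fraction
  growth <- if (responder) config$regrowth_rate
            else config$nonresponder_growth_rate
  cn <- stats::setNames(rep(2, length(genes)), genes)
  if (stats::runif(1) < config$erbb2_amp_fraction)
    cn[["ERBB2"]] <- stats::runif(1, config$erbb2_cn_range[1],
                                  config$erbb2_cn_range[2])
  other <- setdiff(genes, "ERBB2")
  u <- stats::runif(length(other))
  cn[other[u < config$other_gain_prob]] <-
    stats::runif(sum(u < config$other_gain_prob), 3, 8)
  del <- u >= config$other_gain_prob &
    u < config$other_gain_prob + config$other_loss_prob
  cn[other[del]] <- stats::runif(sum(del), 0, 1)

  # somatic variants are never planted on recurrent-artifact sites, so the
  # ideal filtered observation matches the truth record's feature counts
  artifact_keys <- if (!is.null(artifacts)) artifacts$key else character(0)
  coding_idx <- which(sites$effect %in% c("missense", "nonsense",
                                          "synonymous", "frameshift_indel",
                                          "inframe_indel") & !sites$driver &
                        !variant_key(sites) %in% artifact_keys)
  n_c <- sample(seq(config$n_clonal_range[1], config$n_clonal_range[2]), 1)
  n_c <- min(n_c, length(coding_idx))
  clonal_idx <- sample(coding_idx, n_c)
  # occasionally include one known driver hotspot, to exercise TMB exclusion
  if (any(sites$driver) && stats::runif(1) < 0.3)
    clonal_idx <- c(clonal_idx, sample(which(sites$driver), 1))
  truncal <- stats::runif(length(clonal_idx)) < config$truncal_fraction
  cfrac <- ifelse(truncal,
                  stats::runif(length(clonal_idx), config$truncal_c_range[1],
                               config$truncal_c_range[2]),
                  stats::runif(length(clonal_idx),
                               config$subclonal_c_range[1],
                               config$subclonal_c_range[2]))
  clonal <- data.frame(sites[clonal_idx, ], cfrac = cfrac,
                       stringsAsFactors = FALSE)
  clonal$key <- variant_key(clonal)

  n_e <- if (is.finite(t_r) && t_r > 0)
    stats::rpois(1, config$emergent_rate) else 0L
  emergent_pool <- setdiff(coding_idx, clonal_idx)
  n_e <- min(n_e, length(emergent_pool))
  emergent <- data.frame(sites[if (n_e > 0) sample(emergent_pool, n_e)
                               else integer(0), ],
                         cfrac = stats::runif(n_e, 0.5, 1),
                         stringsAsFactors = FALSE)
  emergent$key <- if (n_e > 0) variant_key(emergent) else character(0)

  carried <- if (!is.null(artifacts) && nrow(artifacts)) {
    keep <- stats::runif(nrow(artifacts)) < artifacts$frac
    out <- artifacts[keep, , drop = FALSE]
    out$af <- stats::runif(nrow(out), 0.02, 0.2)
    out
  } else {
    data.frame(key = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), gene = character(0),
               effect = character(0), frac = numeric(0), af = numeric(0))
  }

  cea0 <- if (stats::runif(1) < config$cea_high_fraction)
    stats::runif(1, 6, 80) else stats::runif(1, 0.5, 4.5)
  base_anc <- max(1, stats::rnorm(1, 4, 0.8))
  base_amc <- max(0.1, stats::rnorm(1, 0.5, 0.1))
  base_alc <- max(0.5, stats::rnorm(1, 1.8, 0.4))
  enroll <- config$start_date + sample(0:365, 1)
  tumor_amp <- cn[["ERBB2"]] > 2
  has_biopsy <- stats::runif(1) < config$tissue_biopsy_fraction
  tissue_pos <- xor(tumor_amp,
                    stats::runif(1) < config$tissue_discordance_prob)
  tissue_label <- if (!has_biopsy) NA_character_
                  else if (tissue_pos) "positive" else "negative"

  ## ---- schedule -----------------------------------------------------
  traj <- function(t) tumor_fraction(t, f0, config$decay_rate, growth, t_r)
  scan_days <- interval * seq_len(config$max_draws - 1)
  hit <- scan_days[traj(scan_days) >= config$ct_detection_threshold]
  radiologic_pd_day <- if (length(hit)) hit[1] else NA_real_
  last_day <- if (is.na(radiologic_pd_day)) horizon else radiologic_pd_day
  sample_days <- seq(0, last_day, by = interval)

  latent <- list(f0 = f0, t_r = t_r, growth_rate = growth,
                 copy_numbers = as.list(cn),
                 clonal = clonal, emergent = emergent)
  grid <- 0:last_day
  ts <- truth_feature_series(latent, config, grid)
  molecular_pd_day <- molecular_pd_truth(ts, grid)

  ## ---- emission -----------------------------------------------------
  n_s <- length(sample_days)
  sample_ids <- sprintf("%s_S%02d", patient_id, seq_len(n_s))
  timepoints <- c("BL", "FP", sprintf("P%d", seq_len(max(n_s - 2, 0)) + 2))
  f_days <- traj(sample_days)
  zero_noise <- noise_off(config)

  true_rows <- function(d, f_d) {
    rows <- clonal
    if (nrow(emergent) && d >= t_r) rows <- rbind(rows, emergent)
    rows$p <- pmin(rows$cfrac * f_d / 2, 1)
    rows
  }
  variants <- vector("list", n_s)
  copy_ratios <- vector("list", n_s)
  clin <- vector("list", n_s)
  for (i in seq_len(n_s)) {
    d <- sample_days[i]; f_d <- f_days[i]
    tv <- true_rows(d, f_d)
    p <- numeric(nrow(sites))
    names(p) <- variant_key(sites)
    p[tv$key] <- tv$p
    if (nrow(carried)) p[carried$key] <- p[carried$key] + carried$af
    p <- pmin(p + rbeta_noise(length(p), config$site_error_shape), 1)
    if (zero_noise) {
      alt <- as.integer(round(p * config$depth))
      af <- p
      keep <- p > 0
    } else {
      alt <- stats::rbinom(length(p), config$depth, p)
      af <- alt / config$depth
      keep <- alt >= config$min_alt_reads
    }
    variants[[i]] <- data.frame(
      sample_id = sample_ids[i],
      sites[keep, c("chrom", "pos", "ref", "alt", "gene", "effect")],
      af = af[keep], alt_reads = alt[keep], depth = config$depth,
      stringsAsFactors = FALSE)
    fold <- pmax(0, 1 + f_d * (unname(cn) / 2 - 1) +
                   stats::rnorm(length(cn), 0, config$copy_noise_sd))
    copy_ratios[[i]] <- data.frame(sample_id = sample_ids[i],
                                   gene = names(cn), fold = fold,
                                   stringsAsFactors = FALSE)
    response <- if (d == 0) NA_character_
      else if (f_d >= config$ct_detection_threshold) "PD"
      else if (responder && f_d <= 0.7 * f0) "PR"
      else "SD"
    lnoise <- function(base) base * exp(stats::rnorm(1, 0,
                                                     config$blood_sdlog))
    clin[[i]] <- data.frame(
      patient_id = patient_id, sample_id = sample_ids[i],
      date = enroll + d, timepoint = timepoints[i], response = response,
      cea_ng_ml = cea0 * (1 + config$cea_coef * f_d) *
        exp(stats::rnorm(1, 0, config$cea_sdlog)),
      anc = lnoise(base_anc * (1 + 0.8 * f_d)),
      amc = lnoise(base_amc * (1 + 0.4 * f_d)),
      alc = lnoise(base_alc),
      tissue_her2 = tissue_label,
      stringsAsFactors = FALSE)
  }

  truth <- list(
    patient_id = patient_id, responder = responder, f0 = f0,
    decay_rate = config$decay_rate, growth_rate = growth,
    t_r = if (is.finite(t_r)) t_r else NA_real_,
    copy_numbers = as.list(cn),
    clonal = clonal[c("key", "chrom", "pos", "ref", "alt", "gene", "effect",
                      "driver", "cfrac")],
    emergent = emergent[intersect(names(emergent),
                                  c("key", "chrom", "pos", "ref", "alt",
                                    "gene", "effect", "driver", "cfrac"))],
    artifacts_carried = carried[c("key", "af")],
    baseline_cea = cea0, base_anc = base_anc, base_amc = base_amc,
    base_alc = base_alc, enroll_date = format(enroll),
    sample_days = sample_days, sample_ids = sample_ids,
    tumor_fraction = f_days,
    detection_limit_af = detection_limit_af(config),
    molecular_pd_day = molecular_pd_day,
    radiologic_pd_day = radiologic_pd_day,
    tissue_her2 = tissue_label)
  list(truth = truth,
       variants = do.call(rbind, variants),
       copy_ratios = do.call(rbind, copy_ratios),
       clinical = do.call(rbind, clin))
}

#' Simulate a complete monitoring cohort
#'
#' Generates, from a single seed, the healthy-plasma background pool, the WBC
#' artifact database, and `n_patients` longitudinal patient series with full
#' ground truth. Planted WBC artifacts are carried into patient plasma with
#' probability equal to their WBC occurrence fraction, so the downstream
#' recurrence filter has true positives to remove.
#'
#' @param config A [simulation_config()].
#' @return An object of class `ctdna_cohort`: a list with `config`,
#'   `panel_sites`, `healthy_pool`, `wbc_db`, `patients` (per-patient lists
#'   from [simulate_patient()]), pooled `variants`, `copy_ratios` and
#'   `clinical` tables, and `analysis_panel`, a [panel_definition()] whose
#'   driver catalogue is the simulated hotspot set.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ctdna_sim_config"))
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, config$n_patients + 2L)
  healthy <- generate_background_pool(config, seed = seeds[1])
  wbc <- generate_wbc_database(config, seed = seeds[2])
  planted <- attr(wbc, "planted")
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  patients <- lapply(seq_len(config$n_patients), function(i)
    simulate_patient(config, patient_seed = seeds[i + 2L],
                     patient_id = ids[i], artifacts = planted))
  sites <- build_panel_sites(config)
  drivers <- sites[sites$driver, c("gene", "chrom", "pos", "ref", "alt")]
  structure(list(
    config = config, panel_sites = sites,
    healthy_pool = healthy, wbc_db = wbc, patients = patients,
    variants = do.call(rbind, lapply(patients, `[[`, "variants")),
    copy_ratios = do.call(rbind, lapply(patients, `[[`, "copy_ratios")),
    clinical = do.call(rbind, lapply(patients, `[[`, "clinical")),
    analysis_panel = panel_definition(
      genes = config$panel$genes,
      coding_footprint_mb = config$panel$coding_footprint_mb,
      driver_catalogue = drivers)
  ), class = "ctdna_cohort")
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic ctDNA cohort: %d patients, %d plasma samples, %d healthy, WBC n=%d\n",
    length(x$patients), length(unique(x$variants$sample_id)),
    length(x$healthy_pool), x$wbc_db$total_samples))
  invisible(x)
}

#' Write a simulated cohort to disk / read it back
#'
#' `emit_cohort()` writes the cohort in the pipeline's exchange formats:
#' `healthy/healthy_NN.tsv` (background pool), `wbc_database.tsv`,
#' `samples/<sample_id>.tsv` (per-sample variant tables),
#' `copy_ratios.tsv`, `clinical.csv`, `driver_catalogue.tsv`, and
#' `truth.json` holding every latent quantity needed for recovery tests.
#' `read_cohort()` loads those files back through the same readers the
#' pipeline uses.
#'
#' @param cohort A `ctdna_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `emit_cohort()` returns the directory invisibly; `read_cohort()`
#'   returns a list with `healthy_pool`, `wbc_db`, `variant_files`,
#'   `copy_ratios`, `clinical`, `driver_catalogue` and `truth`.
#' @export
emit_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  if (!length(cohort$patients)) stop("empty cohort")
  dir.create(file.path(out_dir, "healthy"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "samples"), showWarnings = FALSE)
  for (i in seq_along(cohort$healthy_pool))
    write_variant_table(cohort$healthy_pool[[i]],
                        file.path(out_dir, "healthy",
                                  sprintf("healthy_%02d.tsv", i)))
  write_wbc_database(cohort$wbc_db, file.path(out_dir, "wbc_database.tsv"))
  for (sid in unique(cohort$variants$sample_id)) {
    v <- cohort$variants[cohort$variants$sample_id == sid,
                         setdiff(names(cohort$variants), "sample_id")]
    write_variant_table(v, file.path(out_dir, "samples",
                                     paste0(sid, ".tsv")))
  }
  write_copy_ratios(cohort$copy_ratios, file.path(out_dir, "copy_ratios.tsv"))
  write_clinical(cohort$clinical, file.path(out_dir, "clinical.csv"))
  drv <- cohort$analysis_panel$driver_catalogue
  utils::write.table(drv, file.path(out_dir, "driver_catalogue.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- lapply(cohort$patients, `[[`, "truth")
  names(truth) <- vapply(truth, `[[`, "", "patient_id")
  jsonlite::write_json(
    list(coding_footprint_mb = cohort$config$panel$coding_footprint_mb,
         sampling_interval_days = cohort$config$sampling_interval_days,
         ct_detection_threshold = cohort$config$ct_detection_threshold,
         patients = truth),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(out_dir)
}

#' @rdname emit_cohort
#' @param dir Directory previously written by `emit_cohort()`.
#' @export
read_cohort <- function(dir) {
  hfiles <- sort(list.files(file.path(dir, "healthy"), full.names = TRUE))
  vfiles <- sort(list.files(file.path(dir, "samples"), full.names = TRUE))
  list(
    healthy_pool = lapply(hfiles, read_variant_table),
    wbc_db = read_wbc_database(file.path(dir, "wbc_database.tsv")),
    variant_files = stats::setNames(
      vfiles, sub("\\.tsv$", "", basename(vfiles))),
    copy_ratios = read_copy_ratios(file.path(dir, "copy_ratios.tsv")),
    clinical = read_clinical(file.path(dir, "clinical.csv")),
    driver_catalogue = read_driver_catalogue(
      file.path(dir, "driver_catalogue.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  )
}
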