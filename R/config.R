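#' Fixed analysis thresholds for ctDNA genomic features
#'
#' Bundles the cutoffs used throughout the pipeline: copy-ratio thresholds for
#' calling gene amplification and deletion, the mutation-burden and
#' copy-number-load cutoffs separating high from low samples, and the clinical
#' CEA cutoff. The defaults are the values applied consistently to both the
#' HER2-targeted and immunotherapy cohorts.
#'
#' @param cnv_gain_fold Copy ratio at or above which a gene is called
#'   amplified (gain). Default 1.4.
#' @param cnv_loss_fold Copy ratio at or below which a gene is called deleted
#'   (loss). Default 0.65.
#' @param tmb_high_cutoff Mutations per megabase at or above which a sample is
#'   TMB-high. Default 8.5.
#' @param tcl_high_cutoff Total copy-number load (count of amplified plus
#'   deleted genes) at or above which a sample is TCL-high. Default 2.
#' @param cea_cutoff Serum carcinoembryonic antigen cutoff in ng/mL.
#'   Default 5.
#' @return An object of class `ctdna_thresholds` (a named list).
#' @examples
#' th <- threshold_config()
#' th$tmb_high_cutoff
#' @export
threshold_config <- function(cnv_gain_fold = 1.4, cnv_loss_fold = 0.65,
                             tmb_high_cutoff = 8.5, tcl_high_cutoff = 2,
                             cea_cutoff = 5) {
  stopifnot(
    is.numeric(cnv_gain_fold), cnv_gain_fold > 1,
    is.numeric(cnv_loss_fold), cnv_loss_fold > 0, cnv_loss_fold < 1,
    is.numeric(tmb_high_cutoff), tmb_high_cutoff > 0,
    is.numeric(tcl_high_cutoff), tcl_high_cutoff > 0,
    is.numeric(cea_cutoff), cea_cutoff > 0
  )
  structure(
    list(cnv_gain_fold = cnv_gain_fold, cnv_loss_fold = cnv_loss_fold,
         tmb_high_cutoff = tmb_high_cutoff, tcl_high_cutoff = tcl_high_cutoff,
         cea_cutoff = cea_cutoff),
    class = "ctdna_thresholds"
  )
}

#' @export
print.ctdna_thresholds <- function(x, ...) {
  cat("ctDNA feature thresholds:\n")
  cat(sprintf("  CNV gain fold  >= %g\n", x$cnv_gain_fold))
  cat(sprintf("  CNV loss fold  <= %g\n", x$cnv_loss_fold))
  cat(sprintf("  TMB high       >= %g mut/Mb\n", x$tmb_high_cutoff))
  cat(sprintf("  TCL high       >= %g genes\n", x$tcl_high_cutoff))
  cat(sprintf("  CEA cutoff     %g ng/mL\n", x$cea_cutoff))
  invisible(x)
}

#' Default gene symbols used by the built-in panel
#'
#' A compact stand-in for a large (425-gene) pan-cancer panel, anchored on
#' genes recurrently altered in gastric cancer. `ERBB2` is mandatory because
#' its copy ratio drives the amplification status used for stratification.
#'
#' @return Character vector of gene symbols.
#' @export
default_panel_genes <- function() {
  c("ERBB2", "TP53", "CDK12", "CCNE1", "ALK", "APC", "FLT1", "NOTCH2",
    "XPC", "ERBB4", "STAG2", "BCR", "KRAS", "PIK3CA", "MYC", "EGFR",
    "MET", "FGFR2", "CDH1", "ARID1A", "RHOA", "SMAD4", "CCND1", "PTEN")
}

#' Targeted-panel definition
#'
#' Describes the assayed panel: its gene content, the coding footprint used as
#' the TMB denominator, and an optional driver catalogue of known hotspot
#' variants excluded from the TMB count.
#'
#' @param genes Character vector of panel gene symbols; must contain `ERBB2`.
#' @param coding_footprint_mb Megabases of assayed coding sequence, the TMB
#'   denominator. The default 1.2 Mb is a typical footprint for a 425-gene
#'   panel; TMB is undefined without a footprint so it must always be pinned
#'   explicitly when absolute values matter.
#' @param driver_catalogue `NULL` or a data frame with columns `chrom`, `pos`,
#'   `ref`, `alt` (and optionally `gene`) listing known driver hotspots to
#'   exclude from TMB. `NULL` means an empty catalogue. See
#'   [read_driver_catalogue()] for the shipped editable example.
#' @return An object of class `ctdna_panel`.
#' @export
panel_definition <- function(genes = default_panel_genes(),
                             coding_footprint_mb = 1.2,
                             driver_catalogue = NULL) {
  stopifnot(is.character(genes), length(genes) > 0,
            is.numeric(coding_footprint_mb), coding_footprint_mb > 0)
  if (!"ERBB2" %in% genes)
    stop("panel must contain ERBB2", call. = FALSE)
  driver_keys <- character(0)
  if (!is.null(driver_catalogue)) {
    req <- c("chrom", "pos", "ref", "alt")
    if (!all(req %in% names(driver_catalogue)))
      stop("driver_catalogue needs columns chrom, pos, ref, alt",
           call. = FALSE)
    driver_keys <- variant_key(driver_catalogue)
  }
  structure(
    list(genes = genes, coding_footprint_mb = coding_footprint_mb,
         driver_catalogue = driver_catalogue, driver_keys = driver_keys),
    class = "ctdna_panel"
  )
}

#' Read a driver-hotspot catalogue
#'
#' Reads a TSV with columns `gene, chrom, pos, ref, alt, protein_change`
#' listing hotspot variants excluded from TMB. The file shipped at
#' `system.file("extdata", "driver_hotspots_synthetic.tsv", package =
#' "ctdnamon")` is a small synthetic example on the built-in panel
#' coordinates, meant to be replaced by a real catalogue for real panels.
#'
#' @param path Path to the TSV; defaults to the shipped synthetic example.
#' @return Data frame usable as `driver_catalogue` in [panel_definition()].
#' @export
read_driver_catalogue <- function(path = system.file(
  "extdata", "driver_hotspots_synthetic.tsv", package = "ctdnamon")) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(chrom = "character",
                                      ref = "character",
                                      alt = "character"))
}

#' Allele-specific variant key
#'
#' Builds the `chrom:pos:ref:alt` key under which variants are matched across
#' the WBC database, the background model, and the driver catalogue.
#' Recurrence and background statistics are allele-specific, matching VCF
#' semantics.
#'
#' @param x Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Simulation settings for a synthetic ctDNA monitoring cohort
#'
#' Defines the study conditions the simulator emulates: a cohort sampled every
#' two treatment cycles, a 50-individual healthy plasma pool, a 400-patient
#' WBC artifact database, exponential tumor-fraction decline under effective
#' therapy with exponential regrowth after resistance, variant allele
#' fractions and gene copy ratios diluted by tumor fraction, CEA correlated
#' with tumor fraction, and imaging progression that lags the molecular
#' signal.
#'
#' @param n_patients Cohort size. Default 40.
#' @param n_healthy_pool Healthy plasma individuals for the background model.
#'   Default 50.
#' @param n_wbc_samples Patients in the WBC artifact database. Default 400.
#' @param panel A [panel_definition()]; sites are laid out deterministically
#'   over its genes.
#' @param sites_per_gene Assayable coding positions simulated per panel gene.
#'   Default 10.
#' @param sampling_interval_days Days between plasma draws and between CT
#'   scans (two 21-day treatment cycles). Default 42.
#' @param max_draws Maximum number of plasma draws per patient including
#'   baseline; follow-up also stops at the scan that calls imaging
#'   progression. Default 12.
#' @param responder_fraction Probability a patient responds to therapy.
#'   Default 0.6.
#' @param decay_rate Per-day exponential decline of tumor fraction while
#'   responding (k). Default 0.06 (ctDNA half-life of about 12 days, so
#'   responders reach a deep molecular response before resistance).
#' @param regrowth_rate Per-day exponential rise of tumor fraction after
#'   resistance (g). Default 0.03.
#' @param nonresponder_growth_rate Per-day rise for primary non-responders,
#'   whose disease progresses slowly from baseline without an initial
#'   response. Default 0.008.
#' @param baseline_tumor_fraction Length-2 range for the baseline tumor
#'   fraction f0. Default c(0.08, 0.5) (advanced disease).
#' @param resistance_window Length-2 range (days) for the resistance onset
#'   time of responders that progress; resistance emerges from minimal
#'   residual disease after a deep response. Default c(90, 270).
#' @param nonprogressor_fraction Probability a responder never develops
#'   resistance within follow-up. Default 0.25.
#' @param n_clonal_range Integer range for the number of clonal somatic
#'   variants per patient. Default c(8, 30).
#' @param truncal_fraction Fraction of a patient's somatic variants that are
#'   truncal (present in essentially every tumor cell); the rest are
#'   subclonal. A variant's noise-free allele fraction is c_i * f(t) / 2
#'   (heterozygous variant in a diploid background) with clonal fraction c_i
#'   drawn from `truncal_c_range` or `subclonal_c_range`. Default 0.7.
#' @param truncal_c_range Clonal-fraction range of truncal variants.
#'   Default c(0.75, 1).
#' @param subclonal_c_range Clonal-fraction range of subclonal variants.
#'   Default c(0.1, 0.4).
#' @param emergent_rate Poisson mean of the number of new variants introduced
#'   at resistance onset. Default 0.5.
#' @param erbb2_amp_fraction Probability a patient's tumor carries ERBB2
#'   amplification. Default 0.7.
#' @param erbb2_cn_range Tumor ERBB2 copies when amplified; HER2-driven
#'   tumors typically carry many extra copies. Default c(8, 18).
#' @param other_gain_prob,other_loss_prob Per-gene probabilities of
#'   amplification/deletion for non-ERBB2 genes. Defaults 0.05 each.
#' @param site_error_shape Length-2 Beta shape parameters of the per-site
#'   sequencing-noise allele fraction. `c(0, 1)` is the degenerate point mass
#'   at zero (noise off). Default c(20, 9980), i.e. mean 0.002 with the
#'   tight per-site concentration of error-suppressed panel sequencing.
#' @param depth Sequencing depth per site. Default 5000.
#' @param min_alt_reads Minimum supporting reads for a row to be emitted in a
#'   patient variant table. Default 3.
#' @param copy_noise_sd Gaussian noise SD on observed copy ratios.
#'   Default 0.05.
#' @param cea_coef Slope of the affine CEA link CEA = baseline_CEA *
#'   (1 + cea_coef * f). Default 8.
#' @param cea_sdlog Log-normal multiplicative noise SD on CEA. Default 0.25.
#' @param cea_high_fraction Fraction of patients with baseline CEA above the
#'   5 ng/mL clinical cutoff. Default 0.5.
#' @param blood_sdlog Log-normal multiplicative noise SD on absolute blood
#'   counts. Default 0.05.
#' @param ct_detection_threshold Tumor fraction at which a CT scan calls
#'   progression (theta_CT). Default 0.35; chosen jointly with the regrowth
#'   rate so that imaging detection lags the molecular cutoff crossings by
#'   at least one sampling interval of growth.
#' @param artifact_rate Fraction of panel sites planted as recurrent WBC
#'   artifacts (occurrence above 10 percent of WBC samples). Default 0.05.
#' @param tissue_discordance_prob Probability the tissue HER2 label disagrees
#'   with the tumor ERBB2 copy state (assay error). Default 0.03.
#' @param tissue_biopsy_fraction Fraction of patients with a biopsied tumor
#'   and hence a tissue HER2 record available for concordance analysis.
#'   Default 0.45.
#' @param start_date First possible enrollment date. Default "2017-01-01".
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `ctdna_sim_config`.
#' @export
simulation_config <- function(n_patients = 40,
                              n_healthy_pool = 50,
                              n_wbc_samples = 400,
                              panel = panel_definition(),
                              sites_per_gene = 10,
                              sampling_interval_days = 42,
                              max_draws = 12,
                              responder_fraction = 0.6,
                              decay_rate = 0.06,
                              regrowth_rate = 0.03,
                              nonresponder_growth_rate = 0.008,
                              baseline_tumor_fraction = c(0.08, 0.5),
                              resistance_window = c(90, 270),
                              nonprogressor_fraction = 0.25,
                              n_clonal_range = c(8L, 30L),
                              truncal_fraction = 0.7,
                              truncal_c_range = c(0.75, 1),
                              subclonal_c_range = c(0.1, 0.4),
                              emergent_rate = 0.5,
                              erbb2_amp_fraction = 0.7,
                              erbb2_cn_range = c(8, 18),
                              other_gain_prob = 0.05,
                              other_loss_prob = 0.05,
                              site_error_shape = c(20, 9980),
                              depth = 5000,
                              min_alt_reads = 3,
                              copy_noise_sd = 0.05,
                              cea_coef = 8,
                              cea_sdlog = 0.25,
                              cea_high_fraction = 0.5,
                              blood_sdlog = 0.05,
                              ct_detection_threshold = 0.35,
                              artifact_rate = 0.05,
                              tissue_discordance_prob = 0.03,
                              tissue_biopsy_fraction = 0.45,
                              start_date = as.Date("2017-01-01"),
                              seed = 1L) {
  stopifnot(
    n_patients >= 1, n_healthy_pool >= 1, n_wbc_samples >= 1,
    inherits(panel, "ctdna_panel"), sites_per_gene >= 1,
    sampling_interval_days >= 1, max_draws >= 2,
    responder_fraction >= 0, responder_fraction <= 1,
    decay_rate >= 0, regrowth_rate >= 0,
    length(baseline_tumor_fraction) == 2,
    all(baseline_tumor_fraction > 0), all(baseline_tumor_fraction < 1),
    length(site_error_shape) == 2, all(site_error_shape >= 0),
    depth >= 1, copy_noise_sd >= 0, cea_sdlog >= 0,
    ct_detection_threshold > 0, ct_detection_threshold < 1,
    artifact_rate >= 0, artifact_rate <= 1
  )
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_healthy_pool = as.integer(n_healthy_pool),
    n_wbc_samples = as.integer(n_wbc_samples),
    panel = panel, sites_per_gene = as.integer(sites_per_gene),
    sampling_interval_days = as.integer(sampling_interval_days),
    max_draws = as.integer(max_draws),
    responder_fraction = responder_fraction,
    decay_rate = decay_rate, regrowth_rate = regrowth_rate,
    nonresponder_growth_rate = nonresponder_growth_rate,
    baseline_tumor_fraction = baseline_tumor_fraction,
    resistance_window = resistance_window,
    nonprogressor_fraction = nonprogressor_fraction,
    n_clonal_range = as.integer(n_clonal_range),
    truncal_fraction = truncal_fraction,
    truncal_c_range = truncal_c_range,
    subclonal_c_range = subclonal_c_range,
    emergent_rate = emergent_rate,
    erbb2_amp_fraction = erbb2_amp_fraction,
    erbb2_cn_range = erbb2_cn_range,
    other_gain_prob = other_gain_prob, other_loss_prob = other_loss_prob,
    site_error_shape = site_error_shape,
    depth = as.integer(depth), min_alt_reads = as.integer(min_alt_reads),
    copy_noise_sd = copy_noise_sd,
    cea_coef = cea_coef, cea_sdlog = cea_sdlog,
    cea_high_fraction = cea_high_fraction,
    blood_sdlog = blood_sdlog,
    ct_detection_threshold = ct_detection_threshold,
    artifact_rate = artifact_rate,
    tissue_discordance_prob = tissue_discordance_prob,
    tissue_biopsy_fraction = tissue_biopsy_fraction,
    start_date = as.Date(start_date), seed = as.integer(seed)
  )
  structure(cfg, class = "ctdna_sim_config")
}

#' Turn off every stochastic component of a simulation configuration
#'
#' Returns a copy of `config` with the site noise a point mass at zero and
#' the copy-ratio, CEA and blood-count noise terms set to 0, so that every
#' observed quantity equals its closed-form noise-free value. Used by the
#' exact-recovery tests.
#'
#' @param config A [simulation_config()].
#' @return Modified configuration.
#' @export
noiseless <- function(config) {
  stopifnot(inherits(config, "ctdna_sim_config"))
  config$site_error_shape <- c(0, 1)
  config$copy_noise_sd <- 0
  config$cea_sdlog <- 0
  config$blood_sdlog <- 0
  config
}

# Mean and SD of the configured Beta site-noise distribution; the implied
# detection limit (mean + 3 SD) is what the downstream denoiser converges to,
# and is used to define noise-free ground-truth TMB.
site_noise_moments <- function(site_error_shape) {
  a <- site_error_shape[1]
  b <- site_error_shape[2]
  if (a <= 0) return(c(mean = 0, sd = 0))
  m <- a / (a + b)
  v <- a * b / ((a + b)^2 * (a + b + 1))
  c(mean = m, sd = sqrt(v))
}

# Smallest true AF reliably detectable after denoising. Site noise is
# additive on top of the true AF and the retention rule subtracts the site
# mean, so a variant survives when its true AF exceeds 3 SD of the healthy
# background AF, whose variance combines the per-site error distribution
# with binomial read sampling at the configured depth.
detection_limit_af <- function(config) {
  mo <- site_noise_moments(config$site_error_shape)
  m <- unname(mo["mean"])
  3 * sqrt(unname(mo["sd"])^2 + m * (1 - m) / config$depth)
}
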