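#' Build the healthy-plasma background error model
#'
#' Per panel site (allele-specific key `chrom:pos:ref:alt`), computes the
#' mean and sample standard deviation (n - 1 denominator) of the allele
#' fractions observed across the healthy-plasma pool. An individual in which
#' a site was not reported contributes an AF of 0, so every site has
#' `n_obs` equal to the pool size and a defined SD. A panel-wide fallback
#' (pooled mean/SD over all site-observations) covers variants at sites the
#' pool never assayed.
#'
#' @param healthy_tables List of variant-table data frames, one per healthy
#'   individual (as from [generate_background_pool()] or read from disk).
#' @param panel_sites Optional data frame with `chrom, pos, ref, alt` listing
#'   every assayable site; sites never observed in the pool then enter the
#'   model with mean 0 and SD 0. Defaults to the union of observed sites.
#' @return An object of class `ctdna_background_model` with elements
#'   `sites` (data frame `key, mean_af, sd_af, n_obs`), `n_samples`,
#'   `fallback` (`mean_af`, `sd_af`) and `sd_convention`.
#' @export
build_background_model <- function(healthy_tables, panel_sites = NULL) {
  if (!is.list(healthy_tables) || length(healthy_tables) == 0)
    stop("empty healthy pool", call. = FALSE)
  if (is.data.frame(healthy_tables)) healthy_tables <- list(healthy_tables)
  n <- length(healthy_tables)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- healthy_tables[[i]]
    if (!nrow(x)) return(NULL)
    data.frame(key = variant_key(x), af = x$af, stringsAsFactors = FALSE)
  }))
  keys <- if (!is.null(panel_sites)) unique(variant_key(panel_sites))
          else unique(obs$key)
  if (is.null(keys)) stop("no sites to model", call. = FALSE)
  if (!is.null(obs)) {
    extra <- setdiff(unique(obs$key), keys)
    keys <- c(keys, extra)
  }
  sum_af <- stats::setNames(numeric(length(keys)), keys)
  sum_af2 <- sum_af
  if (!is.null(obs)) {
    s1 <- tapply(obs$af, obs$key, sum)
    s2 <- tapply(obs$af^2, obs$key, sum)
    sum_af[names(s1)] <- s1
    sum_af2[names(s2)] <- s2
  }
  # absent observations are imputed as 0, so moments over n per site
  mean_af <- sum_af / n
  var_af <- if (n > 1) pmax(sum_af2 - n * mean_af^2, 0) / (n - 1)
            else rep(0, length(keys))
  sites <- data.frame(key = keys, mean_af = unname(mean_af),
                      sd_af = unname(sqrt(var_af)), n_obs = n,
                      stringsAsFactors = FALSE)
  # pooled fallback over the same zero-imputed site-by-individual matrix
  total_obs <- n * length(keys)
  fb_mean <- sum(sum_af) / total_obs
  fb_var <- if (total_obs > 1)
    max(sum(sum_af2) - total_obs * fb_mean^2, 0) / (total_obs - 1) else 0
  structure(list(sites = sites, n_samples = n,
                 fallback = list(mean_af = fb_mean, sd_af = sqrt(fb_var)),
                 sd_convention =
                   "sample SD (n-1); absent observations imputed as AF 0"),
            class = "ctdna_background_model")
}

#' @export
print.ctdna_background_model <- function(x, ...) {
  cat(sprintf(
    "Background error model: %d sites over %d healthy individuals\n",
    nrow(x$sites), x$n_samples))
  cat(sprintf("  pooled mean AF %.5f, SD %.5f; %s\n",
              x$fallback$mean_af, x$fallback$sd_af, x$sd_convention))
  invisible(x)
}

empty_removal_log <- function() {
  data.frame(key = character(0), gene = character(0), af = numeric(0),
             reason = character(0), detail = numeric(0),
             stringsAsFactors = FALSE)
}

removal_log <- function(variants, reason, detail) {
  if (!nrow(variants)) return(empty_removal_log())
  data.frame(key = variant_key(variants), gene = variants$gene,
             af = variants$af, reason = reason, detail = detail,
             stringsAsFactors = FALSE)
}

#' Remove recurrent white-blood-cell artifacts
#'
#' A variant is considered a likely artifact and removed when it was detected
#' in strictly more than `max_recurrence` (default 10 percent) of the WBC
#' database samples. Variants absent from the database pass. A variant at
#' exactly the 10 percent boundary is retained (the rule is strict).
#'
#' @param variants Variant-call data frame.
#' @param wbc_db A [wbc_database()].
#' @param max_recurrence Recurrence fraction above which a variant is
#'   removed. Default 0.10.
#' @return List with `retained` (variant rows) and `removed` (log with
#'   reason `wbc_recurrent` and the recurrence fraction in `detail`).
#' @export
wbc_artifact_filter <- function(variants, wbc_db, max_recurrence = 0.10) {
  stopifnot(inherits(wbc_db, "wbc_database"), wbc_db$total_samples >= 1)
  if (!nrow(variants))
    return(list(retained = variants, removed = empty_removal_log()))
  keys <- variant_key(variants)
  count <- wbc_db$occurrence$count[match(keys, wbc_db$occurrence$key)]
  count[is.na(count)] <- 0L
  frac <- count / wbc_db$total_samples
  drop <- frac > max_recurrence
  list(retained = variants[!drop, , drop = FALSE],
       removed = removal_log(variants[drop, , drop = FALSE],
                             "wbc_recurrent", frac[drop]))
}

#' Denoise variants against the healthy-plasma background model
#'
#' A variant is retained only when its allele fraction lies strictly more
#' than `sd_multiplier` (default 3) standard deviations above the mean AF of
#' the healthy-plasma pool at its site; variants at sites absent from the
#' model are judged against the pooled panel-wide fallback statistics. An AF
#' of 0 is never retained. Optionally, a one-sided binomial tail test can
#' additionally require the supporting reads to be significantly beyond the
#' site's background error rate.
#'
#' @param variants Variant-call data frame (non-negative AFs).
#' @param model A `ctdna_background_model` from [build_background_model()].
#' @param sd_multiplier Number of SDs above the site mean a variant's AF must
#'   strictly exceed. Default 3.
#' @param binomial_alpha `NULL` (default, off) or a one-sided significance
#'   level: when set, a variant must also have
#'   `P(X >= alt_reads | depth, site mean AF) < binomial_alpha`.
#' @return List with `retained` and `removed` (reason `background_noise`,
#'   retention threshold in `detail`).
#' @export
background_denoise <- function(variants, model, sd_multiplier = 3,
                               binomial_alpha = NULL) {
  stopifnot(inherits(model, "ctdna_background_model"))
  if (!nrow(variants))
    return(list(retained = variants, removed = empty_removal_log()))
  if (any(variants$af < 0)) stop("negative AF", call. = FALSE)
  keys <- variant_key(variants)
  idx <- match(keys, model$sites$key)
  mean_af <- ifelse(is.na(idx), model$fallback$mean_af,
                    model$sites$mean_af[idx])
  sd_af <- ifelse(is.na(idx), model$fallback$sd_af,
                  model$sites$sd_af[idx])
  threshold <- mean_af + sd_multiplier * sd_af
  # strict ">" with a guard far below any meaningful AF difference, so the
  # boundary does not depend on the binary representation of decimal input
  keep <- variants$af > threshold + 1e-12
  if (!is.null(binomial_alpha)) {
    pval <- stats::pbinom(variants$alt_reads - 1, variants$depth,
                          pmax(mean_af, 1e-12), lower.tail = FALSE)
    keep <- keep & pval < binomial_alpha
  }
  list(retained = variants[keep, , drop = FALSE],
       removed = removal_log(variants[!keep, , drop = FALSE],
                             "background_noise", threshold[!keep]))
}

#' Two-stage artifact elimination
#'
#' Applies the WBC recurrence filter then the background denoiser (the two
#' criteria are independent per-variant predicates, so the order does not
#' affect the surviving set) and returns the survivors with a merged removal
#' log.
#'
#' @inheritParams wbc_artifact_filter
#' @inheritParams background_denoise
#' @return List with `retained` and `removed`.
#' @export
denoise_variants <- function(variants, wbc_db, model, max_recurrence = 0.10,
                             sd_multiplier = 3, binomial_alpha = NULL) {
  s1 <- wbc_artifact_filter(variants, wbc_db, max_recurrence)
  s2 <- background_denoise(s1$retained, model, sd_multiplier, binomial_alpha)
  list(retained = s2$retained, removed = rbind(s1$removed, s2$removed))
}
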