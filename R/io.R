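#' Read a somatic variant table
#'
#' Reads one plasma sample's somatic alterations. Two formats are accepted:
#' the package's TSV dialect with columns
#' `chrom, pos, ref, alt, gene, effect, af, alt_reads, depth`, or a VCF
#' (v4.2, 1-based positions) whose records carry `AF` plus `AD`/`DP` in the
#' genotype fields (requires the vcfR package; gene and effect are taken from
#' `GENE`/`EFFECT` INFO keys when present, otherwise left `NA`/`other`).
#'
#' @param path File path; `.vcf` extension dispatches to the VCF reader.
#' @return Data frame of validated variant calls.
#' @export
read_variant_table <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE))
    return(read_variant_vcf(path))
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = list(chrom = "character",
                                           ref = "character",
                                           alt = "character"))
  validate_variants(x, context = path)
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  n <- nrow(fix)
  get1 <- function(el) if (is.null(el) || !ncol(el)) rep(NA, n) else el[, 1]
  af <- suppressWarnings(as.numeric(get1(vcfR::extract.gt(v, "AF"))))
  dp <- suppressWarnings(as.integer(get1(vcfR::extract.gt(v, "DP"))))
  ad <- get1(vcfR::extract.gt(v, "AD"))
  alt_reads <- suppressWarnings(
    as.integer(vapply(strsplit(as.character(ad), ","), function(p)
      if (length(p) >= 2) p[2] else NA_character_, character(1))))
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"),
                                      fix$INFO))
    out <- rep(NA_character_, n)
    hit <- grepl(paste0(key, "="), fix$INFO)
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  gene <- info_field("GENE")
  effect <- info_field("EFFECT")
  effect[is.na(effect)] <- "other"
  x <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT, gene = gene,
                  effect = effect, af = af, alt_reads = alt_reads,
                  depth = dp, stringsAsFactors = FALSE)
  validate_variants(x, context = path)
}

#' @rdname read_variant_table
#' @param x Data frame of variant calls.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

valid_effects <- c("missense", "nonsense", "synonymous", "frameshift_indel",
                   "inframe_indel", "splice", "other")

# Structural validation of a variant table: required columns, AF in [0,1],
# alt_reads <= depth, AF consistent with alt_reads/depth within rounding.
validate_variants <- function(x, context = "variant table") {
  req <- c("chrom", "pos", "ref", "alt", "gene", "effect", "af",
           "alt_reads", "depth")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop(sprintf("%s: missing columns %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(x) == 0) return(x[req])
  bad <- which(x$af < 0 | x$af > 1)
  if (length(bad))
    stop(sprintf("%s: af outside [0,1] at row %d", context, bad[1]),
         call. = FALSE)
  both <- which(!is.na(x$alt_reads) & !is.na(x$depth))
  if (any(x$alt_reads[both] > x$depth[both]))
    stop(sprintf("%s: alt_reads > depth", context), call. = FALSE)
  # AF must agree with alt/depth up to read-count rounding (half a read).
  incons <- both[abs(x$af[both] * x$depth[both] - x$alt_reads[both]) > 0.5 +
                   1e-8]
  if (length(incons))
    stop(sprintf("%s: af inconsistent with alt_reads/depth at row %d",
                 context, incons[1]), call. = FALSE)
  unknown <- setdiff(unique(x$effect), valid_effects)
  if (length(unknown))
    stop(sprintf("%s: unknown effect class '%s'", context, unknown[1]),
         call. = FALSE)
  x[req]
}

#' Read / write a per-gene copy-ratio table
#'
#' TSV with columns `sample_id, gene, fold`: the observed copy ratio of each
#' gene relative to the normal diploid baseline.
#'
#' @param path File path.
#' @return Data frame with columns `sample_id, gene, fold`.
#' @export
read_copy_ratios <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "gene", "fold")
  if (!all(req %in% names(x)))
    stop(sprintf("%s: copy-ratio table needs columns %s", path,
                 paste(req, collapse = ", ")), call. = FALSE)
  if (any(x$fold < 0))
    stop(sprintf("%s: negative copy ratio", path), call. = FALSE)
  x[req]
}

#' @rdname read_copy_ratios
#' @param x Data frame with columns `sample_id, gene, fold`.
#' @export
write_copy_ratios <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the clinical table
#'
#' CSV with one row per plasma sample:
#' `patient_id, sample_id, date, timepoint, response, cea_ng_ml, anc, amc,
#' alc, tissue_her2`. `date` is ISO-8601; `timepoint` is `BL` for the
#' pre-treatment baseline, `FP` for the first response evaluation after
#' treatment, then free labels; `response` is the RECIST assessment (`PR`,
#' `SD`, `PD`) at that visit's CT evaluation, empty when the visit had no
#' scan; blood counts are absolute counts in 1e9/L; `tissue_her2` is
#' `positive`/`negative`/empty.
#'
#' @param path File path.
#' @return Data frame with `date` parsed to `Date`.
#' @export
read_clinical <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  req <- c("patient_id", "sample_id", "date", "timepoint", "response",
           "cea_ng_ml", "anc", "amc", "alc", "tissue_her2")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop(sprintf("%s: clinical table missing columns %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  x$date <- as.Date(x$date)
  if (anyNA(x$date))
    stop(sprintf("%s: unparseable date at row %d", path,
                 which(is.na(x$date))[1]), call. = FALSE)
  x[req]
}

#' @rdname read_clinical
#' @param x Clinical data frame.
#' @export
write_clinical <- function(x, path) {
  y <- x
  y$date <- format(as.Date(y$date))
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a WBC artifact occurrence database
#'
#' TSV with columns `chrom, pos, ref, alt, gene, count, total`: for each
#' variant, the number of white-blood-cell samples (out of `total`) in which
#' it was detected. Used by [wbc_artifact_filter()].
#'
#' @param path File path.
#' @return An object of class `wbc_database`.
#' @export
read_wbc_database <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = list(chrom = "character",
                                           ref = "character",
                                           alt = "character"))
  req <- c("chrom", "pos", "ref", "alt", "count", "total")
  if (!all(req %in% names(x)))
    stop(sprintf("%s: WBC database needs columns %s", path,
                 paste(req, collapse = ", ")), call. = FALSE)
  wbc_database(x, total_samples = if (nrow(x)) x$total[1] else 1L)
}

#' @rdname read_wbc_database
#' @param x A `wbc_database` object.
#' @export
write_wbc_database <- function(x, path) {
  stopifnot(inherits(x, "wbc_database"))
  tab <- x$occurrence
  tab$total <- x$total_samples
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a WBC artifact database object
#'
#' @param occurrence Data frame with columns `chrom, pos, ref, alt` (plus
#'   optional annotation columns) and `count`, the number of WBC samples
#'   carrying the variant.
#' @param total_samples Total number of WBC samples screened.
#' @return An object of class `wbc_database`.
#' @export
wbc_database <- function(occurrence, total_samples) {
  stopifnot(total_samples >= 1)
  if (nrow(occurrence)) {
    stopifnot(all(occurrence$count >= 0),
              all(occurrence$count <= total_samples))
  }
  occurrence$key <- variant_key(occurrence)
  structure(list(occurrence = occurrence,
                 total_samples = as.integer(total_samples)),
            class = "wbc_database")
}

#' @export
print.wbc_database <- function(x, ...) {
  frac <- if (nrow(x$occurrence))
    mean(x$occurrence$count / x$total_samples > 0.10) else 0
  cat(sprintf("WBC artifact database: %d variants over %d samples (%.1f%% recurrent >10%%)\n",
              nrow(x$occurrence), x$total_samples, 100 * frac))
  invisible(x)
}
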