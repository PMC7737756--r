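Package: ctdnamon
Title: Longitudinal Circulating Tumor DNA Monitoring and Outcome Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Plasma circulating tumor DNA (ctDNA) analytics for serially
    sampled targeted-therapy cohorts. Somatic variant calls are denoised
    against a white-blood-cell artifact database and a healthy-plasma
    background error model; per-sample genomic features are derived (panel
    tumor mutation burden, gene-level copy-number calls, total copy-number
    load, ERBB2 amplification status, maximum variant allele frequency,
    neutrophil- and monocyte-to-lymphocyte ratios); feature trajectories are
    normalized to their cutoffs to call molecular progression ahead of
    imaging, with lead-time and emerging-alteration analyses; and cohorts are
    stratified for response-rate, concordance, and Kaplan-Meier survival
    summaries. A synthetic-cohort simulator with full ground truth supports
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
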