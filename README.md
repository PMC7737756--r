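# ctdnamon

Longitudinal plasma ctDNA monitoring and outcome stratification for
targeted-therapy cohorts.

Serial liquid biopsies can track a tumor's response to therapy between CT
evaluations: as treatment takes effect, the tumor fraction in cell-free DNA
falls, and it recovers when resistance emerges — often before imaging shows
progression. `ctdnamon` implements the analytics for this setting, from
somatic variant calls onward, for cohorts such as HER2-positive gastric
cancer patients under anti-HER2 therapy:

* **Denoising** — variants recurrent in strictly more than 10% of a
  white-blood-cell reference database are removed as clonal-hematopoiesis
  or technical artifacts; the rest survive only if their allele fraction AF
  exceeds the healthy-plasma background by more than three standard
  deviations at the site: retain iff `AF > mean_healthy + 3 * SD_healthy`.
* **Per-sample genomic features** — panel tumor mutation burden
  (coding substitutions and indels, synonymous included, known drivers
  excluded, per Mb of coding footprint; high at ≥ 8.5 mut/Mb), gene-level
  copy-number calls (gain at copy ratio ≥ 1.4, loss at ≤ 0.65), total
  copy-number load TCL (count of gained + lost genes; high at ≥ 2), ERBB2
  amplification status (ratio ≥ 1.4), MaxiVAF (the sample's maximum AF, a
  tumor-fraction proxy), and NLR/MLR blood-count ratios.
* **Molecular progression calling** — feature trajectories are normalized
  to cutoff ratios (ERBB2 fold / 1.4, TCL / 2, TMB / 8.5, CEA / 5 ng/mL);
  when a feature re-elevates beyond its cutoff for at least two consecutive
  post-baseline draws, the first point of the run is the ctDNA-based PD
  date, and its lead time over CT-based PD is reported in days.
* **Cohort outcomes** — ORR/DCR and Kaplan-Meier PFS (log-rank test) per
  baseline ERBB2-by-TMB stratum and per baseline-to-first-point dynamics
  category (`dn`, `up`, `remainL`, `remainH`), plasma-tissue ERBB2
  concordance (percent agreement and Cohen's kappa), and Spearman
  correlation of each feature with serum CEA.
* **Synthetic cohorts** — a simulator with piecewise-exponential
  tumor-fraction kinetics, dilution-based variant AFs and copy ratios,
  planted WBC artifacts and a healthy background pool generates complete
  cohorts with ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(ctdnamon)

cfg <- simulation_config(seed = 1)      # 40 patients, draws every 42 days
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic ctDNA cohort: 40 patients, 340 plasma samples, 50 healthy, WBC n=400

emit_cohort(cohort, "gc_cohort")        # TSV/CSV/JSON cohort directory
report <- run_pipeline("gc_cohort", out_dir = "gc_report", verbose = FALSE)
report
#> ctDNA monitoring report
#>   patients: 40, samples: 340, variants in/removed: 80886/78038
#>   ORR 62.5% (25/40), DCR 80.0% (32/40), mPFS not reached
#>   ctDNA PD ahead of CT in 4/10 (40.0%), mean advance 105.0 days
#>   CEA PD ahead of CT in 3/10 (30.0%), mean advance 56.0 days
#>   plasma-tissue ERBB2 concordance 95.5% (kappa 0.891)
```

Of the 80,886 variant rows entering the pipeline, 78,038 are removed as WBC
artifacts or background noise. Ten patients have a CT-confirmed progression
plus at least three plasma draws; in four of them (40%) the ctDNA features
re-elevate beyond their cutoffs at least one full draw before the CT date,
a mean of 105 days earlier. CEA crosses its 5 ng/mL cutoff ahead of CT less
often (30%), and plasma ERBB2 status agrees with the simulated tissue HER2
label in 95.5% of biopsied patients.

Per-sample features show the response-and-relapse dynamics directly — here
a patient whose TMB and ERBB2 fold collapse on treatment:

```r
head(report$features[, c("sample_id", "timepoint", "tmb", "tmb_class",
                         "tcl", "erbb2_fold", "erbb2_status", "maxivaf")], 4)
#>   sample_id timepoint      tmb tmb_class tcl erbb2_fold  erbb2_status maxivaf
#> 1   P01_S01        BL 15.83333      high   4   3.384981     amplified  0.2110
#> 2   P01_S02        FP 15.00000      high   0   1.138549 not_amplified  0.0210
#> 3   P01_S03        P3  2.50000       low   0   1.020443 not_amplified  0.0050
#> 4   P01_S04        P4  2.50000       low   0   1.007107 not_amplified  0.0056
```

and the progression calls carry their triggering feature and lead time:

```r
subset(report$monitor$calls, patient_id == "P06")[, c("source", "date", "trigger", "lead_days")]
#>   source       date trigger lead_days
#> 1     ct 2017-09-20 imaging         0
#> 2  ctdna 2017-08-09     tcl        42
```

A thin command-line wrapper covers the same stages
(`simulate | denoise | features | monitor | outcomes | run`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ctdnamon", package = "ctdnamon"))')
Rscript "$CLI" simulate --out cohort_dir --seed 7
Rscript "$CLI" run --in cohort_dir --out report_dir
```

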