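---
title: "Methods: denoising, feature extraction and progression monitoring of serial plasma ctDNA"
author: "ctdnamon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: denoising, feature extraction and progression monitoring of serial plasma ctDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnamon)
```

# Scope

`ctdnamon` analyzes serially sampled plasma circulating tumor DNA (ctDNA)
from targeted-therapy cohorts, picking up after upstream read processing:
its inputs are per-sample somatic variant calls (allele fraction, supporting
reads, depth), per-gene copy ratios, and a clinical table with visit dates,
RECIST assessments, serum CEA and blood counts. From these it performs
(i) two-stage variant denoising, (ii) per-sample genomic feature
extraction, (iii) longitudinal molecular-progression calling with lead-time
analysis against imaging, and (iv) stratified cohort outcome analysis.
A synthetic-cohort simulator with complete ground truth makes every stage
testable without access to patient data.

# Denoising

Two independent per-variant filters are applied, in either order (the
surviving set is identical):

**WBC recurrence filter.** Variants observed in strictly more than 10% of a
white-blood-cell reference database (clonal hematopoiesis and recurrent
technical artifacts) are removed. The inequality is strict: a variant seen
in exactly 10% of WBC samples is retained.

**Background error model.** From a pool of healthy-plasma samples sequenced
on the same panel, the per-site (allele-specific, keyed
`chrom:pos:ref:alt`) mean and standard deviation of the noise allele
fraction are estimated. A variant is retained only when its AF exceeds the
site mean by strictly more than 3 SD. Conventions, all recorded in the
model object:

* sample SD (n − 1 denominator); a healthy individual in which a site was
  not reported contributes AF 0, so every panel site has a defined SD over
  the full pool size;
* variants at sites absent from the model are judged against pooled
  panel-wide fallback statistics (the same zero-imputed site-by-individual
  matrix, flattened);
* the strict comparison carries an absolute guard of 1e-12 so that boundary
  behaviour does not depend on the binary representation of decimal input
  (an AF recorded as 0.0050 against a threshold of 0.002 + 3 × 0.001 is
  *at* the threshold, hence removed);
* an optional one-sided binomial tail test on supporting reads versus the
  site's mean error rate (`binomial_alpha`) is available but off by
  default: the retention criterion that is precisely specified is the AF
  rule, and the read-support language around it is ambiguous enough that we
  prefer to expose it as an explicit option.

# Per-sample features

* **TMB** — base substitutions and indels in coding regions (`missense`,
  `nonsense`, `synonymous`, `frameshift_indel`, `inframe_indel`;
  synonymous calls are deliberately included to reduce sampling noise),
  minus known driver hotspots, divided by the panel's coding footprint in
  Mb. Splice-site and unclassified calls are excluded by default (flags to
  include). The footprint default is 1.2 Mb, a typical coding footprint for
  a 425-gene pan-cancer panel; since TMB is undefined without it, analyses
  that compare absolute TMB values must pin it explicitly. The driver
  catalogue ships as a small editable table; the file installed with the
  package is a synthetic example matching the simulator's panel layout.
* **Gene CNV calls** — `gain` at copy ratio ≥ 1.4, `loss` at ≤ 0.65,
  `neutral` between; boundaries inclusive, reading "cutoff" as the first
  value inside the class, consistent with the explicitly inclusive TMB and
  TCL cutoffs.
* **TCL** — the count of genes called gain or loss; `high` at ≥ 2.
* **ERBB2 status** — `amplified` at ERBB2 copy ratio ≥ 1.4.
* **MaxiVAF** — the maximum AF among surviving variants, a tumor-fraction
  proxy; undefined (`NA`) when nothing survives denoising.
* **NLR / MLR** — absolute neutrophil (or monocyte) count divided by
  absolute lymphocyte count.

Sample classes use the fixed cutoffs TMB ≥ 8.5 mut/Mb and TCL ≥ 2 as the
primary mode (these were applied unchanged to both cohorts the design
follows); a cohort-specific top-tertile mode (`classify_features(...,
mode = "tertile")`) recomputes and reports the top-33.3% boundary instead.
TCL counts genes rather than segments because the copy-ratio interface is
gene-level.

# Longitudinal monitoring

Feature trajectories are normalized to cutoff ratios (ERBB2 fold / 1.4,
TCL / 2, TMB / 8.5, CEA / 5 ng/mL). A patient qualifies for monitoring with
a CT-confirmed progression and at least three plasma samples. The
ctDNA-based progression (PD) date is the first point of the earliest run in
which any feature is elevated beyond its cutoff at two or more consecutive
post-baseline points; ties between features qualifying on the same date
break in the fixed order ERBB2 CNV, TCL, TMB. Design decisions, each
exposed as a flag:

* **"Beyond" is strict** (ratio > 1): a TCL of exactly 2 is `high` in
  static classification but not *elevated beyond* its cutoff.
* **Consecutive points** (`consecutive = TRUE`): a progression signal is
  sustained; the non-consecutive any-two-points reading is available for
  sensitivity analysis.
* **Baseline can never be the PD point**, and by default a feature must
  have been at or below its cutoff at some earlier time point before a run
  can qualify (`require_reset = TRUE`): progression on therapy is a
  *re*-elevation. Without this requirement the rule flags responders whose
  features are still declining through the first evaluations — elevated
  since baseline but shrinking — which inverts the clinical meaning of the
  call. A feature that stays above its cutoff for the whole course carries
  no monitorable transition; such patients are reported as having no
  ctDNA-based PD rather than an arbitrary early one.

CEA-based PD applies the same rule to CEA normalized to the 5 ng/mL
clinical cutoff (the trigger rule for CEA is not separately specified
anywhere authoritative; symmetry is the least surprising choice, and the
flags apply equally). The log2 of the normalized CEA index is emitted for
display. Lead time is the integer calendar-day difference from the
molecular PD date to the CT-based PD date (the first visit assessed as
progressive disease); a patient counts as "ahead" only with a strictly
positive lead, and the mean advancement is computed over ahead patients
only. Emerging alterations are the variants (by allele-specific key) and
CNV calls present at the progression sample but absent at baseline.

Patients failing timeline invariants — duplicate draw dates, baseline not
the earliest sample — are excluded with a logged reason, never silently.

# Cohort outcomes

Best response per patient is the best visit-level RECIST assessment
(CR > PR > SD > PD; the response enum accepts CR although the motivating
cohort had none). ORR counts CR+PR, DCR additionally SD, both reported as
percentages with their count fractions. PFS runs from the baseline draw to
the first PD visit (event) or the last visit (censored); the median is read
off the Kaplan-Meier curve (earliest time with S(t) ≤ 0.5, "not reached"
when censoring dominates), with the log-rank test for group contrasts —
both via the `survival` package, the field standard. Multi-group contrasts
reduce to pairwise comparisons or the k-sample statistic. Plasma-tissue
ERBB2 concordance is summarized as percent agreement plus unweighted
Cohen's kappa with the large-sample null-variance approximation
(kappa is undefined and reported `NA` when the margins are degenerate).
Feature-CEA association uses Spearman rank correlation.

# The synthetic cohort generator

The generator emulates the study design the pipeline targets: 40 patients
sampled every two 21-day treatment cycles from baseline until the CT scan
that calls progression, a 50-individual healthy plasma pool, a 400-patient
WBC database, and a total cohort scale of roughly 300-340 plasma samples.

**Disease kinetics.** Tumor fraction follows piecewise-exponential
kinetics: responders decay as `f0 exp(-k t)` and, if resistance arises at
`t_r`, regrow as `f(t_r) exp(g (t - t_r))`; primary non-responders grow
slowly from baseline. Defaults — decay 0.06/day (ctDNA half-life about 12
days under effective therapy), regrowth 0.03/day, non-responder growth
0.008/day, resistance onset uniform on 90-270 days, baseline tumor fraction
uniform on 0.08-0.5 — were chosen once so that (a) responders reach a deep
molecular response, with the nadir below the variant detection limit before
resistance, and (b) imaging detection (at tumor fraction
`ct_detection_threshold = 0.35`) lags the molecular cutoff crossings by at
least one sampling interval of growth. Both properties are what make
re-elevation identifiable by the two-point rule and hence the recovery
tests meaningful; they are design-for-testability choices, not fitted
quantities, and single parameters can be changed freely in
`simulation_config()`.

**Observation model.** A variant with clonal fraction `c` reads out as AF
`c f(t) / 2` (heterozygous variant in a diploid background); 70% of a
patient's variants are truncal (`c` in 0.75-1) and the rest subclonal
(0.1-0.4), matching the clonal architecture implied by using MaxiVAF as a
tumor-fraction proxy. Gene copy ratios are `1 + f(t) (CN_g / 2 - 1)` plus
Gaussian noise (SD 0.05). Per-site sequencing noise is Beta-distributed
(default Beta(20, 9980): mean 0.002, tightly concentrated as in
error-suppressed panel sequencing), added to the true AF and binomially
resampled at depth 5000. `site_error_shape = c(0, 1)` is the degenerate
noiseless point mass, and `noiseless()` switches every stochastic component
off, making all observations exact closed forms. CEA follows an affine link
`baseline_CEA (1 + 8 f)` with log-normal noise; baseline CEA falls above
the 5 ng/mL cutoff for half the patients. Recurrent WBC artifacts are
planted at >10% database occurrence and carried into patient plasma with
probability equal to their occurrence fraction; somatic variants are never
planted on artifact sites, so the ideal filtered observation matches the
truth record.

**Ground truth.** The truth record stores every latent quantity: kinetic
parameters, copy numbers, clonal and emergent variants, the per-day
molecular progression time (the earliest upcrossing of any noise-free
feature ratio above 1 — `NA` when no feature ever re-exceeds its cutoff,
mirroring the monitor's re-elevation requirement), and the imaging PD day
(first scheduled scan with `f` at or above the imaging threshold).
`truth_features()` reconstructs the noise-free feature trajectory from a
truth record; the recovery tests compare the pipeline's ctDNA-PD call
against the call the same rule makes on that noise-free trajectory, which
isolates measurement noise from trajectory discretization. The noise-free
TMB uses the detection limit implied by the configured noise (3 SD of the
healthy background AF including the binomial component — site noise is
additive and the retention rule subtracts the site mean).

**What the generator does not emulate.** No read-level data, no clonal
phylogeny or subclonal selection dynamics, no pharmacokinetics, no
inter-lab batch effects, and visit-level RECIST is reduced to a
tumor-fraction threshold. Passing recovery tests therefore demonstrates
correctness of the analytical rules under the stated generative model, not
clinical performance on real cohorts.

# Numerical and degenerate-input choices

* Strict inequalities at the denoising thresholds (>10% recurrence, AF
  over mean + 3 SD) with the 1e-12 representation guard described above.
* A single-sample healthy pool yields SD 0 at every site: only AF > site
  mean survives. An empty pool is an error.
* MaxiVAF of an empty variant set, the median of an all-censored KM curve,
  kappa under degenerate margins, and Spearman rho of a constant series are
  all `NA` rather than errors.
* Empty strata report undefined rates with n = 0.
* Dates are calendar days; lead times are integer day differences with no
  rounding to scan intervals.

# Problem sizes used by the test suite

Unit and property tests run on small constructed instances (3-10 sites,
3-9 time points, 200-1100 random instances per oracle-equivalence
property). Recovery tests use full 40-patient cohorts at the default
configuration: three noisy cohorts (pooled, so the binomial error of the
recovered fraction stays well under the 90% margin) and two noiseless
cohorts for exact grid recovery. These sizes were chosen to keep each
stochastic check's sampling error small relative to the property being
asserted.

# Known limitations

* The denoiser is allele-specific and site-wise; it does not model
  position-level error profiles conditional on trinucleotide context or
  fragment length.
* TMB from a targeted panel is an estimate of exome-wide burden; with a
  1.2 Mb footprint its resolution is about 0.83 mut/Mb, so classification
  near the 8.5 cutoff is sensitive to single calls.
* The monitoring rule is threshold-based; patients whose features never
  fall below cutoff during response carry no monitorable transition and
  receive no ctDNA-based PD call.
* Log-rank contrasts with very small strata (the motivating stratification
  yields groups as small as n = 2) are reported but carry little power.
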