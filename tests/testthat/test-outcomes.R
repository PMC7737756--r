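test_that("baseline strata combine ERBB2 and TMB status and partition the cohort", {
  s <- assign_baseline_stratum(c(2.0, 1.0, 1.4, 1.39), c(5, 3, 9, 8.5))
  expect_equal(s$combined,
               c("EhighTlow", "ElowTlow", "EhighThigh", "ElowThigh"))
  set.seed(2)
  folds <- stats::runif(50, 0.5, 3)
  tmbs <- stats::runif(50, 0, 20)
  lab <- assign_baseline_stratum(folds, tmbs)$combined
  expect_true(all(lab %in% c("EhighThigh", "EhighTlow", "ElowThigh",
                             "ElowTlow")))
  expect_equal(length(lab), 50)   # every patient gets exactly one label
  expect_error(assign_baseline_stratum(NA, 5), "missing")
})

test_that("dynamics categories follow the BL -> FP class table", {
  expect_equal(assign_dynamics_category("high", "low"), "dn")
  expect_equal(assign_dynamics_category("low", "high"), "up")
  expect_equal(assign_dynamics_category("low", "low"), "remainL")
  expect_equal(assign_dynamics_category("high", "high"), "remainH")
  expect_equal(assign_dynamics_category("amplified", "not_amplified"), "dn")
  expect_error(assign_dynamics_category("high", "middling"), "classes")
})

test_that("ORR and DCR are exact count ratios with ORR <= DCR", {
  r <- compute_orr_dcr(c(rep("PR", 17), rep("SD", 7), rep("PD", 4)))
  expect_equal(r$orr_pct, 100 * 17 / 28)
  expect_equal(r$dcr_pct, 100 * 24 / 28)
  expect_equal(compute_orr_dcr(rep("PD", 5))$orr_pct, 0)
  expect_equal(compute_orr_dcr(rep("PD", 5))$dcr_pct, 0)
  cr <- compute_orr_dcr(c("CR", "PR", "SD", "PD"))
  expect_equal(cr$orr_n, 2)   # CR counts toward both rates
  expect_equal(cr$dcr_n, 3)
  expect_true(is.na(compute_orr_dcr(c(NA, NA))$orr_pct))
  expect_error(compute_orr_dcr("MR"), "unknown response")
  set.seed(9)
  for (rep in 1:25) {
    x <- sample(c("PR", "SD", "PD"), sample(1:40, 1), replace = TRUE)
    r <- compute_orr_dcr(x)
    expect_lte(r$orr_pct, r$dcr_pct)
    expect_gte(r$orr_pct, 0)
    expect_lte(r$dcr_pct, 100)
  }
})

test_that("cohort ORR tracks the simulated responder fraction", {
  cfg <- simulation_config(n_patients = 60, responder_fraction = 0.6,
                           seed = 14)
  coh <- simulate_cohort(cfg)
  out <- cohort_outcomes(run_cohort_inmemory(coh)$features)
  # binomial error band: 3 * sqrt(p(1-p)/n) ~ 19 percentage points
  expect_lt(abs(out$overall$orr_pct - 60), 19)
})

test_that("Kaplan-Meier matches hand computation and the empirical survival function", {
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(unname(km$median), 2)  # first time with S(t) <= 0.5
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  set.seed(8)
  for (rep in 1:20) {
    t <- sample(1:30, sample(3:15, 1), replace = TRUE)
    km <- km_estimate(t, rep(1, length(t)))
    for (i in seq_len(nrow(km$curve)))
      expect_equal(km$curve$surv[i], mean(t > km$curve$time[i]))
  }
  expect_true(is.na(km_estimate(c(3, 5, 8), c(0, 0, 0))$median))
  expect_error(km_estimate(-1, 1), "negative")
})

test_that("log-rank of a stratum against itself is zero and groups split medians", {
  t <- c(2, 4, 6, 8, 10, 3, 5, 7)
  e <- c(1, 1, 1, 0, 1, 1, 1, 1)
  self <- km_estimate(c(t, t), c(e, e), rep(c("a", "b"), each = length(t)))
  expect_equal(self$logrank$chisq, 0, tolerance = 1e-12)
  expect_equal(self$logrank$p, 1, tolerance = 1e-6)
  two <- km_estimate(c(1, 2, 3, 10, 12, 14), rep(1, 6),
                     rep(c("short", "long"), c(3, 3)))
  expect_equal(unname(two$median["short"]), 2)
  expect_equal(unname(two$median["long"]), 12)
  expect_gt(two$logrank$chisq, 0)
})

test_that("concordance agreement and kappa follow their closed forms", {
  tab <- matrix(c(15, 1, 0, 2), 2)  # 17 of 18 concordant
  cs <- concordance_stats(tab)
  expect_equal(cs$agreement_pct, 100 * 17 / 18)
  expect_equal(round(cs$agreement_pct, 1), 94.4)
  expect_equal(concordance_stats(matrix(c(7, 0, 0, 3), 2))$kappa, 1)
  expect_equal(concordance_stats(matrix(c(5, 5, 5, 5), 2))$kappa, 0)
  # degenerate margins: agreement defined, kappa not
  deg <- concordance_stats(matrix(c(9, 0, 0, 0), 2))
  expect_true(is.na(deg$kappa))
  # kappa <= agreement as proportions; independent implementation agrees
  set.seed(4)
  for (rep in 1:25) {
    tab <- matrix(stats::rpois(4, 6) + 1, 2)
    cs <- concordance_stats(tab)
    expect_lte(cs$kappa, cs$agreement_pct / 100 + 1e-12)
    expect_equal(cs$kappa, e1071::classAgreement(tab)$kappa)
  }
})

test_that("Spearman correlation against CEA hits the rank closed forms", {
  f <- data.frame(erbb2_fold = 1:6, tcl = 6:1, tmb = rep(2, 6),
                  cea_ng_ml = c(1, 2, 4, 8, 16, 32))
  r <- feature_cea_correlation(f)
  expect_equal(r$rho[r$feature == "erbb2_cnv"], 1)
  expect_equal(r$rho[r$feature == "tcl"], -1)
  expect_true(is.na(r$rho[r$feature == "tmb"]))  # constant series
  f3 <- data.frame(erbb2_fold = c(1, 2, 3), tcl = 0, tmb = 0,
                   cea_ng_ml = c(2, 1, 3))
  expect_equal(feature_cea_correlation(f3)$rho[1], 0.5)
})

test_that("stratified outcome analysis assembles a coherent cohort report", {
  coh <- simulate_cohort(simulation_config(n_patients = 25, seed = 17))
  out <- cohort_outcomes(run_cohort_inmemory(coh)$features)
  expect_equal(nrow(out$patients), 25)
  expect_true(all(table(out$patients$combined) ==
                    out$by_baseline_stratum$combined$n[
                      order(out$by_baseline_stratum$combined$stratum)]))
  expect_lte(out$overall$orr_pct, out$overall$dcr_pct)
  expect_true(!is.null(out$concordance))
  expect_equal(sum(out$concordance$table), out$concordance$n)
  expect_true(all(out$correlation$feature %in% c("erbb2_cnv", "tcl", "tmb")))
  # dynamics labels only come from the four-way table
  expect_true(all(stats::na.omit(out$patients$tmb_dyn) %in%
                    c("dn", "up", "remainL", "remainH")))
})
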