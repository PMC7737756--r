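test_that("relative fold series normalizes each feature to its cutoff", {
  expect_equal(relative_fold_series(8.5, 8.5), 1)
  expect_equal(relative_fold_series(4, 2), 2)
  expect_equal(relative_fold_series(0.7, 1.4), 0.5)
  expect_error(relative_fold_series(1, 0), "cutoff")
})

test_that("ctDNA PD lands on the first point of the earliest sustained run", {
  th <- threshold_config()
  # ratio series 0.5 0.4 1.2 1.6 -> run of two starts at the third draw
  tl <- mk_timeline(tmb = c(0.5, 0.4, 1.2, 1.6) * th$tmb_high_cutoff)
  res <- call_ctdna_pd(tl, th)
  expect_equal(res$call$date, tl$date[3])
  expect_equal(res$call$trigger, "tmb")
  # never above cutoff: no call
  expect_null(call_ctdna_pd(mk_timeline(tmb = c(4, 5, 6, 7)), th)$call)
  # an isolated spike is not at least two time points
  expect_null(call_ctdna_pd(
    mk_timeline(tmb = c(0.9, 1.3, 0.8, 0.9) * 8.5), th)$call)
  # fewer than three samples: excluded, with a logged reason
  few <- call_ctdna_pd(mk_timeline(tmb = c(20, 20)), th)
  expect_true(few$excluded)
  expect_match(few$reason, "fewer than 3")
})

test_that("feature ties at the same date break in fixed order", {
  th <- threshold_config()
  tl <- mk_timeline(tmb = c(1, 12, 12, 12), erbb2 = c(1, 2, 2, 2),
                    tcl = c(0, 5, 5, 5))
  res <- call_ctdna_pd(tl, th)
  expect_equal(res$call$trigger, "erbb2_cnv")
  expect_equal(res$call$date, tl$date[2])
})

test_that("a feature elevated since baseline needs a reset before it can trigger", {
  th <- threshold_config()
  # elevated from BL, declining under response: no transition to call
  expect_null(call_ctdna_pd(
    mk_timeline(tmb = c(20, 18, 15, 12, 10)), th)$call)
  # the same patient after a dip re-elevates: call at the re-elevation
  tl <- mk_timeline(tmb = c(20, 18, 4, 12, 14))
  expect_equal(call_ctdna_pd(tl, th)$call$date, tl$date[4])
  # the flag restores the plain reading
  early <- call_ctdna_pd(mk_timeline(tmb = c(20, 18, 15, 12, 10)), th,
                         require_reset = FALSE)
  expect_equal(early$call$date, mk_timeline(n = 5)$date[2])
})

test_that("the PD date is stable under prepending and appending samples", {
  th <- threshold_config()
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(4:9, 1)
    # sub-cutoff baseline, so prepending earlier sub-cutoff draws cannot
    # unlock a run at the old baseline
    tl <- mk_timeline(tmb = c(0.5, stats::runif(n - 1, 0, 2)) * 8.5,
                      erbb2 = c(0.9, stats::runif(n - 1, 0.5, 2)) * 1.4,
                      tcl = c(0, sample(0:4, n - 1, replace = TRUE)))
    base <- call_ctdna_pd(tl, th)$call
    pre <- rbind(mk_timeline(tmb = 1, erbb2 = 1, tcl = 0,
                             start = tl$date[1] - 42), tl)
    pre_call <- call_ctdna_pd(pre, th)$call
    if (!is.null(base)) {
      expect_equal(pre_call$date, base$date)
      ext <- rbind(tl, mk_timeline(tmb = 20, erbb2 = 3, tcl = 6,
                                   start = max(tl$date) + 42))
      expect_lte(base$date, call_ctdna_pd(ext, th)$call$date)
      expect_equal(call_ctdna_pd(ext, th)$call$date, base$date)
    }
  }
})

test_that("PD calls match a brute-force scan over all runs", {
  th <- threshold_config()
  set.seed(31)
  for (rep in 1:300) {
    n <- sample(3:9, 1)
    tl <- mk_timeline(tmb = stats::runif(n, 0, 2) * 8.5,
                      erbb2 = stats::runif(n, 0.4, 2.2) * 1.4,
                      tcl = sample(0:5, n, replace = TRUE))
    for (consecutive in c(TRUE, FALSE)) {
      for (reset in c(TRUE, FALSE)) {
        got <- call_ctdna_pd(tl, th, consecutive = consecutive,
                             require_reset = reset)$call
        ratios <- data.frame(date = tl$date, erbb2_cnv = tl$erbb2_fold / 1.4,
                             tcl = tl$tcl / 2, tmb = tl$tmb / 8.5)
        want <- oracle_pd(ratios, consecutive, reset)
        if (is.null(want)) {
          expect_null(got)
        } else {
          expect_equal(got$date, tl$date[want$i])
          expect_equal(got$trigger, want$trigger)
        }
      }
    }
  }
})

test_that("CEA-based PD uses the normalized 5 ng/mL rule with log2 index", {
  d <- as.Date("2018-01-01") + 42 * 0:2
  expect_null(call_cea_pd(d, c(2, 2, 2))$call)
  res <- call_cea_pd(d, c(3, 6, 8))
  expect_equal(res$call$date, d[2])
  expect_equal(res$log2_index, log2(c(3, 6, 8) / 5))
  expect_equal(call_cea_pd(d, c(3, 10, 12))$log2_index[2], 1)
  expect_error(call_cea_pd(d, c(3, -1, 2)), "positive")
})

test_that("lead time is calendar-day arithmetic with strict 'ahead'", {
  expect_equal(compute_lead_time(as.Date("2018-01-01"),
                                 as.Date("2018-01-01")), 0L)
  expect_equal(compute_lead_time(as.Date("2018-01-01"),
                                 as.Date("2018-02-08")), 38L)
  expect_equal(compute_lead_time(as.Date("2018-02-08"),
                                 as.Date("2018-01-01")), -38L)
  s <- lead_time_summary(c(38, 0, -10, 60))
  expect_equal(s$ahead_n, 2)
  expect_equal(s$ahead_fraction_pct, 50)
  expect_equal(s$mean_advance_days, 49)   # over ahead patients only
  expect_true(is.na(lead_time_summary(c(0, -5))$mean_advance_days))
})

test_that("emerging alterations are the set difference against baseline", {
  bl <- mk_variants(0.1, gene = "TP53", chrom = "chr17", pos = 100L)
  pd <- rbind(bl, mk_variants(c(0.05, 0.04, 0.08), gene = "ERBB2",
                              chrom = "chr1", pos = c(201L, 202L, 203L)))
  expect_equal(nrow(detect_emerging_alterations(bl, bl)$variants), 0)
  out <- detect_emerging_alterations(bl, pd)
  # several resistance mutations in the target gene appear together
  expect_equal(nrow(out$variants), 3)
  expect_true(all(out$variants$gene == "ERBB2"))
  cn <- detect_emerging_alterations(
    bl, pd,
    bl_cnv = data.frame(gene = c("MET", "EGFR"), fold = c(1.0, 1.1)),
    pd_cnv = data.frame(gene = c("MET", "EGFR"), fold = c(2.1, 1.1)))
  expect_equal(cn$cnv, data.frame(gene = "MET", class = "gain"))
})

test_that("timeline validation rejects duplicate dates and misplaced baselines", {
  f <- data.frame(patient_id = "P1",
                  date = as.Date("2018-01-01") + c(0, 42, 42),
                  timepoint = c("BL", "FP", "P3"))
  expect_false(build_timeline(f)$valid)
  f2 <- data.frame(patient_id = "P1",
                   date = as.Date("2018-01-01") + c(0, 42, 84),
                   timepoint = c("FP", "BL", "P3"))
  expect_false(build_timeline(f2)$valid)
  f3 <- data.frame(patient_id = "P1",
                   date = as.Date("2018-01-01") + c(42, 0, 84),
                   timepoint = c("FP", "BL", "P3"))
  tl3 <- build_timeline(f3)
  expect_true(tl3$valid)
  expect_equal(tl3$data$timepoint[1], "BL")
  expect_equal(tl3$data$date[1], min(f3$date))
})

test_that("zero-noise cohorts are recovered exactly on the sampling grid", {
  coh <- simulate_cohort(noiseless(simulation_config(seed = 4)))
  run <- run_cohort_inmemory(coh)
  rec <- recovery_table(coh, run$monitor)
  expect_gt(nrow(rec), 0)
  expect_true(all(!is.na(rec$call_day)))
  expect_equal(rec$call_day, rec$truth_day)
  expect_true(all(rec$lead_days >= 0))
})
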