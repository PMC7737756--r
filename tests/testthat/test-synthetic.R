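test_that("background pool is seed-deterministic and honours the error model", {
  cfg <- tiny_config()
  expect_identical(generate_background_pool(cfg, seed = 5),
                   generate_background_pool(cfg, seed = 5))
  z <- generate_background_pool(noiseless(cfg), seed = 5)
  expect_true(all(vapply(z, function(x) all(x$af == 0), logical(1))))
})

test_that("pooled healthy AF matches the configured noise mean", {
  cfg <- simulation_config(seed = 1)  # Beta mean 0.002
  pool <- generate_background_pool(cfg, seed = 9)
  af <- unlist(lapply(pool, `[[`, "af"))
  se <- stats::sd(af) / sqrt(length(af))
  expect_lt(abs(mean(af) - 0.002), 3 * se)
})

test_that("WBC database plants recurrent artifacts by direct construction", {
  cfg <- simulation_config(n_wbc_samples = 400, seed = 3)
  db <- generate_wbc_database(cfg, seed = 3)
  expect_identical(db$occurrence,
                   generate_wbc_database(cfg, seed = 3)$occurrence)
  planted <- attr(db, "planted")
  expect_gt(nrow(planted), 0)
  idx <- match(planted$key, db$occurrence$key)
  expect_false(anyNA(idx))
  # planted count = round(fraction x total), all strictly above 10%
  expect_equal(db$occurrence$count[idx], round(planted$frac * 400))
  expect_true(all(db$occurrence$count[idx] / 400 > 0.10))
  expect_true(all(db$occurrence$count <= db$total_samples))
  # no recurrent variants at all when nothing is planted
  db0 <- generate_wbc_database(simulation_config(artifact_rate = 0, seed = 3))
  expect_true(all(db0$occurrence$count / db0$total_samples <= 0.10))
})

test_that("zero-noise observations follow the closed-form dilution model", {
  cfg <- noiseless(tiny_config(seed = 21))
  sim <- simulate_patient(cfg, patient_seed = 11, patient_id = "P01")
  tr <- sim$truth
  for (i in seq_along(tr$sample_ids)) {
    v <- sim$variants[sim$variants$sample_id == tr$sample_ids[i], ]
    m <- match(tr$clonal$key, variant_key(v))
    expect_false(anyNA(m))
    # heterozygous clonal variant diluted by tumor fraction: af = c * f / 2
    expect_equal(v$af[m], tr$clonal$cfrac * tr$tumor_fraction[i] / 2,
                 tolerance = 1e-12, ignore_attr = TRUE)
    cr <- sim$copy_ratios[sim$copy_ratios$sample_id == tr$sample_ids[i], ]
    cn <- unlist(tr$copy_numbers)[cr$gene]
    expect_equal(cr$fold, unname(1 + tr$tumor_fraction[i] * (cn / 2 - 1)),
                 tolerance = 1e-12)
  }
})

test_that("non-responder trajectories are monotone and emergent variants are absent before resistance", {
  found_nonresp <- FALSE
  found_emergent <- FALSE
  for (s in 1:30) {
    cfg <- noiseless(tiny_config(seed = s))
    sim <- simulate_patient(cfg, patient_seed = 100 + s)
    tr <- sim$truth
    if (!tr$responder) {
      found_nonresp <- TRUE
      expect_true(all(diff(tr$tumor_fraction) >= 0))
      for (key in tr$clonal$key) {
        afs <- vapply(tr$sample_ids, function(sid) {
          v <- sim$variants[sim$variants$sample_id == sid, ]
          v$af[match(key, variant_key(v))]
        }, numeric(1))
        expect_true(all(diff(afs) >= -1e-12))
      }
    }
    if (NROW(tr$emergent) > 0 && !is.na(tr$t_r)) {
      found_emergent <- TRUE
      pre <- tr$sample_ids[tr$sample_days < tr$t_r]
      for (sid in pre) {
        v <- sim$variants[sim$variants$sample_id == sid, ]
        expect_false(any(tr$emergent$key %in% variant_key(v)))
      }
    }
    if (found_nonresp && found_emergent) break
  }
  expect_true(found_nonresp)
  expect_true(found_emergent)
})

test_that("noise-free TMB is comonotone with tumor fraction and tracks CEA", {
  # noise-free values come from the truth record; CEA uses its noise-free
  # affine link to the tumor fraction
  cfg <- simulation_config(n_patients = 12, seed = 5)
  coh <- simulate_cohort(cfg)
  checked <- 0
  for (p in coh$patients) {
    tr <- p$truth
    if (NROW(tr$emergent) > 0) next  # TMB then not a function of f alone
    tf <- truth_features(tr)
    cea <- tr$baseline_cea * (1 + cfg$cea_coef * tf$f)
    nz <- diff(tf$tmb) != 0
    expect_true(all(sign(diff(tf$tmb))[nz] == sign(diff(tf$f))[nz]))
    # across time points with pairwise-distinct TMB the ranks must agree
    idx <- which(!duplicated(tf$tmb))
    if (length(idx) >= 3) {
      rho <- suppressWarnings(
        stats::cor(tf$tmb[idx], cea[idx], method = "spearman"))
      expect_equal(rho, 1)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
})

test_that("cohort emission round-trips and matches the study scale", {
  cfg <- tiny_config(seed = 8)
  coh <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_cohort(coh, d1)
  emit_cohort(coh, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)   # identical bytes under identical config + seed
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  back <- read_cohort(d1)
  expect_length(back$healthy_pool, cfg$n_healthy_pool)
  for (sid in unique(coh$variants$sample_id)) {
    v <- read_variant_table(back$variant_files[[sid]])
    expect_equal(nrow(v), sum(coh$variants$sample_id == sid))
  }
  expect_equal(nrow(back$clinical), nrow(coh$clinical))
  # imaging progression never precedes the molecular transition
  for (tr in back$truth$patients) {
    if (!is.null(tr$molecular_pd_day) && !is.null(tr$radiologic_pd_day) &&
        !is.na(tr$molecular_pd_day) && !is.na(tr$radiologic_pd_day))
      expect_lte(tr$molecular_pd_day, tr$radiologic_pd_day)
  }
})

test_that("default cohort reproduces the serial-sampling scale of the study", {
  coh <- simulate_cohort(simulation_config(seed = 2))
  n_samples <- length(unique(coh$variants$sample_id))
  expect_equal(length(coh$patients), 40)
  # ~327 samples for 40 patients sampled every two cycles
  expect_gt(n_samples, 240)
  expect_lt(n_samples, 440)
  draws <- table(coh$clinical$patient_id)
  expect_true(all(draws >= 2))
  expect_true(mean(draws) > 5 && mean(draws) < 11.5)
})
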