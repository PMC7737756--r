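test_that("background model reproduces hand-computed site statistics", {
  sites <- mk_sites(3)
  af <- rbind(c(0.001, 0.002, 0.003),  # site 1: mean 0.002, sd 0.001
              c(0, 0, 0),              # site 2: all zero
              c(0.003, 0, 0))          # site 3: imputation check
  m <- build_background_model(mk_healthy_pool(af, sites), sites)
  k <- variant_key(sites)
  s1 <- m$sites[m$sites$key == k[1], ]
  expect_equal(s1$mean_af, 0.002)
  expect_equal(s1$sd_af, 0.001)
  expect_equal(s1$n_obs, 3)
  s2 <- m$sites[m$sites$key == k[2], ]
  expect_equal(s2$mean_af, 0)
  expect_equal(s2$sd_af, 0)
  s3 <- m$sites[m$sites$key == k[3], ]
  expect_equal(s3$mean_af, 0.001)
  expect_equal(s3$sd_af, stats::sd(c(0.003, 0, 0)))
  # pooled fallback over the zero-imputed site-by-individual matrix
  all_af <- as.vector(af)
  expect_equal(m$fallback$mean_af, mean(all_af))
  expect_equal(m$fallback$sd_af, stats::sd(all_af))
})

test_that("degenerate pools are handled: single sample gives SD 0 everywhere", {
  sites <- mk_sites(4)
  m <- build_background_model(
    mk_healthy_pool(matrix(c(0.01, 0, 0.003, 0.2), ncol = 1), sites), sites)
  expect_true(all(m$sites$sd_af == 0))
  expect_error(build_background_model(list()), "empty")
})

test_that("retention threshold is strict at mean + 3 SD", {
  sites <- mk_sites(1)
  m <- build_background_model(
    mk_healthy_pool(matrix(c(0.001, 0.002, 0.003), nrow = 1), sites), sites)
  pos <- sites$pos[1]
  at <- function(a) mk_variants(a, pos = pos)
  # threshold 0.002 + 3 * 0.001 = 0.005, "over" means strictly above
  expect_equal(nrow(background_denoise(at(0.0051), m)$retained), 1)
  expect_equal(nrow(background_denoise(at(0.0050), m)$retained), 0)
  lg <- background_denoise(at(0.0050), m)$removed
  expect_equal(lg$reason, "background_noise")
  expect_equal(lg$detail, 0.005)
  # mean 0 sd 0: any positive AF survives, zero never does
  z <- build_background_model(
    mk_healthy_pool(matrix(0, nrow = 1, ncol = 3), sites), sites)
  expect_equal(nrow(background_denoise(at(0.0001), z)$retained), 1)
  expect_equal(nrow(background_denoise(at(0), z)$retained), 0)
  expect_error(background_denoise(at(0.1) |> transform(af = -0.1), z),
               "negative")
})

test_that("unseen sites fall back to pooled panel statistics", {
  sites <- mk_sites(2)
  af <- rbind(c(0.001, 0.003), c(0.002, 0.002))
  m <- build_background_model(mk_healthy_pool(af, sites), sites)
  thr <- m$fallback$mean_af + 3 * m$fallback$sd_af
  off_panel <- mk_variants(c(thr + 1e-6, thr - 1e-6), chrom = "chr9",
                           pos = c(1L, 2L))
  out <- background_denoise(off_panel, m)
  expect_equal(out$retained$pos, 1L)
  expect_equal(out$removed$key, "chr9:2:A:T")
})

test_that("WBC recurrence filter removes strictly above 10 percent", {
  occ <- mk_sites(2)
  occ$count <- c(41L, 40L)  # 10.25% vs exactly 10%
  db <- wbc_database(occ, total_samples = 400)
  v <- mk_variants(c(0.05, 0.05), pos = occ$pos)
  out <- wbc_artifact_filter(v, db)
  expect_equal(out$retained$pos, occ$pos[2])
  expect_equal(out$removed$reason, "wbc_recurrent")
  expect_equal(out$removed$detail, 41 / 400)
  # unknown variants and empty databases pass everything
  empty <- wbc_database(mk_sites(0)[0, c("chrom", "pos", "ref", "alt")] |>
                          transform(count = integer(0)), 400)
  expect_equal(nrow(wbc_artifact_filter(v, empty)$retained), 2)
})

test_that("retention is monotone in AF and filter order does not matter", {
  set.seed(41)
  sites <- mk_sites(6)
  for (rep in 1:25) {
    af <- matrix(stats::rbeta(6 * 4, 0.5, 120), nrow = 6)
    m <- build_background_model(mk_healthy_pool(af, sites), sites)
    occ <- sites
    occ$count <- stats::rbinom(6, 50, 0.12)
    db <- wbc_database(occ, 50)
    v <- mk_variants(round(stats::runif(6, 0, 0.02), 4),
                     pos = sites$pos)
    ab <- background_denoise(wbc_artifact_filter(v, db)$retained, m)$retained
    ba <- wbc_artifact_filter(background_denoise(v, m)$retained, db)$retained
    expect_setequal(variant_key(ab), variant_key(ba))
    ret <- denoise_variants(v, db, m)$retained
    if (nrow(ret)) {
      bumped <- ret
      bumped$af <- pmin(bumped$af + 0.01, 1)
      bumped$alt_reads <- as.integer(round(bumped$af * bumped$depth))
      expect_equal(nrow(denoise_variants(bumped, db, m)$retained),
                   nrow(ret))
    }
  }
})

test_that("survivors match the brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:200) {
    n_sites <- sample(3:10, 1)
    sites <- mk_sites(n_sites)
    pool <- sample(2:6, 1)
    af <- matrix(stats::rbeta(n_sites * pool, 0.4, 150), nrow = n_sites)
    m <- build_background_model(mk_healthy_pool(af, sites), sites)
    occ <- sites
    occ$count <- stats::rbinom(n_sites, 40, stats::runif(1, 0, 0.3))
    db <- wbc_database(occ, 40)
    idx <- sample(n_sites, sample(1:n_sites, 1), replace = TRUE)
    v <- mk_variants(round(stats::rbeta(length(idx), 0.6, 80), 4),
                     pos = sites$pos[idx])
    got <- denoise_variants(v, db, m)$retained
    want <- oracle_denoise(v, db, m)
    expect_setequal(paste(variant_key(got), got$af),
                    paste(variant_key(want), want$af))
  }
})

test_that("planted artifacts are removed with no leakage and full sensitivity on clear somatic signal", {
  cfg <- simulation_config(seed = 6)
  pool <- generate_background_pool(cfg, seed = 61)
  model <- build_background_model(pool)
  db <- generate_wbc_database(cfg, seed = 62)
  planted <- attr(db, "planted")
  sites <- build_panel_sites(cfg)
  clean <- sites[!variant_key(sites) %in% planted$key, ][1:20, ]
  # true somatic AFs at >= 10x the noise mean (0.002)
  somatic <- data.frame(clean[c("chrom", "pos", "ref", "alt", "gene",
                                "effect")],
                        af = stats::runif(20, 0.02, 0.3))
  somatic$alt_reads <- as.integer(round(somatic$af * 5000))
  somatic$depth <- 5000L
  artifacts <- data.frame(planted[c("chrom", "pos", "ref", "alt", "gene",
                                    "effect")],
                          af = stats::runif(nrow(planted), 0.02, 0.3))
  artifacts$alt_reads <- as.integer(round(artifacts$af * 5000))
  artifacts$depth <- 5000L
  out <- denoise_variants(rbind(somatic, artifacts), db, model)
  expect_setequal(variant_key(out$retained), variant_key(somatic))
  expect_false(any(planted$key %in% variant_key(out$retained)))
})

test_that("optional binomial tail check vetoes weakly supported variants", {
  sites <- mk_sites(1)
  m <- build_background_model(
    mk_healthy_pool(matrix(c(0.002, 0.002, 0.002), nrow = 1), sites), sites)
  v <- mk_variants(0.004, pos = sites$pos)  # 8 of 2000 reads
  expect_equal(nrow(background_denoise(v, m)$retained), 1)
  strict <- background_denoise(v, m, binomial_alpha = 1e-4)
  expect_equal(nrow(strict$retained), 0)
  lax <- background_denoise(v, m, binomial_alpha = 0.5)
  expect_equal(nrow(lax$retained), 1)
})
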