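test_that("generated patients satisfy invariants and are deterministic", {
  cfg <- cohort_config(seed = 42L)
  p1 <- generate_patients(cfg, 37, 74)
  p2 <- generate_patients(cfg, 37, 74)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 111L)
  expect_equal(sum(p1$race_group == "AA"), 37L)
  expect_true(all(p1$age > 0 & p1$psa > 0 & p1$pv > 0))
  expect_equal(p1$psad, p1$psa / p1$pv, tolerance = 1e-12)
})

test_that("covariate sampler hits the configured median at large n", {
  cfg <- cohort_config(seed = 3L)
  p <- generate_patients(cfg, 10000, 1)
  pv <- p$pv[p$race_group == "AA"]
  expect_equal(qlnorm_med_iqr(0.5, 41, 23), 41)  # generator's own quantile fn
  expect_lt(abs(stats::median(pv) - 41) / 41, 0.05)
  iqr <- diff(qlnorm_med_iqr(c(0.25, 0.75), 41, 23))
  expect_equal(iqr, 23, tolerance = 1e-9)
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(isup_freq = list(
    AA = c("1" = 0.5, "2" = 0.4, "3" = 0.2, "4plus" = 0.2),
    W = c("1" = 0.25, "2" = 0.5, "3" = 0.17, "4plus" = 0.08))), "sum to 1")
  expect_error(cohort_config(zone_prob_tz = 1.4), "zone_prob_tz")
  bad_quant <- default_quant_params()
  bad_quant$AA$isup2$ktrans[["sd"]] <- -1
  expect_error(cohort_config(quant = bad_quant), "scale")
})

test_that("lesion generator matches configured multiplicity and invariants", {
  cfg <- cohort_config(seed = 5L)
  p <- generate_patients(cfg, 5000, 5000)
  les <- generate_lesions(p, cfg)
  expect_false(any(les$isup == 0 & les$pirads == 0))
  expect_true(all(les$ktrans >= 0 & les$kep >= 0 & les$adc > 0))
  map <- default_sector_map()
  zl <- lapply(strsplit(les$sectors, ";"), function(s)
    unique(unname(map$zone_of[s])))
  expect_true(all(lengths(zl) == 1L))
  expect_identical(unlist(zl), les$zone)
  # pathology lesions/patient (isup >= 1): 1 + Poisson per group
  for (g in c("AA", "W")) {
    n_path <- sum(les$isup >= 1 & les$race_group == g)
    n_pat <- sum(p$race_group == g)
    expect_lt(abs(n_path / n_pat - cfg$lesions_per_patient[[g]]) /
                cfg$lesions_per_patient[[g]], 0.03)
  }
  # determinism
  expect_identical(les, generate_lesions(p, cfg))
})

test_that("zero-truncated normal draws reproduce configured moments", {
  set.seed(99)
  x <- rnorm_trunc0(10000, 0.2322, 0.1024)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 0.2322) / 0.2322, 0.02)
  expect_lt(abs(stats::sd(x) - 0.1024) / 0.1024, 0.08)
})

test_that("csPCa ktrans draws through the lesion generator hit the group mean", {
  q <- default_quant_params()
  agg <- c(mean = 0.2322, sd = 0.1024)  # AA ISUP >= 2 aggregate
  q$AA$isup2$ktrans <- agg
  q$AA$isup3plus$ktrans <- agg
  cfg <- cohort_config(quant = q, seed = 17L)
  p <- generate_patients(cfg, 8000, 1)
  les <- generate_lesions(p, cfg)
  k <- les$ktrans[les$race_group == "AA" & les$isup >= 2]
  expect_gt(length(k), 5000)
  expect_lt(abs(mean(k) - 0.2322) / 0.2322, 0.02)
})

test_that("DCE curve generator composes baseline frames with the Tofts model", {
  cc <- generate_dce_curve(0, 0.6, noise_sd = 0)
  expect_equal(cc$conc, rep(0, 75))

  cc <- generate_dce_curve(0.2, 0.6, dt = 5, n_pre = 5, n_post = 70)
  expect_equal(length(cc$t), 75L)
  expect_equal(cc$conc[1:5], rep(0, 5))
  tau <- (0:69) * 5 / 60
  direct <- tofts_forward(tofts_params(0.2, 0.6), parker_aif(tau))
  expect_equal(cc$conc[6:75], direct$conc, tolerance = 1e-12)

  expect_error(generate_dce_curve(0.2, 0.6, noise_sd = -1), "noise_sd")
  expect_error(generate_dce_curve(0.2, 0.6, dt = 12), "dt")

  # seeded noise is reproducible
  n1 <- generate_dce_curve(0.2, 0.6, noise_sd = 0.02, seed = 4L)
  n2 <- generate_dce_curve(0.2, 0.6, noise_sd = 0.02, seed = 4L)
  expect_identical(n1, n2)
})

test_that("noiseless simulated curves round-trip through the Tofts fit", {
  cc <- generate_dce_curve(0.2, 0.6)
  post <- 6:75
  tau <- cc$t[post] - cc$t[6]
  fit <- fit_tofts(conc_curve(tau, cc$conc[post]), parker_aif(tau))
  expect_equal(fit$ktrans, 0.2, tolerance = 5e-4)
  expect_equal(fit$kep, 0.6, tolerance = 5e-4)
})

test_that("cohort and curve CSV round-trips preserve the data", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(seed = 1L)
  p <- generate_patients(cfg, 5, 5)
  les <- generate_lesions(p, cfg)
  write_cohort(p, les, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients$psad, p$psad, tolerance = 1e-12)
  expect_identical(back$lesions$sectors, les$sectors)

  curves <- list(A = generate_dce_curve(0.2, 0.6),
                 B = generate_dce_curve(0.1, 0.4))
  path <- file.path(dir, "curves.csv")
  write_dce_curves(curves, path)
  back_c <- read_dce_curves(path)
  expect_equal(back_c$A$conc, curves$A$conc, tolerance = 1e-9)
  expect_equal(back_c$B$t, curves$B$t, tolerance = 1e-9)

  cfg_path <- file.path(dir, "config.json")
  write_cohort_config(cfg, cfg_path)
  cfg2 <- read_cohort_config(cfg_path)
  expect_equal(cfg2$quant$AA$isup2$ktrans, cfg$quant$AA$isup2$ktrans)
  expect_identical(generate_patients(cfg2, 4, 4), generate_patients(cfg, 4, 4))
})
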