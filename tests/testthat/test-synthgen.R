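test_that("subject draws follow the configured priors", {
  pr <- param_priors()

  # zero dispersion: every subject sits exactly at the nominal values
  cfg0 <- tiny_config(inter_subject_sd = 0)
  p1 <- withr::with_seed(1, draw_subject_params(cfg0))
  p2 <- withr::with_seed(99, draw_subject_params(cfg0))
  for (nm in setdiff(pr$param, "log_snr")) {
    expect_equal(p1[[nm]], pr$nominal[pr$param == nm])
    expect_equal(p2[[nm]], p1[[nm]])
  }
  expect_equal(p1$snr, exp(pr$nominal[pr$param == "log_snr"]))

  # determinism: a fresh RNG at the same seed reproduces the draw
  cfg <- tiny_config()
  d1 <- withr::with_seed(42, draw_subject_params(cfg))
  d2 <- withr::with_seed(42, draw_subject_params(cfg))
  expect_identical(d1, d2)

  # Monte-Carlo: sample sd of erd_depth_contra tracks the prior sd
  cfg_mc <- tiny_config(inter_subject_sd = 0.1)
  target_sd <- 0.1 * pr$base_sd[pr$param == "erd_depth_contra"]
  draws <- withr::with_seed(7, replicate(1000, {
    draw_subject_params(cfg_mc)$erd_depth_contra
  }))
  expect_lt(abs(sd(draws) - target_sd) / target_sd, 0.15)
})

test_that("session perturbations are bounded and smaller than subject spread", {
  pr <- param_priors()
  cfg <- tiny_config()

  # zero inter-session dispersion reproduces the subject parameters
  cfg0 <- tiny_config(inter_session_sd = 0)
  sp <- withr::with_seed(3, draw_subject_params(cfg0))
  ssp <- withr::with_seed(4, draw_session_params(sp, cfg0, 2L))
  for (nm in pr$param) expect_equal(ssp[[nm]], sp[[nm]])
  expect_identical(ssp$session_index, 2L)

  # clipping keeps a near-ceiling ERD depth inside [0, 1)
  cfg_big <- tiny_config(inter_session_sd = 50)
  sp$erd_depth_contra <- 0.95
  draws <- withr::with_seed(5, replicate(200, {
    draw_session_params(sp, cfg_big)$erd_depth_contra
  }))
  expect_true(all(draws < 1))
  expect_true(all(draws >= 0))

  # variance decomposition: between-subject spread dominates
  # within-subject between-session spread for every parameter
  vals <- withr::with_seed(11, {
    lapply(1:10, function(i) {
      s <- draw_subject_params(cfg)
      lapply(1:10, function(j) draw_session_params(s, cfg, j))
    })
  })
  for (nm in c("mu_peak_hz", "beta_peak_hz", "erd_depth_contra")) {
    per_subj <- lapply(vals, function(ss) vapply(ss, `[[`, 0, nm))
    subj_means <- vapply(per_subj, mean, 0)
    within_var <- mean(vapply(per_subj, var, 0))
    expect_gt(var(subj_means), within_var)
  }
})

test_that("synthetic sessions have the paradigm's event structure", {
  cfg <- cohort_config(n_subjects = 1, seed = 9)  # 8 runs x 30 trials
  co <- make_cohort(cfg)
  rec <- co[[1]]
  expect_equal(nrow(rec$events), 240)
  expect_equal(sum(rec$events$class == "left"), 120)
  expect_equal(sum(rec$events$class == "right"), 120)
  expect_equal(sort(unique(rec$events$run)), 1:8)
  # per-run balance
  by_run <- table(rec$events$run, rec$events$class)
  expect_true(all(by_run == 15))
  # every [-2, +8] s window lies inside the recording
  expect_true(all(rec$events$onset_sample - 2 * rec$fs >= 1))
  expect_true(all(rec$events$onset_sample + 8 * rec$fs <= ncol(rec$data)))
})

test_that("cohorts are reproducible and presets have the study layout", {
  cfg <- tiny_config(seed = 21)
  co1 <- make_cohort(cfg)
  co2 <- make_cohort(cfg)
  expect_identical(co1[[1]]$data, co2[[1]]$data)
  expect_identical(co1[[1]]$events, co2[[1]]$events)

  e1 <- exp1_config(seed = 1)
  expect_equal(e1$n_subjects * e1$n_sessions, 8)
  e2 <- exp2_config(seed = 1)
  expect_equal(e2$n_subjects, 2)
  expect_equal(e2$n_sessions, 10)
  expect_equal(e1$n_runs * e1$trials_per_run, 240)
})

test_that("rhythm peaks rise above the 1/f floor in a no-modulation session", {
  rec <- param_session(
    overrides = list(erd_depth_contra = 0, erd_depth_ipsi = 0,
                     ers_rebound = 0, snr = 3),
    seed = 31
  )
  x <- rec$data["C3", ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = rec$fs),
                          spans = c(101, 101), taper = 0, plot = FALSE)
  band_power <- function(lo, hi) mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
  # mu and beta peaks versus the trough between them
  expect_gt(band_power(9.5, 10.5), band_power(14.5, 16.5))
  expect_gt(band_power(19.5, 20.5), band_power(14.5, 16.5))
  # and versus the floor above beta
  expect_gt(band_power(19.5, 20.5), band_power(25, 28))
})

test_that("the 5000 Hz mode scales samples and event indices", {
  cfg250 <- tiny_config(seed = 13)
  cfg5k <- tiny_config(seed = 13, fs = 5000)
  r250 <- make_cohort(cfg250)[[1]]
  r5k <- make_cohort(cfg5k)[[1]]
  expect_equal(ncol(r5k$data), 20 * ncol(r250$data))
  expect_equal(r5k$events$onset_sample,
               (r250$events$onset_sample - 1L) * 20L + 1L)
  expect_equal(r5k$fs, 5000)
})
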