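sine_rec <- function(freq, fs, dur = 10, C = 2, amp = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  make_rec(matrix(rep(amp * sin(2 * pi * freq * t), each = C), nrow = C,
                  byrow = FALSE), fs)
}

trimmed_rms <- function(rec, margin_s = 1) {
  n <- ncol(rec$data)
  m <- round(margin_s * rec$fs)
  sqrt(mean(rec$data[1, (m + 1):(n - m)]^2))
}

test_that("downsampling decimates correctly and preserves slow content", {
  rec <- sine_rec(5, 5000)
  expect_equal(ncol(rec$data), 50000)
  ds <- downsample(rec, 250)
  expect_equal(ncol(ds$data), 2500)
  expect_equal(ds$fs, 250)

  # identity when already at the target rate
  rec250 <- sine_rec(5, 250)
  expect_identical(downsample(rec250, 250), rec250)

  # a 5 Hz sine survives the factor-20 decimation
  t_lo <- (seq_len(2500) - 1) / 250
  ref <- sin(2 * pi * 5 * t_lo)
  interior <- 300:2200
  expect_gt(cor(ds$data[1, interior], ref[interior]), 0.999)

  # non-integer factor rejected
  expect_error(downsample(sine_rec(5, 300), 250), "integer multiple")

  # event indices rescale with the decimation
  ev <- tibble::tibble(onset_sample = c(1L, 2001L), class = c("left", "right"),
                       run = c(1L, 1L))
  rec_ev <- make_rec(matrix(rnorm(2 * 50000), 2), 5000, events = ev)
  ds_ev <- downsample(rec_ev, 250)
  expect_equal(ds_ev$events$onset_sample, c(1L, 101L))
})

test_that("notch filter removes 50 Hz and leaves the passband intact", {
  r50 <- notch_filter(sine_rec(50, 250))
  expect_lt(trimmed_rms(r50), 0.05 * sqrt(0.5))

  r10 <- notch_filter(sine_rec(10, 250))
  expect_lt(abs(trimmed_rms(r10) - sqrt(0.5)) / sqrt(0.5), 0.02)

  zeros <- make_rec(matrix(0, 2, 2500), 250)
  expect_equal(notch_filter(zeros)$data, zeros$data)

  expect_error(notch_filter(sine_rec(10, 90), freq = 50), "Nyquist")
})

test_that("band-pass keeps 8-30 Hz and rejects DC and slow drift", {
  dc <- make_rec(matrix(5, 2, 2500), 250)
  expect_lt(max(abs(bandpass_filter(dc)$data[, 200:2300])), 1e-6)

  r20 <- bandpass_filter(sine_rec(20, 250))
  expect_lt(abs(trimmed_rms(r20) - sqrt(0.5)) / sqrt(0.5), 0.05)

  r2 <- bandpass_filter(sine_rec(2, 250))
  expect_lt(trimmed_rms(r2), 0.10 * sqrt(0.5))

  expect_error(bandpass_filter(sine_rec(5, 250), lo = 20, hi = 10), "lo < hi")

  # linearity
  a <- make_rec(matrix(rnorm(2 * 2500), 2), 250)
  b <- make_rec(matrix(rnorm(2 * 2500), 2), 250)
  ab <- make_rec(a$data + b$data, 250)
  expect_equal(bandpass_filter(ab)$data,
               bandpass_filter(a)$data + bandpass_filter(b)$data,
               tolerance = 1e-10)
})

test_that("frequency-domain filtering matches forward-backward filtfilt", {
  withr::with_seed(8, {
    x <- rnorm(20000)
  })
  bf <- signal::butter(2, c(8, 30) / 125, type = "pass")
  ref <- signal::filtfilt(bf, x)
  mine <- smrbci:::apply_filtfilt(matrix(x, 1), bf)[1, ]
  interior <- 2000:18000
  expect_lt(max(abs(ref[interior] - mine[interior])), 1e-8)
})

test_that("zero-phase filtering does not shift oscillation peaks", {
  fs <- 250
  t <- (seq_len(10 * fs) - 1) / fs
  x <- sin(2 * pi * 10 * t)
  filt <- bandpass_filter(make_rec(matrix(x, 1), fs))$data[1, ]
  # cross-correlation between input and output peaks at lag zero
  interior <- 500:2000
  lags <- -3:3
  cc <- vapply(lags, function(l) {
    cor(x[interior], filt[interior + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("epoching slices exactly at events and conserves trials", {
  fs <- 250
  n <- 5000
  # channel value = sample index: a slicing oracle
  data <- matrix(rep(seq_len(n), each = 2), nrow = 2, byrow = FALSE)
  ev <- tibble::tibble(onset_sample = c(1000L, 2000L, 3500L),
                       class = c("left", "right", "left"),
                       run = c(1L, 1L, 2L))
  rec <- make_rec(data, fs, events = ev)
  ep <- epoch_trials(rec, window = c(0, 4))
  expect_equal(dim(ep$trials), c(2, 1000, 3))
  for (i in 1:3) {
    expect_equal(ep$trials[1, , i], ev$onset_sample[i] + 0:999)
  }
  expect_equal(ep$labels, c(1L, 2L, 1L))
  expect_equal(ep$runs, c(1L, 1L, 2L))

  # negative-start window shifts the slice
  ep2 <- epoch_trials(rec, window = c(-2, 0))
  expect_equal(unname(ep2$trials[1, 1, 1]), 1000 - 500)

  # empty event list
  rec0 <- make_rec(data, fs)
  ep0 <- epoch_trials(rec0, window = c(0, 4))
  expect_equal(n_trials(ep0), 0)

  # bounds are enforced
  expect_error(epoch_trials(rec, window = c(0, 10)), "bounds")
  expect_error(epoch_trials(rec, window = c(-5, 0)), "bounds")
})

test_that("epoch sets subset and concatenate consistently", {
  ep <- toy_epochs(seed = 2, n_per_class = 6)
  sub <- subset_epochs(ep, ep$labels == 1L)
  expect_equal(n_trials(sub), 6)
  both <- combine_epochs(list(ep, ep))
  expect_equal(n_trials(both), 2 * n_trials(ep))
  expect_equal(both$trials[, , 1], ep$trials[, , 1])
  expect_equal(both$trials[, , n_trials(ep) + 1], ep$trials[, , 1])
})

test_that("the fused preprocessing pass equals the notch+band-pass chain", {
  withr::with_seed(9, {
    rec <- make_rec(matrix(rnorm(3 * 6000), 3), 250)
  })
  chained <- rec |> notch_filter() |> bandpass_filter()
  fused <- preprocess_session(rec)
  interior <- 500:5500
  expect_lt(max(abs(chained$data[, interior] - fused$data[, interior])),
            1e-8)
})
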