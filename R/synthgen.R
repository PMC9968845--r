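#' Configure a synthetic SMR cohort
#'
#' Describes a multi-subject, multi-session motor-imagery study: how many
#' subjects and sessions to simulate, the run/trial structure of each
#' session, the trial timeline, and how strongly the underlying
#' sensorimotor-rhythm parameters disperse across subjects
#' (`inter_subject_sd`) versus across sessions of one subject
#' (`inter_session_sd`).  The dispersion arguments are dimensionless
#' multipliers on per-parameter base scales (see [param_priors()]); the
#' default 3:1 ratio makes between-subject variability dominate
#' between-session variability, the contrast the downstream analyses are
#' designed to detect.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_sessions Sessions per subject (recorded on "different days").
#' @param n_runs Runs per session (default 8).
#' @param trials_per_run Trials per run, must be even: classes are balanced
#'   within each run (default 30, i.e. 15 left + 15 right).
#' @param fs Sampling rate in Hz, 250 (native) or 5000 (native synthesis at
#'   250 Hz followed by interpolation, provided to exercise the
#'   downsampling stage).
#' @param channel_labels Electrode montage; defaults to the 20-channel
#'   sensorimotor grid of [smr_channels()].
#' @param fixation_s,imagery_s,rest_s Trial timeline in seconds: fixation
#'   cross, motor imagery, inter-trial rest.
#' @param inter_subject_sd,inter_session_sd Non-negative dispersion
#'   multipliers for subject-level draws and session-level perturbations.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @seealso [exp1_config()], [exp2_config()], [make_cohort()]
#' @export
cohort_config <- function(n_subjects,
                          n_sessions = 1,
                          n_runs = 8,
                          trials_per_run = 30,
                          fs = 250,
                          channel_labels = smr_channels(),
                          fixation_s = 2,
                          imagery_s = 4,
                          rest_s = 4,
                          inter_subject_sd = 1,
                          inter_session_sd = 1 / 3,
                          seed = 1L) {
  stopifnot_scalar_number(n_subjects, "n_subjects", lower = 1)
  stopifnot_scalar_number(n_sessions, "n_sessions", lower = 1)
  stopifnot_scalar_number(n_runs, "n_runs", lower = 1)
  stopifnot_scalar_number(trials_per_run, "trials_per_run", lower = 2)
  if (trials_per_run %% 2 != 0) {
    abort("`trials_per_run` must be even (balanced left/right classes).")
  }
  stopifnot_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(inter_subject_sd, "inter_subject_sd", lower = 0)
  stopifnot_scalar_number(inter_session_sd, "inter_session_sd", lower = 0)
  stopifnot_scalar_number(fixation_s, "fixation_s", lower = 0)
  stopifnot_scalar_number(imagery_s, "imagery_s", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(rest_s, "rest_s", lower = 0)
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_sessions = as.integer(n_sessions),
      n_runs = as.integer(n_runs),
      trials_per_run = as.integer(trials_per_run),
      fs = fs,
      channel_labels = channel_labels,
      fixation_s = fixation_s,
      imagery_s = imagery_s,
      rest_s = rest_s,
      inter_subject_sd = inter_subject_sd,
      inter_session_sd = inter_session_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Study-design presets
#'
#' `exp1_config()` is the multi-subject design (8 subjects, one session
#' each, 8 runs of 30 trials: 240 trials, 120 per class); `exp2_config()`
#' is the multi-session design (2 subjects, 10 sessions each, same session
#' structure).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
exp1_config <- function(seed = 1L, ...) {
  cohort_config(n_subjects = 8, n_sessions = 1, seed = seed, ...)
}

#' @rdname exp1_config
#' @export
exp2_config <- function(seed = 1L, ...) {
  cohort_config(n_subjects = 2, n_sessions = 10, seed = seed, ...)
}

#' Parameter priors of the SMR generator
#'
#' Each simulated subject is a draw from truncated-normal priors around the
#' nominal values below, with standard deviation `inter_subject_sd *
#' base_sd`; sessions of one subject perturb the subject's values with
#' standard deviation `inter_session_sd * base_sd` (bounds enforced by
#' clipping).  `snr` is drawn on the log scale.
#'
#' @return A tibble with columns `param`, `nominal`, `base_sd`, `lower`,
#'   `upper`.
#' @export
param_priors <- function() {
  tibble(
    param   = c("mu_peak_hz", "beta_peak_hz", "erd_depth_contra",
                "erd_depth_ipsi", "ers_rebound", "log_snr",
                "topo_shift", "topo_width"),
    nominal = c(10, 20, 0.45, 0.25, 0.40, log(2), 0, 1.2),
    base_sd = c(1.2, 2.0, 0.20, 0.15, 0.20, 0.6, 0.7, 0.30),
    lower   = c(8.5, 16, 0, 0, 0, log(0.2), -1.5, 0.5),
    upper   = c(12.5, 26, 0.95, 0.95, 2, log(20), 1.5, 2.5)
  )
}

new_smr_params <- function(values, channel_labels, class, session_index = NA) {
  p <- as.list(values)
  p$snr <- exp(p$log_snr)
  gC3 <- topography_gain("C3", p$topo_shift, p$topo_width)[channel_labels]
  gC4 <- topography_gain("C4", -p$topo_shift, p$topo_width)[channel_labels]
  p$topography <- list(C3 = gC3 / max(gC3), C4 = gC4 / max(gC4))
  p$session_index <- session_index
  structure(p, class = class)
}

#' Draw subject- and session-level SMR parameters
#'
#' `draw_subject_params()` draws one subject's rhythm parameters (mu/beta
#' peak frequencies, contralateral and ipsilateral ERD depths, post-imagery
#' beta ERS rebound, signal-to-noise ratio and topography shape) from the
#' priors in [param_priors()].  `draw_session_params()` perturbs a
#' subject's parameters to model day-to-day drift.  Both consume the
#' current RNG state, so wrap calls in `set.seed()`/[withr::with_seed()]
#' for reproducibility ([make_cohort()] does this for you).
#'
#' @param config A [cohort_config()].
#' @return An object of class `subject_params` / `session_params`.
#' @export
draw_subject_params <- function(config) {
  pr <- param_priors()
  v <- clip(rnorm(nrow(pr), pr$nominal, config$inter_subject_sd * pr$base_sd),
            pr$lower, pr$upper)
  names(v) <- pr$param
  new_smr_params(v, config$channel_labels, "subject_params")
}

#' @rdname draw_subject_params
#' @param subject A `subject_params` object.
#' @param session_index Ordinal session number within the subject.
#' @export
draw_session_params <- function(subject, config, session_index = 1L) {
  pr <- param_priors()
  base <- unlist(subject[pr$param])
  v <- clip(base + rnorm(nrow(pr), 0, config$inter_session_sd * pr$base_sd),
            pr$lower, pr$upper)
  names(v) <- pr$param
  new_smr_params(v, config$channel_labels,
                 c("session_params", "subject_params"),
                 session_index = as.integer(session_index))
}

# ---- signal synthesis ------------------------------------------------------

# total background RMS per channel, microvolts
BACKGROUND_RMS <- 10

# spontaneous waxing/waning of the rhythm sources: slow log-normal
# amplitude fluctuations (log-amplitude sd and cutoff frequency); this is
# what gives CSP log band-power features their trial-to-trial spread
AMP_FLUCT_SD <- 0.25
AMP_FLUCT_HZ <- 0.06

# unit-variance slow Gaussian process (Gaussian low-pass shaped noise);
# synthesized at 2 Hz, far above f_c, and linearly interpolated to fs
slow_fluctuation <- function(n, fs, f_c = AMP_FLUCT_HZ) {
  fs_lo <- 2
  m <- ceiling(n / fs * fs_lo) + 2
  m2 <- stats::nextn(m, c(2, 3, 5))
  h <- exp(-(fft_freqs(m2, fs_lo) / f_c)^2 / 2)
  h[1] <- 0
  z <- Re(fft(fft(rnorm(m2)) * h, inverse = TRUE))[seq_len(m)] / m2
  z <- z / sd(z)
  stats::approx(seq_len(m), z, xout = 1 + (seq_len(n) - 1) / fs * fs_lo,
                rule = 2)$y
}

# two-sided FFT frequency grid folded to [0, fs/2]
fft_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

# 1/f amplitude weights on an FFT frequency grid (flat below 1 Hz, DC removed)
pink_weights <- function(n, fs) {
  w <- 1 / sqrt(pmax(fft_freqs(n, fs), 1))
  w[1] <- 0
  w
}

# fraction of background power inside [lo, hi] Hz
inband_fraction <- function(n, fs, lo = 8, hi = 30) {
  f <- fft_freqs(n, fs)
  w2 <- pink_weights(n, fs)^2
  sum(w2[f >= lo & f <= hi]) / sum(w2)
}

# unit-RMS narrowband Gaussian carriers centred at f0 (Hz), ~1 Hz
# bandwidth, one column per requested centre frequency (batched FFTs at
# an FFT-friendly length, truncated to n)
narrowband_carriers <- function(n, fs, f0s, bw = 1) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  f <- fft_freqs(n2, fs)
  h <- vapply(f0s, function(f0) exp(-(f - f0)^2 / (2 * bw^2)),
              numeric(n2))
  x <- Re(mvfft(mvfft(matrix(rnorm(n2 * length(f0s)), n2)) * h,
                inverse = TRUE))[seq_len(n), , drop = FALSE] / n2
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

narrowband_carrier <- function(n, fs, f0, bw = 1) {
  narrowband_carriers(n, fs, f0, bw)[, 1]
}

# moving-average smoothing turns step envelopes into linear ramps
# (centred running mean via cumulative sums, edges left untouched)
ramp_smooth <- function(env, width) {
  if (width < 2) return(env)
  n <- length(env)
  half <- width %/% 2
  cs <- cumsum(env)
  lo <- seq_len(n) - half
  hi <- lo + width - 1
  ok <- lo >= 1 & hi <= n
  out <- env
  out[ok] <- (cs[hi[ok]] - c(0, cs)[lo[ok]]) / width
  out
}

session_timeline <- function(config, fs) {
  trial_s <- config$fixation_s + config$imagery_s + config$rest_s
  lead_in <- 4
  gap <- 2
  tail <- 4
  run_s <- config$trials_per_run * trial_s
  total_s <- lead_in + config$n_runs * run_s + (config$n_runs - 1) * gap + tail
  onsets <- numeric(0)
  runs <- integer(0)
  for (r in seq_len(config$n_runs)) {
    run_start <- lead_in + (r - 1) * (run_s + gap)
    t0 <- run_start + (seq_len(config$trials_per_run) - 1) * trial_s +
      config$fixation_s
    onsets <- c(onsets, t0)
    runs <- c(runs, rep(r, config$trials_per_run))
  }
  list(
    n_samples = round(total_s * fs),
    onset_sample = round(onsets * fs) + 1L,
    run = runs
  )
}

#' Synthesize one motor-imagery session
#'
#' Generates a continuous 20-channel recording as the sum of spatially
#' correlated 1/f background noise and four amplitude-modulated narrowband
#' sources: a mu and a beta rhythm under each of two Gaussian topographies
#' centred on C3 and C4.  During each imagery interval the band power of
#' the source contralateral to the imagined hand is scaled by
#' `1 - erd_depth_contra` and the ipsilateral source by
#' `1 - erd_depth_ipsi` (both rhythms desynchronize); for 2 s after imagery
#' offset the beta source rebounds by `1 + ers_rebound` (contralateral;
#' ipsilateral at 30% of the rebound).  Envelope transitions use 250 ms
#' linear ramps.  Rhythm amplitude at the topography peak equals `snr`
#' times the in-band (8-30 Hz) background RMS; the beta source is half the
#' mu amplitude.  On top of the task-locked envelope every source waxes
#' and wanes spontaneously (slow log-normal amplitude fluctuations,
#' log-sd 0.25, roughly 0.06 Hz bandwidth), the property that gives log
#' band-power features their trial-to-trial spread.
#'
#' @param params A `session_params` (or `subject_params`) object.
#' @param config A [cohort_config()].
#' @param subject_id,session_id Identifiers stored in the recording.
#' @return A `session_recording`: list with `data` (channels x samples
#'   matrix, microvolts), `fs`, `channel_labels`, `events` (tibble:
#'   `onset_sample`, `class`, `run`), ids, and `ground_truth` (the
#'   parameters used).
#' @export
synthesize_session <- function(params, config,
                               subject_id = "sub01", session_id = "ses01") {
  fs_native <- 250
  tl <- session_timeline(config, fs_native)
  n <- tl$n_samples
  chans <- config$channel_labels
  C <- length(chans)

  # balanced classes within each run
  cls <- unlist(lapply(seq_len(config$n_runs), function(r) {
    sample(rep(c("left", "right"), each = config$trials_per_run / 2))
  }))
  events <- tibble(onset_sample = tl$onset_sample, class = cls, run = tl$run)

  # spatially correlated pink background (power-of-two FFT, truncated)
  n2 <- stats::nextn(n, c(2, 3, 5))
  w <- pink_weights(n2, fs_native)
  noise <- matrix(rnorm(n2 * C), n2, C)
  shaped <- (Re(mvfft(mvfft(noise) * w, inverse = TRUE)) / n2)[seq_len(n), ]
  shaped <- sweep(shaped, 2, sqrt(colMeans(shaped^2)), "/")
  kern <- background_kernel()[chans, chans]
  bg <- shaped %*% chol(kern) * BACKGROUND_RMS

  # rhythm amplitudes relative to the in-band background
  sigma_inband <- BACKGROUND_RMS * sqrt(inband_fraction(n, fs_native))
  a_mu <- params$snr * sigma_inband
  a_beta <- 0.5 * a_mu

  imagery_n <- round(config$imagery_s * fs_native)
  rebound_n <- round(2 * fs_native)
  ramp_n <- round(0.25 * fs_native)

  envelope <- function(depths, rebounds) {
    env <- rep(1, n)
    for (i in seq_len(nrow(events))) {
      o <- events$onset_sample[i]
      img <- o:min(o + imagery_n - 1L, n)
      env[img] <- sqrt(1 - depths[i])
      if (rebounds[i] > 0) {
        post <- (o + imagery_n):min(o + imagery_n + rebound_n - 1L, n)
        env[post] <- sqrt(1 + rebounds[i])
      }
    }
    ramp_smooth(env, ramp_n)
  }

  # contralateral side: left-hand imagery modulates the C4 source
  depth_C4 <- ifelse(events$class == "left",
                     params$erd_depth_contra, params$erd_depth_ipsi)
  depth_C3 <- ifelse(events$class == "right",
                     params$erd_depth_contra, params$erd_depth_ipsi)
  reb_C4 <- ifelse(events$class == "left", 1, 0.3) * params$ers_rebound
  reb_C3 <- ifelse(events$class == "right", 1, 0.3) * params$ers_rebound
  zero <- rep(0, nrow(events))

  data <- t(bg)
  sources <- list(
    list(g = params$topography$C3, a = a_mu, f = params$mu_peak_hz,
         env = envelope(depth_C3, zero)),
    list(g = params$topography$C4, a = a_mu, f = params$mu_peak_hz,
         env = envelope(depth_C4, zero)),
    list(g = params$topography$C3, a = a_beta, f = params$beta_peak_hz,
         env = envelope(depth_C3, reb_C3)),
    list(g = params$topography$C4, a = a_beta, f = params$beta_peak_hz,
         env = envelope(depth_C4, reb_C4))
  )
  carriers <- narrowband_carriers(n, fs_native,
                                  vapply(sources, `[[`, 0, "f"))
  for (k in seq_along(sources)) {
    s <- sources[[k]]
    # spontaneous waxing/waning on top of the task-locked envelope
    fluct <- exp(AMP_FLUCT_SD * slow_fluctuation(n, fs_native) -
                   AMP_FLUCT_SD^2 / 2)
    data <- data + outer(unname(s$g), s$a * s$env * fluct * carriers[, k])
  }
  rownames(data) <- chans

  if (config$fs != fs_native) {
    q <- config$fs / fs_native
    if (q != round(q)) abort("`fs` must be a multiple of 250 Hz.")
    n_up <- n * q
    t_up <- (seq_len(n_up) - 1) / config$fs
    t_na <- (seq_len(n) - 1) / fs_native
    data <- t(apply(data, 1, function(ch) {
      stats::approx(t_na, ch, xout = t_up, rule = 2)$y
    }))
    rownames(data) <- chans
    events$onset_sample <- (events$onset_sample - 1L) * as.integer(q) + 1L
  }

  structure(
    list(
      data = data,
      fs = config$fs,
      channel_labels = chans,
      events = events,
      subject_id = subject_id,
      session_id = session_id,
      ground_truth = params
    ),
    class = "session_recording"
  )
}

#' Generate a full synthetic cohort
#'
#' Draws `n_subjects` subject parameter sets, perturbs each into
#' `n_sessions` session parameter sets, and synthesizes every session.
#' Fully reproducible from `config$seed`: each subject, session and signal
#' uses its own deterministic child seed, so any single recording can be
#' re-generated in isolation.
#'
#' @param config A [cohort_config()].
#' @return A list of `session_recording` objects (subjects varying
#'   slowest), named `"subXX_sesYY"`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- list()
  for (i in seq_len(config$n_subjects)) {
    sp <- withr::with_seed(child_seed(config$seed, "subject", i),
                           draw_subject_params(config))
    for (j in seq_len(config$n_sessions)) {
      ssp <- withr::with_seed(child_seed(config$seed, "params", i, j),
                              draw_session_params(sp, config, j))
      sid <- sprintf("sub%02d", i)
      ses <- sprintf("ses%02d", j)
      rec <- withr::with_seed(
        child_seed(config$seed, "signal", i, j),
        synthesize_session(ssp, config, subject_id = sid, session_id = ses)
      )
      recs[[paste(sid, ses, sep = "_")]] <- rec
    }
  }
  recs
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> %s/%s: %d channels x %d samples @ %g Hz, %d events (%d left / %d right)\n",
    x$subject_id, x$session_id, nrow(x$data), ncol(x$data), x$fs,
    nrow(x$events), sum(x$events$class == "left"),
    sum(x$events$class == "right")
  ))
  invisible(x)
}
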