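#' Offline preprocessing chain
#'
#' The standard offline chain applied to every continuous recording before
#' analysis, in fixed order: [downsample()] to 250 Hz, [notch_filter()] at
#' 50 Hz, [bandpass_filter()] 8-30 Hz, then [epoch_trials()].  All filters
#' are Butterworth designs applied forward-backward
#' ([signal::filtfilt()]), so the net phase response is zero and ERD/ERS
#' latencies are not shifted; the effective filter order doubles.
#'
#' @param rec A `session_recording`.
#' @param target_fs Target sampling rate in Hz; `fs` must be an integer
#'   multiple of it.
#' @return A `session_recording` with updated `data`, `fs` and event
#'   sample indices.
#' @export
downsample <- function(rec, target_fs = 250) {
  stopifnot(is_session_recording(rec))
  if (rec$fs == target_fs) return(rec)
  q <- rec$fs / target_fs
  if (q != round(q) || q < 1) {
    abort("`fs` must be an integer multiple of `target_fs`.")
  }
  q <- as.integer(q)
  # anti-alias low-pass at 80% of the target Nyquist, zero phase
  bf <- signal::butter(4, 0.8 * (target_fs / 2) / (rec$fs / 2), type = "low")
  filtered <- apply_filtfilt(rec$data, bf)
  keep <- seq(1, ncol(filtered), by = q)
  rec$data <- filtered[, keep, drop = FALSE]
  rec$events$onset_sample <- (rec$events$onset_sample - 1L) %/% q + 1L
  rec$fs <- target_fs
  rec
}

# squared magnitude response |H(e^{-iw})|^2 of a designed IIR filter on an
# n2-point FFT grid: the net (zero-phase) response of forward-backward
# filtering
zerophase_mag2 <- function(bf, n2) {
  z <- exp(-2i * pi * (seq_len(n2) - 1) / n2)
  polyval <- function(coef, z) {
    acc <- 0 + 0i
    for (c_k in coef) acc <- acc * z + c_k
    acc
  }
  Mod(polyval(rev(bf$b), z) / polyval(rev(bf$a), z))^2
}

# Zero-phase filtering in the frequency domain, batched over channels with
# one FFT pair; numerically equivalent to forward-backward (filtfilt)
# application away from the signal edges.  Signals are zero-padded to an
# FFT-friendly length; recordings carry lead-in/tail margins so the
# circular edges never reach an epoch.
apply_mag2 <- function(data, mag2) {
  n <- ncol(data)
  n2 <- length(mag2)
  x <- matrix(0, n2, nrow(data))
  x[seq_len(n), ] <- t(data)
  y <- Re(mvfft(mvfft(x) * mag2, inverse = TRUE)) / n2
  out <- t(y[seq_len(n), , drop = FALSE])
  dimnames(out) <- dimnames(data)
  out
}

apply_filtfilt <- function(data, bf) {
  n2 <- stats::nextn(ncol(data), c(2, 3, 5))
  apply_mag2(data, zerophase_mag2(bf, n2))
}

#' @rdname downsample
#' @param freq Centre frequency of the power-line notch, Hz.
#' @param width Half-width of the stop band, Hz (stop band
#'   `freq +/- width`).
#' @param order Butterworth design order (4 gives a 4th-order band-stop /
#'   band-pass polynomial).
#' @export
notch_filter <- function(rec, freq = 50, width = 2, order = 4) {
  stopifnot(is_session_recording(rec))
  if (freq + width >= rec$fs / 2) {
    abort("Notch frequency must lie below the Nyquist frequency.")
  }
  bf <- signal::butter(order / 2, c(freq - width, freq + width) / (rec$fs / 2),
                       type = "stop")
  rec$data <- apply_filtfilt(rec$data, bf)
  rec
}

#' @rdname downsample
#' @param lo,hi Band-pass edges in Hz.
#' @export
bandpass_filter <- function(rec, lo = 8, hi = 30, order = 4) {
  stopifnot(is_session_recording(rec))
  if (!(0 < lo && lo < hi && hi < rec$fs / 2)) {
    abort("Band edges must satisfy 0 < lo < hi < fs/2.")
  }
  bf <- signal::butter(order / 2, c(lo, hi) / (rec$fs / 2), type = "pass")
  rec$data <- apply_filtfilt(rec$data, bf)
  rec
}

#' @rdname downsample
#' @param notch_freq,notch_width Notch parameters, as in [notch_filter()].
#' @export
preprocess_session <- function(rec, target_fs = 250, notch_freq = 50,
                               notch_width = 2, lo = 8, hi = 30) {
  rec <- downsample(rec, target_fs)
  # notch and band-pass are LTI and zero-phase, so their responses fuse
  # into a single frequency-domain pass (identical result, one FFT pair)
  n2 <- stats::nextn(ncol(rec$data), c(2, 3, 5))
  nyq <- rec$fs / 2
  notch <- signal::butter(2, c(notch_freq - notch_width,
                               notch_freq + notch_width) / nyq, type = "stop")
  bp <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
  rec$data <- apply_mag2(rec$data,
                         zerophase_mag2(notch, n2) * zerophase_mag2(bp, n2))
  rec
}

#' Cut trials out of a continuous recording
#'
#' Extracts one epoch per event.  Time is imagery-relative: t = 0 at
#' imagery onset, so the 4 s classification window is `c(0, 4)` and the
#' time-frequency window is `c(-2, 8)`.  Epochs are cut after
#' whole-recording filtering, so no per-epoch padding is required.
#'
#' @param rec A `session_recording`.
#' @param window Length-2 numeric, epoch window in seconds relative to
#'   imagery onset.
#' @return An `epoch_set`: list with `trials` (channels x samples x trials
#'   array), `labels` (1 = left, 2 = right), `runs`, `time_axis`, `fs`,
#'   `channel_labels` and ids.
#' @export
epoch_trials <- function(rec, window = c(0, 4)) {
  stopifnot(is_session_recording(rec), length(window) == 2)
  n_samp <- round((window[2] - window[1]) * rec$fs)
  offset <- round(window[1] * rec$fs)
  starts <- rec$events$onset_sample + offset
  if (nrow(rec$events) > 0 &&
      (min(starts) < 1 || max(starts) + n_samp - 1 > ncol(rec$data))) {
    abort("Epoch window exceeds recording bounds.")
  }
  cols <- as.vector(outer(seq_len(n_samp) - 1L, starts, "+"))
  trials <- array(
    rec$data[, cols, drop = FALSE],
    dim = c(nrow(rec$data), n_samp, nrow(rec$events)),
    dimnames = list(rec$channel_labels, NULL, NULL)
  )
  labels <- ifelse(rec$events$class == "left", 1L, 2L)
  structure(
    list(
      trials = trials,
      labels = labels,
      runs = rec$events$run,
      time_axis = window[1] + (seq_len(n_samp) - 1) / rec$fs,
      fs = rec$fs,
      window = window,
      channel_labels = rec$channel_labels,
      subject_id = rec$subject_id,
      session_id = rec$session_id
    ),
    class = "epoch_set"
  )
}

#' Work with epoch sets
#'
#' `n_trials()` counts trials; `subset_epochs()` keeps the given trial
#' indices; `combine_epochs()` concatenates epoch sets sharing channel
#' layout and window (used by the All training strategy).
#'
#' @param epochs An `epoch_set`.
#' @return An `epoch_set` (or a count for `n_trials()`).
#' @export
n_trials <- function(epochs) {
  stopifnot(is_epoch_set(epochs))
  length(epochs$labels)
}

#' @rdname n_trials
#' @param idx Integer or logical trial index.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(is_epoch_set(epochs))
  epochs$trials <- epochs$trials[, , idx, drop = FALSE]
  epochs$labels <- epochs$labels[idx]
  epochs$runs <- epochs$runs[idx]
  epochs
}

#' @rdname n_trials
#' @param sets A list of `epoch_set` objects.
#' @export
combine_epochs <- function(sets) {
  stopifnot(length(sets) >= 1, all(vapply(sets, is_epoch_set, logical(1))))
  base <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$channel_labels, base$channel_labels) ||
        !isTRUE(all.equal(s$window, base$window)) || s$fs != base$fs) {
      abort("Epoch sets must share channels, window and sampling rate.")
    }
  }
  dims <- dim(base$trials)
  total <- sum(vapply(sets, n_trials, integer(1)))
  trials <- array(0, dim = c(dims[1], dims[2], total),
                  dimnames = list(base$channel_labels, NULL, NULL))
  at <- 0L
  for (s in sets) {
    k <- n_trials(s)
    if (k > 0) trials[, , at + seq_len(k)] <- s$trials
    at <- at + k
  }
  base$trials <- trials
  base$labels <- unlist(lapply(sets, `[[`, "labels"))
  base$runs <- unlist(lapply(sets, `[[`, "runs"))
  base$session_id <- paste(unique(vapply(sets, `[[`, "", "session_id")),
                           collapse = "+")
  base$subject_id <- paste(unique(vapply(sets, `[[`, "", "subject_id")),
                           collapse = "+")
  base
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf(
    "<epoch_set> %s/%s: %d trials (%d left / %d right), %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
    x$subject_id, x$session_id, d[3], sum(x$labels == 1L),
    sum(x$labels == 2L), d[1], d[2], x$fs, x$window[1], x$window[2]
  ))
  invisible(x)
}
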