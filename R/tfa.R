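#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets (fixed 7
#' cycles, implemented as Gaussian kernels in the frequency domain) and
#' averages the single-trial power across trials (induced-activity
#' convention: power is taken before averaging, so non-phase-locked
#' activity survives).  To avoid edge contamination `trim_s` seconds are
#' dropped from each end of the epoch after the transform; pass epochs cut
#' 1 s wider than the window you want to analyse (e.g. `c(-3, 9)` for a
#' `[-2, 8]` s map).
#'
#' @param epochs An `epoch_set`.
#' @param freqs Analysis frequencies in Hz (default 8-30 in 1 Hz steps);
#'   all must lie below the Nyquist frequency.
#' @param channels Channel labels to analyse (default: all).
#' @param class `"left"`, `"right"` or `NULL` to average over all trials.
#' @param n_cycles Morlet width in cycles.
#' @param trim_s Seconds trimmed from each epoch edge after the transform.
#' @return A `tf_response`: `power` (channels x frequencies x times,
#'   microvolt^2), `freqs`, `times`, `class`, `n_trials`,
#'   `baseline_corrected`.
#' @export
wavelet_tfr <- function(epochs, freqs = 8:30, channels = NULL, class = NULL,
                        n_cycles = 7, trim_s = 1) {
  stopifnot(is_epoch_set(epochs))
  if (any(freqs <= 0) || any(freqs >= epochs$fs / 2)) {
    abort("All `freqs` must lie in (0, fs/2).")
  }
  freqs <- sort(freqs)
  channels <- channels %||% epochs$channel_labels
  if (!all(channels %in% epochs$channel_labels)) {
    abort("Unknown channel label.")
  }
  keep_trials <- seq_len(n_trials(epochs))
  if (!is.null(class)) {
    keep_trials <- which(epochs$labels == c(left = 1L, right = 2L)[[class]])
  }
  n_t <- dim(epochs$trials)[2]
  n_pad <- stats::nextn(n_t, 2)
  fgrid <- fft_freqs(n_pad, epochs$fs)
  trim_n <- round(trim_s * epochs$fs)
  keep_time <- (trim_n + 1):(n_t - trim_n)
  if (length(keep_time) < 1) abort("`trim_s` leaves no samples.")

  power <- array(
    0, dim = c(length(channels), length(freqs), length(keep_time)),
    dimnames = list(channels, NULL, NULL)
  )
  for (ci in seq_along(channels)) {
    ch <- match(channels[ci], epochs$channel_labels)
    sig <- matrix(0, n_pad, length(keep_trials))
    sig[seq_len(n_t), ] <- epochs$trials[ch, , keep_trials]
    spec <- mvfft(sig)
    for (fi in seq_along(freqs)) {
      sigma_f <- freqs[fi] / n_cycles
      # analytic Morlet: Gaussian on the positive-frequency half only
      h <- exp(-(fgrid - freqs[fi])^2 / (2 * sigma_f^2))
      h[seq_len(n_pad) - 1 > n_pad / 2] <- 0
      conv <- mvfft(spec * h, inverse = TRUE) / n_pad
      p <- Mod(conv[keep_time, , drop = FALSE])^2
      power[ci, fi, ] <- rowMeans(p)
    }
  }
  structure(
    list(
      power = power,
      freqs = freqs,
      times = epochs$time_axis[keep_time],
      class = class %||% "both",
      n_trials = length(keep_trials),
      baseline_corrected = FALSE
    ),
    class = "tf_response"
  )
}

#' Baseline-correct a time-frequency response
#'
#' Subtracts, per channel and frequency, the mean power over the reference
#' interval (default the 2 s of fixation before imagery onset).
#'
#' @param tfr A `tf_response`.
#' @param ref Length-2 numeric, reference interval in imagery-relative
#'   seconds; must lie inside the time axis.
#' @return The corrected `tf_response` (`baseline_corrected = TRUE`).
#' @export
baseline_correct <- function(tfr, ref = c(-2, 0)) {
  stopifnot(inherits(tfr, "tf_response"))
  if (tfr$baseline_corrected) abort("Already baseline-corrected.")
  sel <- tfr$times >= ref[1] & tfr$times <= ref[2]
  if (!any(sel)) abort("Reference interval lies outside the time axis.")
  base <- apply(tfr$power[, , sel, drop = FALSE], c(1, 2), mean)
  tfr$power <- sweep(tfr$power, c(1, 2), base)
  tfr$baseline_corrected <- TRUE
  tfr
}

#' Percent ERD/ERS index
#'
#' The classical band-power index `(P_post - P_pre) / P_pre * 100`, where
#' `P_pre` is the mean raw wavelet power over the reference interval
#' (default -2-0 s) and `P_post` over the imagery interval (default
#' 0-4 s), both averaged over the 8-30 Hz band.  Negative values indicate
#' desynchronization (ERD), positive values synchronization (ERS).  The
#' index is a power ratio, so it is invariant to global amplitude scaling
#' of the recording.  Requires an uncorrected `tf_response`.
#'
#' @param tfr An uncorrected `tf_response`.
#' @param channels Channel label(s); default: all channels in `tfr`.
#' @param pre,post Reference and imagery intervals in seconds.
#' @param band Frequency band in Hz averaged over.
#' @return An `erd_report` tibble: `channel`, `class`, `p_pre`, `p_post`,
#'   `index` (percent).
#' @export
erd_ers_index <- function(tfr, channels = NULL, pre = c(-2, 0),
                          post = c(0, 4), band = c(8, 30)) {
  stopifnot(inherits(tfr, "tf_response"))
  if (tfr$baseline_corrected) {
    abort("The ERD/ERS index uses raw (uncorrected) power.")
  }
  channels <- channels %||% dimnames(tfr$power)[[1]]
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  pre_sel <- tfr$times >= pre[1] & tfr$times <= pre[2]
  post_sel <- tfr$times >= post[1] & tfr$times <= post[2]
  if (!any(pre_sel) || !any(post_sel)) {
    abort("Index intervals lie outside the time axis.")
  }
  rows <- lapply(channels, function(ch) {
    p <- tfr$power[ch, fsel, , drop = FALSE]
    p_pre <- mean(p[, , pre_sel])
    p_post <- mean(p[, , post_sel])
    if (p_pre <= 0) abort("P_pre must be positive.")
    tibble(channel = ch, class = tfr$class, p_pre = p_pre, p_post = p_post,
           index = (p_post - p_pre) / p_pre * 100)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("erd_report", class(out))
  out
}

#' Per-session ERD/ERS analysis
#'
#' Convenience pipeline: preprocess a continuous recording, cut wide
#' epochs (`[-3, 9]` s so the analysed `[-2, 8]` s map is free of edge
#' effects), run the wavelet transform on the motor channels per class,
#' and return the ERD/ERS index table with a contralateral/ipsilateral
#' annotation (left-hand imagery is contralateral on C4).
#'
#' @param rec A `session_recording` (raw; preprocessing is applied here).
#' @param channels Channels to report (default C3 and C4).
#' @param ... Passed to [wavelet_tfr()].
#' @return An `erd_report` tibble with columns `subject_id`, `session_id`,
#'   `channel`, `class`, `side`, `p_pre`, `p_post`, `index`.
#' @export
session_erd <- function(rec, channels = c("C3", "C4"), ...) {
  epochs <- rec |> preprocess_session() |> epoch_trials(window = c(-3, 9))
  out <- dplyr::bind_rows(lapply(c("left", "right"), function(cl) {
    tfr <- wavelet_tfr(epochs, channels = channels, class = cl, ...)
    erd_ers_index(tfr)
  }))
  out$side <- ifelse(
    (out$class == "left") == (out$channel %in% c("C4", "C2", "C6")),
    "contralateral", "ipsilateral"
  )
  out$subject_id <- rec$subject_id
  out$session_id <- rec$session_id
  out[, c("subject_id", "session_id", "channel", "class", "side",
          "p_pre", "p_post", "index")]
}
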