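# Minimal European Data Format (EDF) writer/reader: 16-bit samples,
# 1-second data records, one continuous recording per file.  Event markers
# travel in a plain-CSV sidecar (columns onset_sample, class, run), the
# format the cohort generator writes and the reader expects.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write and read EDF session files
#'
#' `write_session_edf()` stores a `session_recording` as a 16-bit EDF file
#' plus a CSV event sidecar (`<path>.events.csv` by default); amplitudes
#' are scaled per channel into the signed 16-bit range, so the round trip
#' is exact up to quantization (about `max(abs(x))/32767` per channel).
#' `read_session_edf()` reconstructs the recording (without generator
#' ground truth).
#'
#' @param rec A `session_recording`.
#' @param path Output `.edf` path.
#' @param events_path Sidecar CSV path.
#' @return `write_session_edf()` returns `path` invisibly;
#'   `read_session_edf()` returns a `session_recording`.
#' @export
write_session_edf <- function(rec, path,
                              events_path = paste0(path, ".events.csv")) {
  stopifnot(is_session_recording(rec))
  fs <- rec$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate.")
  n <- ncol(rec$data)
  ns <- nrow(rec$data)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n

  phys_max <- vapply(seq_len(ns), function(i) {
    m <- max(abs(rec$data[i, ]), 1e-6)
    as.numeric(edf_pad(signif(m, 6), 8))
  }, numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(paste(rec$subject_id, rec$session_id), 80),
    edf_pad(sprintf("smrbci n_samples=%d", n), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(edf_pad(rec$channel_labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(-phys_max, 8), collapse = ""),
    paste(edf_pad(phys_max, 8), collapse = ""),
    paste(rep(edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  ), con, eos = NULL)

  padded <- cbind(rec$data, matrix(0, ns, pad))
  digital <- round(sweep(padded, 1, phys_max / 32767, "/"))
  digital <- pmin(pmax(digital, -32768), 32767)
  # EDF layout: per record, each signal's fs samples in sequence
  arr <- array(t(digital), dim = c(fs, n_rec, ns))
  writeBin(as.integer(aperm(arr, c(1, 3, 2))), con, size = 2,
           endian = "little")

  readr::write_csv(rec$events, events_path)
  invisible(path)
}

#' @rdname write_session_edf
#' @export
read_session_edf <- function(path,
                             events_path = paste0(path, ".events.csv")) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  ids <- strsplit(fld(hdr, 9, 80), " ")[[1]]
  n_true <- suppressWarnings(
    as.integer(sub("n_samples=", "", fld(hdr, 89, 80) |>
                     strsplit(" ") |> unlist() |>
                     grep(pattern = "n_samples=", value = TRUE)))
  )
  n_rec <- as.integer(fld(hdr, 237, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  sig_hdr <- readChar(con, ns * 256, useBytes = TRUE)
  grab <- function(offset, width) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1,
                    offset + i * width))
    }, character(1))
  }
  labels <- grab(0, 16)
  phys_max <- as.numeric(grab(ns * (16 + 80 + 8 + 8), 8))
  spr <- as.integer(grab(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  fs <- spr[1]
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  arr <- array(raw, dim = c(fs, ns, n_rec))
  data <- matrix(aperm(arr, c(1, 3, 2)), nrow = n_rec * fs, ncol = ns) |> t()
  data <- sweep(data, 1, phys_max / 32767, "*")
  if (length(n_true) == 1 && !is.na(n_true)) {
    data <- data[, seq_len(n_true), drop = FALSE]
  }
  rownames(data) <- labels
  events <- if (file.exists(events_path)) {
    readr::read_csv(events_path, show_col_types = FALSE)
  } else {
    tibble(onset_sample = integer(), class = character(), run = integer())
  }
  structure(
    list(
      data = data, fs = fs, channel_labels = labels, events = events,
      subject_id = ids[1] %||% NA_character_,
      session_id = ids[2] %||% NA_character_,
      ground_truth = NULL
    ),
    class = "session_recording"
  )
}

#' Write and read a session as an array bundle
#'
#' A directory with `data.rds` (compressed channels x samples matrix),
#' `meta.json` (sampling rate, labels, ids and, when present, the
#' generator's ground-truth parameters) and `events.csv`.  Lossless,
#' unlike the 16-bit EDF path.
#'
#' @param rec A `session_recording`.
#' @param dir Bundle directory (created if needed).
#' @return `write_session_bundle()` returns `dir` invisibly;
#'   `read_session_bundle()` a `session_recording`.
#' @export
write_session_bundle <- function(rec, dir) {
  stopifnot(is_session_recording(rec))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(rec$data, file.path(dir, "data.rds"), compress = "gzip")
  meta <- list(
    fs = rec$fs, channel_labels = rec$channel_labels,
    subject_id = rec$subject_id, session_id = rec$session_id
  )
  if (!is.null(rec$ground_truth)) {
    gt <- unclass(rec$ground_truth)
    gt$topography <- lapply(gt$topography, as.list)
    meta$ground_truth <- gt
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  readr::write_csv(rec$events, file.path(dir, "events.csv"))
  invisible(dir)
}

#' @rdname write_session_bundle
#' @export
read_session_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    gt <- meta$ground_truth
    gt$topography <- lapply(gt$topography, unlist)
    cls <- if (is.null(gt$session_index) || is.na(gt$session_index)) {
      "subject_params"
    } else {
      c("session_params", "subject_params")
    }
    gt <- structure(gt, class = cls)
  }
  structure(
    list(
      data = readRDS(file.path(dir, "data.rds")),
      fs = meta$fs,
      channel_labels = meta$channel_labels,
      events = readr::read_csv(file.path(dir, "events.csv"),
                               show_col_types = FALSE),
      subject_id = meta$subject_id,
      session_id = meta$session_id,
      ground_truth = gt
    ),
    class = "session_recording"
  )
}
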