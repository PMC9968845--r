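# Serializers for fitted objects and derived arrays: JSON for models
# (small, human-readable, diffable), CSV for per-trial feature tables,
# CSV-matrix + JSON metadata for time-frequency power.

#' Serialize fitted models and feature tables
#'
#' `write_csp_model()`/`read_csp_model()` round-trip a CSP model through
#' JSON (filters, eigenvalues, metadata).  `write_lda_model()`/
#' `read_lda_model()` do the same for an LDA model.  `write_features()`
#' writes a `feature_set` as CSV (one row per trial: features, label,
#' run) with its provenance attributes in a JSON sidecar read back by
#' `read_features()`.
#'
#' @param model A `csp_model` or `lda_model`.
#' @param path Output file path.
#' @return Writers return `path` invisibly; readers return the object.
#' @export
write_csp_model <- function(model, path) {
  stopifnot(inherits(model, "csp_model"))
  jsonlite::write_json(
    list(
      filters = model$filters, eigenvalues = model$eigenvalues,
      n_pairs = model$n_pairs, channels = rownames(model$filters),
      filter_names = colnames(model$filters), metadata = model$metadata
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_csp_model
#' @export
read_csp_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  filters <- matrix(unlist(x$filters), nrow = length(x$channels),
                    dimnames = list(x$channels, x$filter_names))
  structure(
    list(filters = filters, eigenvalues = x$eigenvalues,
         n_pairs = as.integer(x$n_pairs), metadata = as.list(x$metadata)),
    class = "csp_model"
  )
}

#' @rdname write_csp_model
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  jsonlite::write_json(
    list(w = model$w, b = model$b, S = model$S, mu1 = model$mu1,
         mu2 = model$mu2, n1 = model$n1, n2 = model$n2,
         terms = names(model$w)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_csp_model
#' @export
read_lda_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(x$w)
  nm <- if (length(x$terms)) x$terms else NULL
  structure(
    list(w = setNames(x$w, nm), b = x$b, S = matrix(unlist(x$S), d),
         mu1 = setNames(x$mu1, nm), mu2 = setNames(x$mu2, nm),
         n1 = as.integer(x$n1), n2 = as.integer(x$n2)),
    class = "lda_model"
  )
}

#' @rdname write_csp_model
#' @param features A `feature_set`.
#' @export
write_features <- function(features, path) {
  readr::write_csv(as.data.frame(features), path)
  jsonlite::write_json(
    list(n_pairs = attr(features, "n_pairs"),
         csp_session = attr(features, "csp_session"),
         source_session = attr(features, "source_session")),
    paste0(path, ".meta.json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_csp_model
#' @export
read_features <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "n_pairs") <- meta$n_pairs
    attr(out, "csp_session") <- meta$csp_session
    attr(out, "source_session") <- meta$source_session
  }
  class(out) <- c("feature_set", class(out))
  out
}

#' Export a time-frequency response
#'
#' Writes one CSV power matrix (frequencies x times) per channel plus a
#' `meta.json` describing the axes, class and baseline state.
#'
#' @param tfr A `tf_response`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tfr <- function(tfr, dir) {
  stopifnot(inherits(tfr, "tf_response"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- dimnames(tfr$power)[[1]]
  for (ch in chans) {
    m <- tfr$power[ch, , ]
    df <- as.data.frame(m)
    names(df) <- sprintf("t%.4f", tfr$times)
    df <- cbind(freq_hz = tfr$freqs, df)
    readr::write_csv(df, file.path(dir, paste0("power_", ch, ".csv")))
  }
  jsonlite::write_json(
    list(channels = chans, freqs = tfr$freqs, times = tfr$times,
         class = tfr$class, n_trials = tfr$n_trials,
         baseline_corrected = tfr$baseline_corrected),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
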