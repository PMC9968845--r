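#' Normalized spatial covariance
#'
#' For a trial `X` (channels x samples), the normalized spatial covariance
#' is `X X' / trace(X X')`: a symmetric positive semi-definite channels x
#' channels matrix with unit trace, so every trial contributes equally
#' regardless of its broadband amplitude.
#'
#' @param trial Numeric matrix, channels x samples, with more samples than
#'   channels.
#' @return A channels x channels matrix with trace 1.
#' @export
trial_covariance <- function(trial) {
  stopifnot(is.matrix(trial), all(is.finite(trial)))
  if (ncol(trial) <= nrow(trial)) {
    abort("Trial must have more samples than channels.")
  }
  s <- tcrossprod(trial)
  tr <- sum(diag(s))
  if (tr <= 0) abort("All-zero trial: covariance trace is zero.")
  s / tr
}

#' @rdname trial_covariance
#' @param epochs An `epoch_set`.
#' @return `trial_covariances()` returns a list of per-trial covariance
#'   matrices.
#' @export
trial_covariances <- function(epochs) {
  stopifnot(is_epoch_set(epochs))
  lapply(seq_len(n_trials(epochs)),
         function(i) trial_covariance(epochs$trials[, , i]))
}

#' @rdname trial_covariance
#' @param covs List of per-trial covariance matrices.
#' @param labels Integer class labels (1 = left, 2 = right), one per trial.
#' @return `class_mean_covariances()` returns `list(left = , right = )` of
#'   arithmetic-mean covariance matrices.
#' @export
class_mean_covariances <- function(covs, labels) {
  stopifnot(length(covs) == length(labels))
  if (!all(c(1L, 2L) %in% labels)) {
    abort("Both classes must be present to average covariances.")
  }
  avg <- function(idx) Reduce(`+`, covs[idx]) / length(idx)
  list(left = avg(which(labels == 1L)), right = avg(which(labels == 2L)))
}

#' Fit common spatial patterns
#'
#' Solves the generalized eigenvalue problem `Sigma_r w = lambda Sigma_l w`
#' on the class-mean covariance matrices, via whitening of `Sigma_l`
#' (symmetric inverse square root) followed by a symmetric eigen
#' decomposition.  Filters are returned in the order `top 1 ... top
#' n_pairs, bottom 1 ... bottom n_pairs` of descending eigenvalue, each
#' scaled to unit Euclidean norm.  Large eigenvalues give filters whose
#' projections have high variance for right-hand trials and low variance
#' for left-hand trials; small eigenvalues the reverse.  `Sigma_l` is
#' ridge-regularized by `1e-10 trace(Sigma_l) I` when its condition number
#' exceeds 1e12.
#'
#' @param cov_left,cov_right Class-mean spatial covariance matrices.
#' @param n_pairs Number of filter pairs to keep (3 for the 6-D online
#'   feature set; 1 for the 2-D analysis feature space).
#' @param metadata Optional list stored in the model (e.g. training
#'   session ids).
#' @return A `csp_model`: `filters` (channels x 2 n_pairs), `eigenvalues`,
#'   `n_pairs`, `metadata`.
#' @export
fit_csp <- function(cov_left, cov_right, n_pairs = 3, metadata = list()) {
  stopifnot(is.matrix(cov_left), is.matrix(cov_right),
            all(dim(cov_left) == dim(cov_right)))
  C <- nrow(cov_left)
  if (n_pairs > C / 2) abort("`n_pairs` must be at most half the channel count.")
  sl <- (cov_left + t(cov_left)) / 2
  el <- eigen(sl, symmetric = TRUE)
  if (min(el$values) <= 0 ||
      max(el$values) / max(min(el$values), .Machine$double.xmin) > 1e12) {
    sl <- sl + 1e-10 * sum(diag(sl)) * diag(C)
    el <- eigen(sl, symmetric = TRUE)
  }
  if (min(el$values) <= 0) abort("`cov_left` is singular beyond regularization.")
  # whitening transform W with W Sigma_l W = I
  white <- el$vectors %*% diag(1 / sqrt(el$values), C) %*% t(el$vectors)
  m <- white %*% ((cov_right + t(cov_right)) / 2) %*% white
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)   # eigenvalues descending
  filters_all <- white %*% em$vectors
  idx <- c(seq_len(n_pairs), C - seq_len(n_pairs) + 1L)
  filters <- filters_all[, idx, drop = FALSE]
  filters <- sweep(filters, 2, sqrt(colSums(filters^2)), "/")
  rownames(filters) <- rownames(cov_left)
  colnames(filters) <- c(paste0("top", seq_len(n_pairs)),
                         paste0("bottom", seq_len(n_pairs)))
  structure(
    list(
      filters = filters,
      eigenvalues = em$values[idx],
      n_pairs = as.integer(n_pairs),
      metadata = metadata
    ),
    class = "csp_model"
  )
}

#' @rdname fit_csp
#' @param epochs An `epoch_set` with both classes present.
#' @param ... Passed to `fit_csp()`.
#' @export
fit_csp_epochs <- function(epochs, n_pairs = 3, ...) {
  covs <- trial_covariances(epochs)
  cm <- class_mean_covariances(covs, epochs$labels)
  fit_csp(cm$left, cm$right, n_pairs = n_pairs,
          metadata = list(session_id = epochs$session_id,
                          subject_id = epochs$subject_id), ...)
}

# per-class covariance sums of an epoch set; additive over sessions, so
# the class-mean covariances of concatenated sessions are recovered by
# summing these and dividing by the trial counts
class_cov_sums <- function(epochs) {
  covs <- trial_covariances(epochs)
  idx_l <- which(epochs$labels == 1L)
  idx_r <- which(epochs$labels == 2L)
  list(
    left = Reduce(`+`, covs[idx_l]), n_left = length(idx_l),
    right = Reduce(`+`, covs[idx_r]), n_right = length(idx_r)
  )
}

add_cov_sums <- function(a, b) {
  list(left = a$left + b$left, n_left = a$n_left + b$n_left,
       right = a$right + b$right, n_right = a$n_right + b$n_right)
}

fit_csp_sums <- function(sums, n_pairs = 3, metadata = list()) {
  fit_csp(sums$left / sums$n_left, sums$right / sums$n_right,
          n_pairs = n_pairs, metadata = metadata)
}

#' Log band-power CSP features
#'
#' Projects each trial through the spatial filters and takes the log of
#' the variance of each projected signal: `2 * n_pairs` features per
#' trial.  With `normalize = TRUE` the variances are divided by their sum
#' over filters before the log (the normalized-variance variant); the
#' default is the raw log band power.
#'
#' @param model A `csp_model`.
#' @param epochs An `epoch_set` with the same channel count.
#' @param normalize Normalize projected variances to their sum first?
#' @return A `feature_set` tibble: columns `trial`, `run`, `label` and
#'   `f1 ... f<2 n_pairs>`, with attributes `n_pairs`, `csp_session`
#'   (where the filters were fit) and `source_session` (where the trials
#'   come from).
#' @export
extract_features <- function(model, epochs, normalize = FALSE) {
  stopifnot(inherits(model, "csp_model"), is_epoch_set(epochs))
  if (nrow(model$filters) != dim(epochs$trials)[1]) {
    abort("Channel count of epochs does not match the CSP model.")
  }
  n <- n_trials(epochs)
  d <- dim(epochs$trials)
  # project all trials at once, then per-trial variance of each projection
  proj <- crossprod(model$filters, matrix(epochs$trials, d[1], d[2] * n))
  feats <- matrix(0, n, ncol(model$filters))
  for (k in seq_len(ncol(model$filters))) {
    pk <- matrix(proj[k, ], d[2], n)
    feats[, k] <- (colSums(pk^2) - d[2] * colMeans(pk)^2) / (d[2] - 1)
  }
  if (any(feats <= 0)) abort("Zero-variance projection: cannot take log power.")
  if (normalize) feats <- feats / rowSums(feats)
  feats <- log(feats)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  out <- tibble(trial = seq_len(n), run = epochs$runs, label = epochs$labels)
  out <- dplyr::bind_cols(out, as_tibble(feats))
  attr(out, "n_pairs") <- model$n_pairs
  attr(out, "csp_session") <- model$metadata$session_id %||% NA_character_
  attr(out, "source_session") <- epochs$session_id
  class(out) <- c("feature_set", class(out))
  out
}

# numeric feature matrix of a feature_set (or plain matrix passthrough)
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  as.matrix(features[grep("^f[0-9]+$", names(features))])
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf(
    "<csp_model> %d filter pairs over %d channels; eigenvalues %s\n",
    x$n_pairs, nrow(x$filters),
    paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")
  ))
  invisible(x)
}
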