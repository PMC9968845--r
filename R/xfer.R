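#' Cross-train/test transfer matrix
#'
#' For every ordered pair of sessions (i, j): fit CSP and LDA on all
#' trials of session i, extract session j's features with session i's
#' spatial filters, and score session i's classifier on them.  The
#' diagonal is the within-session self-test (train set = test set); the
#' off-diagonal cells measure cross-session or cross-subject transfer.
#'
#' @param sessions A named list of `epoch_set` objects with identical
#'   channel layouts (at least 2).
#' @param n_pairs CSP filter pairs; 1 (the 2-D analysis feature space) by
#'   default.
#' @param normalize Passed to [extract_features()].
#' @return A `cross_matrix`: `acc` (m x m accuracy matrix, percent),
#'   `feats` (m x m list of `feature_set`s), `sessions` (ids).
#' @export
build_cross_matrix <- function(sessions, n_pairs = 1, normalize = FALSE) {
  stopifnot(length(sessions) >= 2,
            all(vapply(sessions, is_epoch_set, logical(1))))
  ids <- names(sessions) %||% paste0("s", seq_along(sessions))
  chans <- lapply(sessions, `[[`, "channel_labels")
  if (!all(vapply(chans, identical, logical(1), chans[[1]]))) {
    abort("All sessions must share the same channel set.")
  }
  m <- length(sessions)
  acc <- matrix(NA_real_, m, m, dimnames = list(train = ids, test = ids))
  feats <- vector("list", m * m)
  dim(feats) <- c(m, m)
  dimnames(feats) <- list(train = ids, test = ids)
  for (i in seq_len(m)) {
    csp <- fit_csp_epochs(sessions[[i]], n_pairs = n_pairs)
    csp$metadata$session_id <- ids[i]
    train_feats <- extract_features(csp, sessions[[i]], normalize = normalize)
    lda <- fit_lda(train_feats)
    for (j in seq_len(m)) {
      fj <- if (j == i) train_feats else {
        extract_features(csp, sessions[[j]], normalize = normalize)
      }
      acc[i, j] <- accuracy(predict(lda, fj), fj$label)
      feats[[i, j]] <- fj
    }
  }
  structure(list(acc = acc, feats = feats, sessions = ids, n_pairs = n_pairs),
            class = "cross_matrix")
}

#' @export
print.cross_matrix <- function(x, ...) {
  cat(sprintf("<cross_matrix> %d x %d sessions, %d CSP pair(s)\n",
              length(x$sessions), length(x$sessions), x$n_pairs))
  print(round(x$acc, 2))
  invisible(x)
}

#' Distribution statistics of a 2-D feature cloud
#'
#' Four statistics of a two-dimensional CSP feature distribution, with
#' `n` trials per class: the pooled mean over all `2n` trials (per
#' dimension); the pooled population standard deviation around the pooled
#' mean (per dimension, `1/(2n)` normalization); the within-class
#' distance `Dist_w`, the mean Euclidean distance of each trial to its
#' own class centre; and the between-class distance `Dist_b`, the
#' Euclidean distance between the two class centres.
#'
#' @param features A `feature_set` (or matrix plus `labels`) with exactly
#'   two feature dimensions and both classes present.
#' @param labels Class labels when `features` is a matrix.
#' @return A one-row `dist_stats` tibble: `mean1`, `mean2`, `std1`,
#'   `std2`, `dist_w`, `dist_b`, `n` (trials per class, averaged if
#'   unbalanced).
#' @export
dist_stats <- function(features, labels = NULL) {
  x <- feature_matrix(features)
  labels <- labels %||% features$label
  if (ncol(x) != 2) abort("Distribution statistics are defined for 2-D features.")
  if (!all(c(1L, 2L) %in% labels)) abort("Both classes must be present.")
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, mu)^2))
  mu1 <- colMeans(x[labels == 1L, , drop = FALSE])
  mu2 <- colMeans(x[labels == 2L, , drop = FALSE])
  centred <- x - rbind(mu1, mu2)[labels, ]
  dist_w <- mean(sqrt(rowSums(centred^2)))
  dist_b <- sqrt(sum((mu1 - mu2)^2))
  out <- tibble(
    mean1 = mu[1], mean2 = mu[2], std1 = s[1], std2 = s[2],
    dist_w = dist_w, dist_b = dist_b, n = length(labels) / 2
  )
  class(out) <- c("dist_stats", class(out))
  out
}

#' Distribution statistics of every transfer-matrix cell
#'
#' @param cm A `cross_matrix`.
#' @return A tibble with one row per cell: `train`, `test`, `cell`
#'   (`"diagonal"` or `"offdiagonal"`), `accuracy` and the [dist_stats()]
#'   columns.
#' @export
cross_matrix_stats <- function(cm) {
  stopifnot(inherits(cm, "cross_matrix"))
  m <- length(cm$sessions)
  rows <- list()
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      st <- dist_stats(cm$feats[[i, j]])
      st$train <- cm$sessions[i]
      st$test <- cm$sessions[j]
      st$cell <- if (i == j) "diagonal" else "offdiagonal"
      st$accuracy <- cm$acc[i, j]
      rows[[length(rows) + 1L]] <- st
    }
  }
  out <- dplyr::bind_rows(rows)
  out[, c("train", "test", "cell", "accuracy", "mean1", "mean2",
          "std1", "std2", "dist_w", "dist_b", "n")]
}

#' Compare distribution statistics between two experiments
#'
#' Two-sample t-tests (Student's equal-variance by default; Welch with
#' `var_equal = FALSE`) on each of the six statistics (mean and std per
#' dimension, `Dist_w`, `Dist_b`) between two groups of feature-cloud
#' statistics, e.g. the diagonal cells of a multi-subject experiment
#' versus the diagonal cells of a multi-session experiment.  Significance
#' is declared at the Bonferroni-adjusted threshold `family_alpha /
#' n_comparisons`; the default family counts 6 statistics in each of 2
#' tasks (self-test and transfer), i.e. 12 comparisons, giving 0.05/12 =
#' 4.17e-3.
#'
#' @param stats_a,stats_b Tibbles of [dist_stats()] rows (one per cell).
#' @param family_alpha Family-wise error rate.
#' @param n_comparisons Size of the comparison family.
#' @param var_equal Use the pooled-variance t-test?
#' @return A `ttest_report` tibble: `statistic`, `mean_a`, `mean_b`,
#'   `t_value`, `p_value`, `significant`, plus `alpha_adjusted`,
#'   `n_a`/`n_b` as attributes-free columns.
#' @export
compare_exp_groups <- function(stats_a, stats_b, family_alpha = 0.05,
                               n_comparisons = 12, var_equal = TRUE) {
  cols <- c("mean1", "mean2", "std1", "std2", "dist_w", "dist_b")
  stopifnot(all(cols %in% names(stats_a)), all(cols %in% names(stats_b)))
  if (nrow(stats_a) < 2 || nrow(stats_b) < 2) {
    abort("Each group needs at least two cells for a t-test.")
  }
  alpha_adj <- family_alpha / n_comparisons
  rows <- lapply(cols, function(cl) {
    a <- stats_a[[cl]]
    b <- stats_b[[cl]]
    if (isTRUE(all.equal(var(a), 0)) && isTRUE(all.equal(var(b), 0)) &&
        isTRUE(all.equal(mean(a), mean(b)))) {
      tv <- 0
      pv <- 1
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
      tv <- unname(tt$statistic)
      pv <- tt$p.value
    }
    tibble(statistic = cl, mean_a = mean(a), mean_b = mean(b),
           t_value = tv, p_value = pv,
           significant = pv < alpha_adj,
           alpha_adjusted = alpha_adj,
           n_a = length(a), n_b = length(b))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ttest_report", class(out))
  out
}

#' Paired two-sample t-test on accuracy vectors
#'
#' Standard paired t-test on the per-session differences, used e.g. to
#' compare 6-filter against 2-filter decoding accuracies over the same
#' sessions.  Zero-variance differences (identical vectors) are flagged
#' as degenerate with an undefined p-value.
#'
#' @param acc_a,acc_b Equal-length numeric vectors (length >= 2).
#' @return A tibble: `t_value`, `p_value`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2) {
    abort("Inputs must have equal length of at least 2.")
  }
  d <- acc_a - acc_b
  if (isTRUE(all.equal(var(d), 0))) {
    warn("Zero-variance differences: paired t-test is degenerate.")
    return(tibble(t_value = NA_real_, p_value = NA_real_,
                  mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(acc_a, acc_b, paired = TRUE)
  tibble(t_value = unname(tt$statistic), p_value = tt$p.value,
         mean_diff = mean(d), degenerate = FALSE)
}
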