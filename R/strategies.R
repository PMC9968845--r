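STRATEGY_NAMES <- c("Prev", "Next", "Best", "Worst", "Closest", "All")

#' Symmetrized Gaussian KL divergence between feature clouds
#'
#' Fits a single multivariate normal (pooled over classes) to each 2-D
#' feature cloud and returns the symmetrized Kullback-Leibler divergence
#' `KL(P||Q) + KL(Q||P)` via the closed multivariate-normal form.
#' Covariances are ridge-regularized when near-singular.
#'
#' @param feats_train,feats_test `feature_set`s (or matrices) with two
#'   feature dimensions and at least 3 trials each.
#' @return A non-negative scalar (0 for identical clouds).
#' @export
kl_divergence <- function(feats_train, feats_test) {
  a <- feature_matrix(feats_train)
  b <- feature_matrix(feats_test)
  if (ncol(a) != 2 || ncol(b) != 2) abort("KL divergence expects 2-D features.")
  if (nrow(a) < 3 || nrow(b) < 3) abort("Need at least 3 trials per cloud.")
  fit <- function(x) {
    s <- stats::cov(x)
    if (rcond(s) < 1e-12) s <- s + 1e-8 * sum(diag(s)) / ncol(x) * diag(ncol(x))
    if (rcond(s) < 1e-12) abort("Singular feature covariance.")
    list(mu = colMeans(x), sigma = s)
  }
  p <- fit(a)
  q <- fit(b)
  gaussian_kl(p$mu, p$sigma, q$mu, q$sigma) +
    gaussian_kl(q$mu, q$sigma, p$mu, p$sigma)
}

# closed-form KL(N(mu1, S1) || N(mu2, S2)) for multivariate normals
gaussian_kl <- function(mu1, s1, mu2, s2) {
  k <- length(mu1)
  s2i <- solve(s2)
  d <- mu2 - mu1
  0.5 * (sum(diag(s2i %*% s1)) + drop(t(d) %*% s2i %*% d) - k +
           determinant(s2)$modulus - determinant(s1)$modulus)[1]
}

#' Select a training set for a target session
#'
#' The six selection rules compared on cross-session and cross-subject
#' decoding tasks:
#' \describe{
#'   \item{Prev / Next}{the session recorded immediately before / after
#'     the target (cross-session tasks only; unavailable at the first /
#'     last session).}
#'   \item{Best / Worst}{the candidate with the highest / lowest
#'     within-session self-test accuracy.}
#'   \item{Closest}{the candidate whose 2-D feature cloud has the
#'     smallest symmetrized Gaussian KL divergence to the target's; for
#'     each candidate, both clouds are extracted with the candidate's own
#'     CSP filters, the space in which its classifier would operate.}
#'   \item{All}{every candidate concatenated.}
#' }
#' Ties are broken toward the lowest session index.
#'
#' @param strategy One of `"Prev"`, `"Next"`, `"Best"`, `"Worst"`,
#'   `"Closest"`, `"All"`.
#' @param target_id Name of the target session in `sessions`.
#' @param sessions Named list of `epoch_set`s, in acquisition order.
#' @param self_test_acc Named numeric of diagonal self-test accuracies
#'   (required for Best/Worst).
#' @param task `"cross-session"` or `"cross-subject"`; Prev/Next are
#'   rejected for cross-subject tasks.
#' @param n_pairs CSP pairs used for the Closest feature extraction.
#' @param cov_sums Optional named list of precomputed per-session class
#'   covariance sums (internal reuse by [evaluate_strategies()]).
#' @return Character vector of selected session ids (length > 1 only for
#'   All), or `NA` when the strategy is unavailable at this target
#'   (Prev at the first session, Next at the last).
#' @export
select_training <- function(strategy, target_id, sessions,
                            self_test_acc = NULL,
                            task = c("cross-session", "cross-subject"),
                            n_pairs = 1, cov_sums = NULL) {
  strategy <- match.arg(strategy, STRATEGY_NAMES)
  task <- match.arg(task)
  ids <- names(sessions)
  stopifnot(length(ids) >= 2, target_id %in% ids)
  if (strategy %in% c("Prev", "Next") && task == "cross-subject") {
    abort("Prev/Next apply to cross-session tasks only.")
  }
  pos <- match(target_id, ids)
  candidates <- setdiff(ids, target_id)
  switch(
    strategy,
    Prev = if (pos == 1) NA_character_ else ids[pos - 1],
    Next = if (pos == length(ids)) NA_character_ else ids[pos + 1],
    Best = {
      stopifnot(!is.null(self_test_acc))
      acc <- self_test_acc[candidates]
      candidates[which.max(acc)]
    },
    Worst = {
      stopifnot(!is.null(self_test_acc))
      acc <- self_test_acc[candidates]
      candidates[which.min(acc)]
    },
    Closest = {
      kl <- vapply(candidates, function(cand) {
        csp <- if (is.null(cov_sums)) {
          fit_csp_epochs(sessions[[cand]], n_pairs = n_pairs)
        } else {
          fit_csp_sums(cov_sums[[cand]], n_pairs = n_pairs,
                       metadata = list(session_id = cand))
        }
        kl_divergence(extract_features(csp, sessions[[cand]]),
                      extract_features(csp, sessions[[target_id]]))
      }, numeric(1))
      candidates[which.min(kl)]
    },
    All = candidates
  )
}

#' Evaluate all training-set selection strategies
#'
#' For each target session and each applicable strategy: select the
#' training set, fit CSP (`n_pairs` filter pairs) and LDA on its trials,
#' and score the target session.  Prev/Next are skipped for cross-subject
#' tasks and marked unavailable (`NA`) at the first/last session of
#' cross-session tasks.
#'
#' @param sessions Named list of `epoch_set`s in acquisition order
#'   (at least 3 for meaningful selection).
#' @param task `"cross-session"` or `"cross-subject"`.
#' @param n_pairs CSP filter pairs (default 1, the 2-D feature space).
#' @return A `strategy_report` tibble: `target`, `strategy`, `training`
#'   (ids collapsed with `+`), `accuracy` (percent, `NA` when
#'   unavailable); strategy means are available via
#'   [summarise_strategies()].
#' @export
evaluate_strategies <- function(sessions, task = c("cross-session",
                                                   "cross-subject"),
                                n_pairs = 1) {
  task <- match.arg(task)
  stopifnot(length(sessions) >= 3)
  ids <- names(sessions)
  strategies <- if (task == "cross-session") STRATEGY_NAMES else {
    setdiff(STRATEGY_NAMES, c("Prev", "Next"))
  }
# per-session covariance sums, computed once and reused by every fit
  cov_sums <- lapply(sessions, class_cov_sums)

  fit_on <- function(chosen) {
    sums <- Reduce(add_cov_sums, cov_sums[chosen])
    csp <- fit_csp_sums(sums, n_pairs = n_pairs,
                        metadata = list(session_id = paste(chosen,
                                                           collapse = "+")))
    train_feats <- dplyr::bind_rows(
      lapply(chosen, function(id) extract_features(csp, sessions[[id]]))
    )
    list(csp = csp, lda = fit_lda(train_feats))
  }

  diag_acc <- vapply(ids, function(id) {
    fit <- fit_on(id)
    f <- extract_features(fit$csp, sessions[[id]])
    accuracy(predict(fit$lda, f), f$label)
  }, numeric(1))

  rows <- list()
  for (target in ids) {
    for (strat in strategies) {
      chosen <- select_training(strat, target, sessions,
                                self_test_acc = diag_acc, task = task,
                                n_pairs = n_pairs, cov_sums = cov_sums)
      if (length(chosen) == 1 && is.na(chosen)) {
        rows[[length(rows) + 1L]] <- tibble(
          target = target, strategy = strat,
          training = NA_character_, accuracy = NA_real_
        )
        next
      }
      fit <- fit_on(chosen)
      ft <- extract_features(fit$csp, sessions[[target]])
      rows[[length(rows) + 1L]] <- tibble(
        target = target, strategy = strat,
        training = paste(chosen, collapse = "+"),
        accuracy = accuracy(predict(fit$lda, ft), ft$label)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$strategy <- factor(out$strategy, levels = STRATEGY_NAMES)
  attr(out, "task") <- task
  attr(out, "self_test_acc") <- diag_acc
  class(out) <- c("strategy_report", class(out))
  out
}

#' @rdname evaluate_strategies
#' @param report A `strategy_report`.
#' @return `summarise_strategies()` returns one row per strategy with the
#'   mean accuracy over available cells.
#' @export
summarise_strategies <- function(report) {
  report |>
    dplyr::group_by(strategy) |>
    dplyr::summarise(
      mean_accuracy = mean(accuracy, na.rm = TRUE),
      n_available = sum(!is.na(accuracy)),
      .groups = "drop"
    )
}
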