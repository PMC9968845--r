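#' Configure an end-to-end study
#'
#' Bundles a cohort design with the analysis settings used by
#' [run_study()]: the CSP pair counts for the 2-D analysis space and the
#' 6-D "online" replay, the classification window, and toggles for the
#' individual analysis stages.
#'
#' @param preset `"exp1"` (multi-subject), `"exp2"` (multi-session) or
#'   `"custom"` (supply `cohort`).
#' @param cohort A [cohort_config()] when `preset = "custom"`; otherwise
#'   built from the preset and `...`.
#' @param seed Study seed, forwarded to the cohort.
#' @param n_pairs_analysis CSP pairs for transfer/strategy analyses
#'   (default 1, the 2-D feature space).
#' @param n_pairs_online CSP pairs for the online replay (default 3).
#' @param window Classification window, imagery-relative seconds.
#' @param with_tfa,with_cross,with_stats,with_strategies,with_replay
#'   Stage toggles.
#' @param ... Overrides forwarded to the preset [cohort_config()].
#' @return A `study_config`.
#' @export
study_config <- function(preset = c("exp1", "exp2", "custom"),
                         cohort = NULL, seed = 1L,
                         n_pairs_analysis = 1, n_pairs_online = 3,
                         window = c(0, 4),
                         with_tfa = TRUE, with_cross = TRUE,
                         with_stats = TRUE, with_strategies = TRUE,
                         with_replay = TRUE, ...) {
  preset <- match.arg(preset)
  cohort <- switch(preset,
    exp1 = exp1_config(seed = seed, ...),
    exp2 = exp2_config(seed = seed, ...),
    custom = {
      if (is.null(cohort)) abort("`preset = \"custom\"` requires `cohort`.")
      cohort$seed <- as.integer(seed)
      cohort
    }
  )
  structure(
    list(
      preset = preset, cohort = cohort, seed = as.integer(seed),
      n_pairs_analysis = n_pairs_analysis, n_pairs_online = n_pairs_online,
      window = window, with_tfa = with_tfa, with_cross = with_cross,
      with_stats = with_stats, with_strategies = with_strategies,
      with_replay = with_replay
    ),
    class = "study_config"
  )
}

#' Run a full study on a synthetic cohort
#'
#' Generates the cohort, preprocesses and epochs every session, and runs
#' the enabled analyses: per-session ERD/ERS table, cross-train/test
#' matrices (one cross-subject matrix for single-session designs, one
#' cross-session matrix per subject otherwise), per-cell feature
#' distribution statistics, training-set selection strategies, and the
#' first-half/second-half online replay at both CSP pair counts.  When
#' `out_dir` is given, every table is written as CSV along with a
#' `manifest.json` listing the configuration and the MD5 checksum of each
#' file; outputs are byte-identical across reruns with the same seed.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory.
#' @return A `study_result` list: `config`, `erd`, `matrices` (named list
#'   of `cross_matrix`), `cell_stats`, `strategies`, `replay`, `manifest`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cohort <- make_cohort(config$cohort)
  epochs <- lapply(cohort, function(rec) {
    rec |> preprocess_session() |> epoch_trials(window = config$window)
  })
  subject_of <- vapply(cohort, `[[`, "", "subject_id")
  cross_session <- config$cohort$n_sessions > 1

  erd <- NULL
  if (config$with_tfa) {
    erd <- dplyr::bind_rows(lapply(cohort, session_erd))
  }

  matrices <- list()
  cell_stats <- NULL
  if (config$with_cross) {
    groups <- if (cross_session) split(names(epochs), subject_of) else {
      list(cohort = names(epochs))
    }
    matrices <- lapply(groups, function(ids) {
      build_cross_matrix(epochs[ids], n_pairs = config$n_pairs_analysis)
    })
    if (config$with_stats) {
      cell_stats <- dplyr::bind_rows(
        lapply(names(matrices), function(g) {
          st <- cross_matrix_stats(matrices[[g]])
          st$group <- g
          st
        })
      )
    }
  }

  strategies <- NULL
  if (config$with_strategies) {
    task <- if (cross_session) "cross-session" else "cross-subject"
    groups <- if (cross_session) split(names(epochs), subject_of) else {
      list(cohort = names(epochs))
    }
    strategies <- dplyr::bind_rows(lapply(names(groups), function(g) {
      rep_g <- evaluate_strategies(epochs[groups[[g]]], task = task,
                                   n_pairs = config$n_pairs_analysis)
      rep_g$group <- g
      as_tibble(rep_g)
    }))
  }

  replay <- NULL
  if (config$with_replay) {
    replay <- dplyr::bind_rows(lapply(names(epochs), function(id) {
      tibble(
        session = id,
        acc_online = replay_online_split(epochs[[id]],
                                         n_pairs = config$n_pairs_online),
        acc_2d = replay_online_split(epochs[[id]],
                                     n_pairs = config$n_pairs_analysis)
      )
    }))
  }

  result <- structure(
    list(config = config, erd = erd, matrices = matrices,
         cell_stats = cell_stats, strategies = strategies, replay = replay,
         manifest = NULL),
    class = "study_result"
  )
  if (!is.null(out_dir)) {
    result$manifest <- write_study(result, out_dir)
  }
  result
}

write_study <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    files[[length(files) + 1]] <<- path
  }
  put(result$erd, "erd.csv")
  for (g in names(result$matrices)) {
    put(tidy(result$matrices[[g]]), sprintf("accuracy_%s.csv", g))
  }
  put(result$cell_stats, "cell_stats.csv")
  put(result$strategies, "strategies.csv")
  put(result$replay, "replay.csv")
  manifest <- list(
    package = "smrbci",
    version = as.character(utils::packageVersion("smrbci")),
    seed = result$config$seed,
    preset = result$config$preset,
    cohort = unclass(result$config$cohort),
    files = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Replay the online train/test split offline
#'
#' Fits CSP+LDA on the first half of the runs and scores the second half,
#' mirroring the online protocol in which the first four of eight runs
#' train the decoder and the last four test it.
#'
#' @param epochs An `epoch_set` with run indices (at least 2 runs).
#' @param n_pairs CSP filter pairs (3 replays the 6-D online decoder, 1
#'   the 2-D offline analysis).
#' @return Test accuracy in percent.
#' @export
replay_online_split <- function(epochs, n_pairs = 3) {
  stopifnot(is_epoch_set(epochs))
  runs <- sort(unique(epochs$runs))
  if (length(runs) < 2) abort("Need at least two runs to split train/test.")
  train_runs <- runs[seq_len(floor(length(runs) / 2))]
  train <- subset_epochs(epochs, epochs$runs %in% train_runs)
  test <- subset_epochs(epochs, !(epochs$runs %in% train_runs))
  csp <- fit_csp_epochs(train, n_pairs = n_pairs)
  lda <- fit_lda(extract_features(csp, train))
  ft <- extract_features(csp, test)
  accuracy(predict(lda, ft), ft$label)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> preset %s, seed %d: %d session(s)\n",
              x$config$preset, x$config$seed,
              x$config$cohort$n_subjects * x$config$cohort$n_sessions))
  for (g in names(x$matrices)) {
    a <- x$matrices[[g]]$acc
    cat(sprintf("  %s: %dx%d matrix, diag %.1f%%, offdiag %.1f%%\n",
                g, nrow(a), ncol(a), mean(diag(a)),
                mean(a[row(a) != col(a)])))
  }
  invisible(x)
}
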