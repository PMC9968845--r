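# Fixtures are generated in code at test time; heavyweight derived results
# are cached per test run so several test blocks can share one computation.

`%||%` <- function(x, y) if (is.null(x)) y else x

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort: 1 subject, 2 runs x 8 trials
tiny_config <- function(seed = 1L, ...) {
  cohort_config(n_subjects = 1, n_runs = 2, trials_per_run = 8,
                seed = seed, ...)
}

# one session with prescribed rhythm parameters (others at nominal values)
param_session <- function(overrides = list(), seed = 1L,
                          n_runs = 2, trials_per_run = 10, ...) {
  cfg <- cohort_config(n_subjects = 1, n_runs = n_runs,
                       trials_per_run = trials_per_run,
                       inter_subject_sd = 0, seed = seed, ...)
  p <- withr::with_seed(seed, draw_subject_params(cfg))
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  withr::with_seed(seed + 1L, synthesize_session(p, cfg))
}

# bare continuous recording around an arbitrary signal matrix
make_rec <- function(data, fs, events = NULL) {
  labels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  rownames(data) <- labels
  structure(
    list(
      data = data, fs = fs, channel_labels = labels,
      events = events %||% tibble::tibble(onset_sample = integer(),
                                          class = character(),
                                          run = integer()),
      subject_id = "subXX", session_id = "sesXX", ground_truth = NULL
    ),
    class = "session_recording"
  )
}

# epoch_set directly from an array (channels x samples x trials)
make_epochs <- function(trials, labels, fs = 250, window = c(0, 4),
                        runs = NULL, session_id = "sesXX") {
  ch <- dimnames(trials)[[1]] %||% paste0("ch", seq_len(dim(trials)[1]))
  dimnames(trials)[[1]] <- ch
  structure(
    list(
      trials = trials, labels = as.integer(labels),
      runs = runs %||% rep(1L, length(labels)),
      time_axis = window[1] + (seq_len(dim(trials)[2]) - 1) / fs,
      fs = fs, window = window, channel_labels = ch,
      subject_id = "subXX", session_id = session_id
    ),
    class = "epoch_set"
  )
}

# toy two-class epochs: class 1 boosts channel 1, class 2 boosts channel 2
toy_epochs <- function(seed = 1, n_per_class = 10, C = 4, T = 120,
                       contrast = 3, fs = 250, session_id = "sesXX") {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c(1L, 2L), each = n_per_class)
    trials <- array(rnorm(C * T * n), dim = c(C, T, n))
    for (i in seq_len(n)) {
      ch <- if (labels[i] == 1L) 1 else 2
      trials[ch, , i] <- trials[ch, , i] * contrast
    }
    make_epochs(trials, labels, fs = fs,
                runs = rep(rep(1:2, each = n_per_class / 2), 2),
                session_id = session_id)
  })
}

random_spd <- function(C, seed = NULL) {
  gen <- function() {
    a <- matrix(rnorm(C * C), C)
    s <- crossprod(a) + 0.1 * diag(C)
    s / sum(diag(s))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# size-scaled study cohorts used by the heavier end-to-end checks:
# the 8-subject multi-subject design vs the 2-subject x 10-session
# multi-session design, at 4 runs x 24 trials per session and a short
# inter-trial rest (the paradigm leaves the rest duration free)
scaled_cohort_config <- function(kind = c("exp1", "exp2"), seed) {
  kind <- match.arg(kind)
  if (kind == "exp1") {
    cohort_config(n_subjects = 8, n_sessions = 1, n_runs = 4,
                  trials_per_run = 24, rest_s = 2, seed = seed)
  } else {
    cohort_config(n_subjects = 2, n_sessions = 10, n_runs = 4,
                  trials_per_run = 24, rest_s = 2, seed = seed)
  }
}

preprocessed_epochs <- function(config) {
  cohort <- make_cohort(config)
  eps <- lapply(cohort, function(r) {
    r |> preprocess_session() |> epoch_trials(window = c(0, 4))
  })
  attr(eps, "subject_of") <- vapply(cohort, `[[`, "", "subject_id")
  eps
}

# Per-seed replicate of the two study designs, reduced to the small tables
# the acceptance checks need (epoch arrays are discarded to bound memory).
replicate_analysis <- function(seed) {
  ep1 <- preprocessed_epochs(scaled_cohort_config("exp1", seed))
  m1 <- build_cross_matrix(ep1, n_pairs = 1)
  stats1 <- cross_matrix_stats(m1)
  strat1 <- evaluate_strategies(ep1, task = "cross-subject", n_pairs = 1)
  rm(ep1)

  ep2 <- preprocessed_epochs(scaled_cohort_config("exp2", seed))
  subj <- attr(ep2, "subject_of")
  stats2 <- list()
  strat2 <- list()
  for (s in unique(subj)) {
    eps_s <- ep2[subj == s]
    m2 <- build_cross_matrix(eps_s, n_pairs = 1)
    stats2[[s]] <- cross_matrix_stats(m2)
    strat2[[s]] <- evaluate_strategies(eps_s, task = "cross-session",
                                       n_pairs = 1)
  }
  rm(ep2)
  list(
    stats_exp1 = stats1,
    stats_exp2 = dplyr::bind_rows(stats2),
    strat_exp1 = summarise_strategies(strat1),
    strat_exp2 = dplyr::bind_rows(lapply(strat2, as.data.frame)) |>
      dplyr::group_by(strategy) |>
      dplyr::summarise(mean_accuracy = mean(accuracy, na.rm = TRUE),
                       .groups = "drop")
  )
}

acceptance_replicates <- function() {
  cached("acceptance_replicates", lapply(101:110, replicate_analysis))
}
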