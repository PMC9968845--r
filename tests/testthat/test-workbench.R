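small_study <- function(seed = 71) {
  study_config(
    preset = "custom",
    cohort = cohort_config(n_subjects = 3, n_sessions = 1, n_runs = 2,
                           trials_per_run = 8, seed = seed),
    seed = seed, with_tfa = FALSE
  )
}

test_that("run_study produces the expected artifacts and manifest", {
  out <- file.path(withr::local_tempdir(), "study")
  res <- run_study(small_study(), out_dir = out)
  expect_s3_class(res, "study_result")
  expect_named(res$matrices, "cohort")
  expect_equal(dim(res$matrices$cohort$acc), c(3, 3))
  expect_true(file.exists(file.path(out, "accuracy_cohort.csv")))
  expect_true(file.exists(file.path(out, "cell_stats.csv")))
  expect_true(file.exists(file.path(out, "strategies.csv")))
  expect_true(file.exists(file.path(out, "replay.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 71)
  # every listed file carries a checksum that matches the file on disk
  for (k in seq_len(nrow(man$files))) {
    f <- file.path(out, man$files$file[k])
    expect_true(file.exists(f))
    expect_equal(unname(tools::md5sum(f)), man$files$md5[k])
  }
})

test_that("identical seeds reproduce byte-identical outputs", {
  base <- withr::local_tempdir()
  run_study(small_study(), out_dir = file.path(base, "a"))
  run_study(small_study(), out_dir = file.path(base, "b"))
  run_study(small_study(seed = 72), out_dir = file.path(base, "c"))
  for (f in list.files(file.path(base, "a"))) {
    expect_equal(unname(tools::md5sum(file.path(base, "a", f))),
                 unname(tools::md5sum(file.path(base, "b", f))),
                 label = f)
  }
  expect_false(
    unname(tools::md5sum(file.path(base, "a", "accuracy_cohort.csv"))) ==
      unname(tools::md5sum(file.path(base, "c", "accuracy_cohort.csv")))
  )
})

test_that("multi-session designs yield one matrix and strategy set per subject", {
  cfg <- study_config(
    preset = "custom",
    cohort = cohort_config(n_subjects = 2, n_sessions = 3, n_runs = 2,
                           trials_per_run = 8, seed = 73),
    seed = 73, with_tfa = FALSE
  )
  res <- run_study(cfg)
  expect_named(res$matrices, c("sub01", "sub02"))
  expect_equal(dim(res$matrices$sub01$acc), c(3, 3))
  expect_setequal(unique(res$strategies$group), c("sub01", "sub02"))
  expect_true(all(c("Prev", "Next") %in% as.character(res$strategies$strategy)))
})

test_that("presets yield one 8x8 grid and two 10x10 grids of accuracies", {
  cfg1 <- study_config("exp1", seed = 91, n_runs = 2, trials_per_run = 8,
                       with_tfa = FALSE, with_strategies = FALSE,
                       with_replay = FALSE)
  res1 <- run_study(cfg1)
  expect_length(res1$matrices, 1)
  expect_equal(dim(res1$matrices[[1]]$acc), c(8, 8))
  expect_equal(sum(!is.na(res1$matrices[[1]]$acc)), 64)

  cfg2 <- study_config("exp2", seed = 92, n_runs = 2, trials_per_run = 8,
                       with_tfa = FALSE, with_strategies = FALSE,
                       with_replay = FALSE)
  res2 <- run_study(cfg2)
  expect_length(res2$matrices, 2)
  expect_true(all(vapply(res2$matrices, function(m) {
    all(dim(m$acc) == c(10, 10))
  }, logical(1))))
})

test_that("study presets encode the two experimental designs", {
  s1 <- study_config("exp1", seed = 5)
  expect_equal(s1$cohort$n_subjects, 8)
  expect_equal(s1$cohort$n_sessions, 1)
  s2 <- study_config("exp2", seed = 5)
  expect_equal(s2$cohort$n_subjects, 2)
  expect_equal(s2$cohort$n_sessions, 10)
  expect_error(study_config("custom"), "requires")
})

test_that("the online replay splits runs in half and wires both widths", {
  ep <- toy_epochs(seed = 74, n_per_class = 16)  # runs 1-2 per class pattern
  ep$runs <- rep(1:4, 8)
  acc6 <- replay_online_split(ep, n_pairs = 2)
  acc2 <- replay_online_split(ep, n_pairs = 1)
  expect_true(acc6 >= 0 && acc6 <= 100)
  # strongly contrasted toy classes transfer across halves
  expect_gte(acc2, 90)

  single <- ep
  single$runs <- rep(1L, n_trials(ep))
  expect_error(replay_online_split(single), "two runs")

  # paired comparison across sessions is wired through paired_ttest;
  # weaker contrast keeps accuracies off the 100% ceiling
  accs <- vapply(1:4, function(i) {
    e <- toy_epochs(seed = 80 + i, n_per_class = 16, contrast = 1.12)
    e$runs <- rep(1:4, 8)
    c(replay_online_split(e, n_pairs = 2), replay_online_split(e, n_pairs = 1))
  }, numeric(2))
  expect_true(any(accs[1, ] != accs[2, ]))
  res <- paired_ttest(accs[1, ], accs[2, ])
  expect_true(is.finite(res$p_value))
})

test_that("tidiers and plots summarise fitted objects", {
  ep <- toy_epochs(seed = 75, n_per_class = 10)
  m <- fit_csp_epochs(ep, n_pairs = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 4)
  expect_setequal(unique(td$rank), c("top", "bottom"))
  expect_equal(glance(m)$lambda_max, max(m$eigenvalues))

  f <- extract_features(m, ep)
  lda <- fit_lda(f)
  expect_equal(nrow(tidy(lda)), 3)
  expect_equal(glance(lda)$n1, 10)

  cm <- build_cross_matrix(list(a = ep, b = toy_epochs(seed = 76)),
                           n_pairs = 1)
  expect_equal(glance(cm)$n_sessions, 2)

  p1 <- autoplot(cm)
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(f)
  expect_s3_class(p2, "ggplot")
  tfr <- wavelet_tfr(toy_epochs(seed = 77), freqs = c(10, 20), trim_s = 0.1)
  expect_s3_class(autoplot(tfr), "ggplot")
  rep <- evaluate_strategies(list(s1 = ep, s2 = toy_epochs(seed = 78),
                                  s3 = toy_epochs(seed = 79)),
                             task = "cross-subject")
  expect_s3_class(plot_strategies(rep), "ggplot")
})
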