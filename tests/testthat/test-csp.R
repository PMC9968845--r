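test_that("trial covariance is the unit-trace spatial covariance", {
  # orthogonal equal-power rows: covariance is I/C
  x <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1)) * 3
  expect_equal(trial_covariance(x), diag(2) / 2)

  withr::with_seed(1, {
    r <- matrix(rnorm(5 * 100), 5)
  })
  s <- trial_covariance(r)
  expect_equal(sum(diag(s)), 1)
  expect_equal(s, t(s))
  expect_true(all(eigen(s, symmetric = TRUE)$values > -1e-12))

  expect_error(trial_covariance(matrix(0, 3, 50)), "zero")
  expect_error(trial_covariance(matrix(1, 5, 4)), "more samples")
})

test_that("class-mean covariances are plain arithmetic means", {
  withr::with_seed(2, {
    covs <- lapply(1:6, function(i) random_spd(4))
  })
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L)
  cm <- class_mean_covariances(covs, labels)
  expect_equal(cm$left, (covs[[1]] + covs[[2]] + covs[[3]]) / 3)
  expect_equal(cm$right, (covs[[4]] + covs[[5]] + covs[[6]]) / 3)

  # single trial per class: mean is the trial itself
  cm1 <- class_mean_covariances(covs[c(1, 4)], c(1L, 2L))
  expect_equal(cm1$left, covs[[1]])

  # duplication leaves the mean unchanged
  cm2 <- class_mean_covariances(c(covs, covs), rep(labels, 2))
  expect_equal(cm2$left, cm$left)

  expect_error(class_mean_covariances(covs[1:3], c(1L, 1L, 1L)), "Both classes")
})

test_that("fit_csp solves the generalized eigenvalue problem", {
  # identical classes: all eigenvalues 1
  s <- random_spd(6, seed = 3)
  m_id <- fit_csp(s, s, n_pairs = 2)
  expect_equal(m_id$eigenvalues, rep(1, 4), tolerance = 1e-10)

  # 2x2 closed form: diagonal covariances give axis-aligned filters
  m2 <- fit_csp(diag(c(1, 4)) / 5, diag(c(4, 1)) / 5, n_pairs = 1)
  expect_equal(sort(m2$eigenvalues), c(1 / 4, 4), tolerance = 1e-10)
  expect_equal(unname(abs(m2$filters)), diag(2), tolerance = 1e-8)

  # residual of the generalized eigen equation
  withr::with_seed(4, {
    for (C in c(4, 8, 20)) {
      sl <- random_spd(C)
      sr <- random_spd(C)
      m <- fit_csp(sl, sr, n_pairs = 2)
      for (k in seq_along(m$eigenvalues)) {
        w <- m$filters[, k]
        resid <- sr %*% w - m$eigenvalues[k] * (sl %*% w)
        expect_lt(sqrt(sum(resid^2)), 1e-8 * sqrt(sum(w^2)))
      }
      # brute-force dense solve as the independent oracle
      all_l <- sort(Re(eigen(solve(sl) %*% sr)$values))
      expect_equal(sort(m$eigenvalues), c(head(all_l, 2), tail(all_l, 2)),
                   tolerance = 1e-8)
    }
  })

  expect_error(fit_csp(random_spd(4, 5), random_spd(4, 6), n_pairs = 3),
               "half the channel count")
})

test_that("class swap inverts eigenvalues and mirrors filter selection", {
  sl <- random_spd(6, seed = 7)
  sr <- random_spd(6, seed = 8)
  m <- fit_csp(sl, sr, n_pairs = 3)
  m_swap <- fit_csp(sr, sl, n_pairs = 3)
  expect_equal(sort(m_swap$eigenvalues), sort(1 / m$eigenvalues),
               tolerance = 1e-8)
  # the top filters of one problem span the bottom filters of the other
  align <- abs(crossprod(m$filters[, 1:3], m_swap$filters[, 4:6]))
  expect_equal(unname(sort(apply(align, 1, max))), rep(1, 3),
               tolerance = 1e-6)
})

test_that("features are log variances of the projected trials", {
  ep <- toy_epochs(seed = 11, n_per_class = 10)
  m3 <- fit_csp_epochs(ep, n_pairs = 2)
  f3 <- extract_features(m3, ep)
  expect_equal(sum(grepl("^f[0-9]+$", names(f3))), 4)

  m1 <- fit_csp_epochs(ep, n_pairs = 1)
  f1 <- extract_features(m1, ep)
  expect_equal(sum(grepl("^f[0-9]+$", names(f1))), 2)

  # doubling a trial's amplitude adds log 4 to every feature
  ep2 <- ep
  ep2$trials <- ep2$trials * 2
  f1s <- extract_features(m1, ep2)
  expect_equal(f1s$f1, f1$f1 + log(4), tolerance = 1e-10)
  expect_equal(f1s$f2, f1$f2 + log(4), tolerance = 1e-10)

  # zero-variance projection is an error
  ep0 <- ep
  ep0$trials[] <- 0
  expect_error(extract_features(m1, ep0), "Zero-variance")
})

test_that("CSP+LDA self-test separates strongly contrasted classes", {
  ep <- toy_epochs(seed = 12, n_per_class = 20, contrast = 3)
  m <- fit_csp_epochs(ep, n_pairs = 1)
  f <- extract_features(m, ep)
  acc <- accuracy(predict(fit_lda(f), f), f$label)
  expect_gte(acc, 95)

  # class means separate along opposite feature dimensions
  mu1 <- colMeans(f[f$label == 1L, c("f1", "f2")])
  mu2 <- colMeans(f[f$label == 2L, c("f1", "f2")])
  expect_gt((mu2["f1"] - mu1["f1"]) * (mu1["f2"] - mu2["f2"]), 0)
})

test_that("rescaling a spatial filter leaves downstream LDA unchanged", {
  ep <- toy_epochs(seed = 13, n_per_class = 12)
  m <- fit_csp_epochs(ep, n_pairs = 1)
  m_scaled <- m
  m_scaled$filters[, 1] <- 5 * m_scaled$filters[, 1]
  f <- extract_features(m, ep)
  fs <- extract_features(m_scaled, ep)
  p1 <- predict(fit_lda(f), f)
  p2 <- predict(fit_lda(fs), fs)
  expect_identical(p1, p2)
})
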