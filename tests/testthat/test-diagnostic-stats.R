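test_that("adjudication reproduces the questionnaire rows", {
  # software agrees with both
  r <- adjudicate(data.frame(label_a = 1, label_b = 1, software = 1))
  expect_equal(r$status, "concordant")
  expect_equal(r$consensus, 1L)
  # software disagrees with both (who agree)
  r <- adjudicate(data.frame(label_a = 1, label_b = 1, software = 2))
  expect_equal(r$status, "discordant")
  expect_equal(r$consensus, 1L)
  # third rater sides with the software
  r <- adjudicate(data.frame(label_a = 1, label_b = 2, software = 1, label_c = 1))
  expect_equal(r$status, "partial-congruent")
  expect_equal(r$consensus, 1L)
  # third rater sides against the software
  r <- adjudicate(data.frame(label_a = 1, label_b = 2, software = 1, label_c = 2))
  expect_equal(r$status, "discordant")
  expect_equal(r$consensus, 2L)
  # partial concordance without the required third label is an error
  expect_error(
    adjudicate(data.frame(label_a = 1, label_b = 2, software = 1)),
    "label_c required"
  )
  # three-way disagreement where C matches neither: no consensus
  r <- adjudicate(data.frame(label_a = 1, label_b = 2, software = 3, label_c = 4))
  expect_equal(r$status, "discordant")
  expect_true(is.na(r$consensus))
})

test_that("observed agreement is the percent of identical positions", {
  expect_equal(observed_agreement(1:5, 1:5), 100)
  expect_equal(observed_agreement(c(1, 2, 3, 4), c(1, 2, 3, 0)), 75)
  x <- c(rep(1, 287), rep(2, 57))
  y <- c(rep(1, 287), rep(3, 57))
  expect_equal(round(observed_agreement(x, y), 1), 83.4)
  expect_error(observed_agreement(1:3, 1:4), "equal length")
})

test_that("Cohen's kappa matches hand and library oracles", {
  # perfect agreement with >= 2 categories
  k <- cohen_kappa(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(k$kappa, 1)

  # 2x2 table (40, 10, 10, 40): po 0.8, pe 0.5, kappa 0.6
  x <- c(rep(1, 50), rep(2, 50))
  y <- c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40))
  k <- cohen_kappa(x, y)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$observed_agreement, 80)
  expect_lt(k$p_value, 1e-6)
  expect_true(k$ci[1] < 0.6 && 0.6 < k$ci[2])

  # cross-check the point estimate against an independent implementation
  skip_if_not_installed("e1071")
  set.seed(9)
  for (i in 1:5) {
    a <- sample(0:4, 300, replace = TRUE)
    b <- ifelse(runif(300) < 0.6, a, sample(0:4, 300, replace = TRUE))
    ours <- cohen_kappa(a, b)$kappa
    theirs <- e1071::classAgreement(table(a, b))$kappa
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("kappa is invariant under relabeling and ~0 for independent labels", {
  set.seed(21)
  a <- sample(0:8, 400, replace = TRUE)
  b <- ifelse(runif(400) < 0.5, a, sample(0:8, 400, replace = TRUE))
  perm <- sample(0:8)
  k1 <- cohen_kappa(a, b)$kappa
  k2 <- cohen_kappa(perm[a + 1], perm[b + 1])$kappa
  expect_equal(k1, k2)

  set.seed(22)
  x <- sample(0:3, 5000, replace = TRUE)
  y <- sample(0:3, 5000, replace = TRUE)
  expect_equal(cohen_kappa(x, y)$kappa, 0, tolerance = 0.05)

  # degenerate single-category input: not calculable
  expect_true(is.na(cohen_kappa(rep(1, 10), rep(1, 10))$kappa))
})

test_that("Wilson intervals reproduce printed confidence limits", {
  expect_equal(round(unlist(wilson_interval(31, 34)[, c("low", "high")]), 1),
    c(low = 77.0, high = 97.0)
  )
  expect_equal(round(unlist(wilson_interval(310, 310)[, c("low", "high")]), 1),
    c(low = 98.8, high = 100.0)
  )
  expect_equal(round(unlist(wilson_interval(11, 18)[, c("low", "high")]), 1),
    c(low = 38.6, high = 79.7)
  )
  expect_error(wilson_interval(5, 0), "n must be")
  expect_error(wilson_interval(5, 4), "successes")
})

test_that("Wilson interval agrees with prop.test and swaps symmetrically", {
  cases <- list(c(3, 10), c(0, 25), c(25, 25), c(54, 60), c(276, 284))
  for (cs in cases) {
    ours <- wilson_interval(cs[1], cs[2])
    ref <- stats::prop.test(cs[1], cs[2], correct = FALSE)$conf.int
    expect_equal(c(ours$low, ours$high) / 100, as.numeric(ref), tolerance = 1e-9)
    # success/failure swap equivariance
    swapped <- wilson_interval(cs[2] - cs[1], cs[2])
    expect_equal(c(ours$low, ours$high), 100 - c(swapped$high, swapped$low),
      tolerance = 1e-9
    )
  }
})

test_that("one-vs-rest counts reconstruct per-category tables", {
  expect_equal(
    one_vs_rest_counts(c(1, 1, 2, 3), c(1, 1, 2, 3), 1),
    tibble::tibble(tp = 2L, fp = 0L, fn = 0L, tn = 2L)
  )
  lab <- build_labels(31, 0, 3, 310, k = 1L)
  expect_equal(
    one_vs_rest_counts(lab$reference, lab$software, 1L),
    tibble::tibble(tp = 31L, fp = 0L, fn = 3L, tn = 310L)
  )
  lab <- build_labels(25, 1, 8, 310, k = 3L)
  expect_equal(
    one_vs_rest_counts(lab$reference, lab$software, 3L),
    tibble::tibble(tp = 25L, fp = 1L, fn = 8L, tn = 310L)
  )
})

test_that("accuracy statistics and predictive values follow their definitions", {
  s <- accuracy_stats(54, 8, 6, 276)
  expect_equal(round(s$sensitivity, 1), 90.0)
  expect_equal(round(s$specificity, 1), 97.2)
  expect_equal(round(s$accuracy, 1), 95.9)
  expect_equal(round(s$ppv, 1), 87.1)
  expect_equal(round(s$npv, 1), 97.9)
  expect_equal(round(s$prevalence, 1), 17.4)

  # empty positive class: sensitivity not calculable, specificity fine
  z <- accuracy_stats(0, 0, 0, 10)
  expect_true(is.na(z$sensitivity))
  expect_equal(z$specificity, 100)

  # PPV/NPV from counts equal the Bayes form on random tables
  set.seed(5)
  for (i in 1:20) {
    cts <- rmultinom(1, 500, prob = runif(4, 0.05, 1))
    tp <- cts[1]
    fp <- cts[2]
    fn <- cts[3]
    tn <- cts[4]
    s <- accuracy_stats(tp, fp, fn, tn)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    prev <- (tp + fn) / sum(cts)
    bayes_ppv <- 100 * sens * prev / (sens * prev + (1 - spec) * (1 - prev))
    bayes_npv <- 100 * spec * (1 - prev) /
      (spec * (1 - prev) + (1 - sens) * prev)
    expect_equal(s$ppv, bayes_ppv, tolerance = 1e-10)
    expect_equal(s$npv, bayes_npv, tolerance = 1e-10)
  }
})

test_that("likelihood ratios use unrounded intermediates and NA conventions", {
  lr <- likelihood_ratios(54, 8, 6, 276)
  expect_equal(round(lr$lr_positive, 1), 32.0)
  expect_equal(round(lr$lr_inverse_negative, 1), 9.7)
  expect_equal(round(lr$lr_negative, 1), 0.1)

  expect_equal(round(likelihood_ratios(25, 1, 8, 310)$lr_positive, 1), 235.6)

  # no false positives: LR+ not calculable
  expect_true(is.na(likelihood_ratios(31, 0, 3, 310)$lr_positive))
  # no false negatives: inverse LR- not calculable
  expect_true(is.na(likelihood_ratios(31, 2, 0, 310)$lr_inverse_negative))
})

test_that("sensitivity x positives reconstructs integer counts", {
  rows <- list(
    c(54, 8, 6, 276), c(31, 0, 3, 310), c(11, 0, 7, 326), c(25, 1, 8, 310)
  )
  for (r in rows) {
    s <- accuracy_stats(r[1], r[2], r[3], r[4])
    expect_equal(round(s$sensitivity / 100 * (r[1] + r[3])), r[1])
    expect_equal(round(s$specificity / 100 * (r[2] + r[4])), r[4])
  }
})
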