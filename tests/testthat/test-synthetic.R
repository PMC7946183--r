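test_that("generated samples carry their requested category with full fidelity", {
  set.seed(101)
  for (k in 0:8) {
    s <- simulate_abg_samples(k, n = 30)
    codes <- abg_classify(s)$category_code
    expect_true(all(codes == k), label = sprintf("category %d fidelity", k))
  }
})

test_that("generated triples are Henderson-consistent at the default tolerance", {
  set.seed(102)
  for (k in 0:8) {
    s <- simulate_abg_samples(k, n = 25)
    cons <- check_internal_consistency(s)
    expect_true(all(cons$consistent), label = sprintf("category %d", k))
  }
})

test_that("respiratory acidosis draws satisfy the category geometry", {
  set.seed(103)
  s <- simulate_abg_samples(2, n = 200)
  expect_true(all(s$pco2 > 45))
  expect_true(all(s$ph < 7.35))
})

test_that("the inconsistent-sample flag produces Henderson violations", {
  set.seed(104)
  s <- simulate_abg_samples(0, n = 40, inconsistent = TRUE)
  cons <- check_internal_consistency(s)
  expect_gt(mean(!cons$consistent), 0.9)
})

test_that("cohort generation is deterministic in the seed", {
  a <- generate_cohort(abg_cohort_spec(n_samples = 40, seed = 7))
  b <- generate_cohort(abg_cohort_spec(n_samples = 40, seed = 7))
  expect_identical(a$samples, b$samples)
  expect_identical(a$raters, b$raters)
  c2 <- generate_cohort(abg_cohort_spec(n_samples = 40, seed = 8))
  expect_false(identical(a$samples, c2$samples))
})

test_that("cohort files round-trip through the CSV readers", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(abg_cohort_spec(n_samples = 12, seed = 5),
    output_dir = dir
  )
  expect_true(file.exists(file.path(dir, "samples.csv")))
  back <- read_abg_csv(file.path(dir, "samples.csv"))
  orig <- as_abg_tbl(dplyr::select(cohort$samples, -"true_category"))
  expect_equal(as.data.frame(back), as.data.frame(orig))
  raters <- readr::read_csv(file.path(dir, "raters.csv"),
    show_col_types = FALSE
  )
  expect_equal(nrow(raters), 12)
})

test_that("category counts track the multinomial design prevalences", {
  cohort <- generate_cohort(abg_cohort_spec(n_samples = 346, seed = 31))
  counts <- table(factor(cohort$truth$true_category, levels = 0:8))
  expected <- 346 * abg_cohort_spec()$prevalences
  # each within 4 SDs of its binomial expectation
  sds <- sqrt(expected * (1 - abg_cohort_spec()$prevalences))
  expect_true(all(abs(counts - expected) <= 4 * sds + 1))
})

test_that("cohort marginals resemble the study's medians", {
  cohort <- generate_cohort(abg_cohort_spec(n_samples = 400, seed = 19))
  s <- cohort$samples
  expect_gt(median(s$ph), 7.34)
  expect_lt(median(s$ph), 7.46)
  expect_gt(median(s$pco2), 35)
  expect_lt(median(s$pco2), 43)
  expect_gt(median(s$hco3), 21.2)
  expect_lt(median(s$hco3), 27.9)
})

test_that("perfect raters yield full concordance; rater C appears only when required", {
  set.seed(55)
  spec <- abg_cohort_spec(rater_accuracy = c(a = 1, b = 1, c = 1))
  labels <- sample(0:8, 60, replace = TRUE)
  recs <- simulate_raters(labels, spec)
  adj <- adjudicate(recs)
  expect_true(all(adj$status == "concordant"))
  expect_true(all(is.na(recs$label_c)))

  spec2 <- abg_cohort_spec(rater_accuracy = c(a = 0.6, b = 0.6, c = 0.9))
  recs2 <- simulate_raters(sample(0:8, 400, replace = TRUE), spec2)
  partial <- (recs2$software == recs2$label_a) != (recs2$software == recs2$label_b)
  expect_equal(!is.na(recs2$label_c), partial)
})

test_that("two-rater observed agreement matches the closed-form chance level", {
  # accuracy p, uniform kernel over the other 8 of 9 codes, uniform truth:
  # agree if both right (p^2) or both wrong on the same label ((1-p)^2/8)
  set.seed(77)
  p <- 0.5
  spec <- abg_cohort_spec(rater_accuracy = c(a = p, b = p, c = p))
  labels <- sample(0:8, 6000, replace = TRUE)
  recs <- simulate_raters(labels, spec)
  expected <- p^2 + (1 - p)^2 / 8
  expect_equal(mean(recs$label_a == recs$label_b), expected, tolerance = 0.05)
})
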