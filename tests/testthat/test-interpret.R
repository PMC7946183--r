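test_that("the full pipeline composes all four stages on the median record", {
  d <- median_sample()
  d$mechanically_ventilated <- TRUE
  d$peep <- 5
  rep <- abg_interpret(d)
  expect_equal(rep$category_code, 0L)
  expect_equal(rep$pf_ratio, 265)
  expect_equal(rep$ards_band, "mild")
  expect_equal(rep$bcr_pattern, "prerenal")
  expect_true(rep$consistent)
  expect_equal(rep$n_alerts, 0L)
  for (section in c("Safety", "Oxygenation", "Acid-base", "Renal")) {
    expect_match(rep$rendered_text, section)
  }
  # deterministic rendering
  expect_identical(rep$rendered_text, abg_interpret(d)$rendered_text)
})

test_that("missing biochemistry degrades to not-assessable, never omission", {
  rep <- abg_interpret(data.frame(ph = 7.30, pco2 = 30, hco3 = 14))
  expect_equal(rep$category_code, 3L)
  expect_equal(rep$gap_status, "not-assessed")
  expect_equal(rep$bcr_pattern, "not-assessable")
  expect_equal(rep$ards_band, "not-assessable")
  expect_match(rep$rendered_text, "not assessable")
})

test_that("batch interpretation preserves order and is row-wise identical", {
  set.seed(33)
  cohort <- generate_cohort(abg_cohort_spec(n_samples = 25, seed = 33))
  batch <- abg_interpret(cohort$samples)
  expect_equal(batch$sample_id, cohort$samples$sample_id)
  single <- abg_interpret(cohort$samples[10, ])
  expect_equal(batch$category_code[10], single$category_code)
  expect_equal(batch$rendered_text[10], single$rendered_text)
})

test_that("an inconsistent sample is still classified but flagged for caution", {
  rep <- abg_interpret(data.frame(ph = 7.20, pco2 = 40, hco3 = 24))
  expect_false(rep$consistent)
  expect_true(rep$interpret_with_caution)
  expect_true(rep$category_code %in% 0:8)
  expect_match(rep$rendered_text, "interpret with caution")
})

test_that("JSON report serializes with stable stage keys", {
  d <- median_sample()
  rep <- abg_interpret(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 1)
  expect_named(
    parsed[[1]],
    c("sample_id", "safety", "oxygenation", "acid_base", "renal", "rendered_text")
  )
  expect_equal(parsed[[1]]$acid_base$category_code, 0)
  expect_equal(parsed[[1]]$safety$consistent, TRUE)
})

test_that("run_validation produces the study-shaped tables and files", {
  cohort <- generate_cohort(abg_cohort_spec(
    n_samples = 120, seed = 2,
    rater_accuracy = c(a = 1, b = 1, c = 1)
  ))
  dir <- withr::local_tempdir()
  res <- run_validation(cohort$raters, output_dir = dir)
  # perfect raters + perfect software: kappa 1 and all sensitivities 100
  expect_equal(res$agreement$comparisons$consensus$kappa, 1)
  acc <- tibble::as_tibble(res$accuracy)
  expect_true(all(acc$sensitivity == 100))
  expect_true(all(acc$specificity == 100))
  for (f in c(
    "agreement.csv", "accuracy.csv", "likelihood_ratios.csv",
    "predictive_values.csv", "validation.json"
  )) {
    expect_true(file.exists(file.path(dir, f)), label = f)
  }
  agr_csv <- readr::read_csv(file.path(dir, "agreement.csv"),
    show_col_types = FALSE
  )
  expect_equal(agr_csv$comparison, c("clinician_a", "clinician_b", "consensus"))

  # a CSV path is accepted as input too
  res2 <- run_validation(file.path(dir, "..", "raters_does_not_exist.csv")) |>
    try(silent = TRUE)
  expect_s3_class(res2, "try-error")
})

test_that("imperfect raters still yield a valid agreement analysis", {
  cohort <- generate_cohort(abg_cohort_spec(n_samples = 200, seed = 13))
  res <- run_validation(cohort$raters)
  td <- tidy(res$agreement)
  expect_equal(nrow(td), 3)
  expect_true(all(td$kappa > 0.5 & td$kappa <= 1))
  expect_true(all(td$conf.low <= td$kappa & td$kappa <= td$conf.high))
  g <- glance(res$agreement)
  expect_equal(
    g$concordant + g$partial_congruent + g$discordant,
    nrow(res$agreement$records)
  )
})

test_that("tidy and autoplot work on accuracy objects", {
  cohort <- generate_cohort(abg_cohort_spec(n_samples = 150, seed = 4))
  res <- run_validation(cohort$raters)
  long <- tidy(res$accuracy)
  expect_true(all(c("category", "statistic", "estimate", "low", "high")
  %in% names(long)))
  expect_true(all(long$low <= long$estimate + 1e-9, na.rm = TRUE))
  expect_true(all(long$estimate <= long$high + 1e-9, na.rm = TRUE))
  p <- autoplot(res$accuracy)
  expect_s3_class(p, "ggplot")
})
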