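test_that("direction logic yields the expected primary-disorder candidates", {
  expect_equal(primary_disorders(7.41, 39, 24.9, 0.05)[[1]], character())
  expect_equal(
    primary_disorders(7.30, 60, 28, 2.5)[[1]],
    "respiratory acidosis"
  )
  expect_equal(
    primary_disorders(7.50, 30, 23, 0)[[1]],
    "respiratory alkalosis"
  )
  expect_setequal(
    primary_disorders(7.25, 50, 18)[[1]],
    c("respiratory acidosis", "metabolic acidosis")
  )
  # normal pH, opposing abnormalities: both mixed candidates
  expect_setequal(
    primary_disorders(7.40, 50, 31)[[1]],
    c("respiratory acidosis", "metabolic alkalosis")
  )
})

test_that("expected compensation bands match the bedside rules", {
  expect_equal(expected_compensation("metabolic acidosis", hco3 = 14), c(27, 31))
  expect_equal(
    expected_compensation("respiratory acidosis", pco2 = 60, chronicity = "acute"),
    c(24, 28)
  )
  expect_equal(
    expected_compensation("respiratory acidosis", pco2 = 60, chronicity = "chronic"),
    c(29, 33)
  )
  expect_equal(
    expected_compensation("metabolic alkalosis", hco3 = 24), c(35, 45)
  )
  expect_equal(
    expected_compensation("respiratory alkalosis", pco2 = 20, chronicity = "chronic"),
    c(14, 18)
  )
  expect_error(expected_compensation("renal acidosis", hco3 = 10), "unknown")
})

test_that("anion gap, albumin correction and delta ratio are exact arithmetic", {
  expect_equal(anion_gap(139, 107, 24.9), 7.1)
  expect_equal(anion_gap(140, 104, 24), 12.0)
  expect_equal(anion_gap(140, 100, 10), 30.0)
  expect_true(is.na(anion_gap(NA, 104, 24)))

  expect_equal(corrected_anion_gap(7.1, 2.2), 11.6)
  expect_equal(corrected_anion_gap(12, 4.0), 12.0)
  expect_equal(corrected_anion_gap(10, 3.0), 12.5)
  expect_equal(corrected_anion_gap(10, 5.0), 10.0) # never corrected downward

  expect_equal(delta_ratio(24, 12), 1.0)
  expect_equal(delta_ratio(20, 20), 2.0)
  expect_equal(round(delta_ratio(24, 12, baseline_ag = 16), 3), 0.667)
  expect_true(is.na(delta_ratio(24, 24))) # HCO3 at baseline: not assessable
})

test_that("classification reproduces the worked examples", {
  expect_equal(abg_classify(median_sample())$category_code, 0L)
  expect_equal(
    abg_classify(median_sample())$category_label,
    "Normal acid-base status"
  )

  m <- abg_classify(data.frame(
    ph = 7.25, pco2 = 29, hco3 = 14, na = 140, cl = 104, albumin = 4
  ))
  expect_equal(m$category_code, 3L)
  expect_equal(m$gap_status, "high-gap")
  expect_equal(m$compensation_status, "appropriate")
  expect_equal(m$anion_gap, 22)

  expect_equal(
    abg_classify(data.frame(ph = 7.20, pco2 = 60, hco3 = 23))$category_code,
    6L
  )
  expect_equal(
    abg_classify(
      data.frame(ph = 7.61, pco2 = 30, hco3 = 29, sbe = 5)
    )$category_code,
    5L
  )
})

test_that("the engine is exhaustive, exclusive and never unsure", {
  grid <- oracle_grid(ph_step = 0.1, pco2_step = 7.5, hco3_step = 6)
  codes <- abg_classify(grid)$category_code
  expect_true(all(codes %in% 0:8))
  expect_false(any(is.na(codes)))
  # determinism
  expect_identical(codes, abg_classify(grid)$category_code)
})

test_that("classification agrees with the brute-force oracle on a coarse grid", {
  grid <- oracle_grid(ph_step = 0.08, pco2_step = 6, hco3_step = 5)
  engine <- abg_classify(grid)$category_code
  oracle <- mapply(oracle_classify, grid$ph, grid$pco2, grid$hco3)
  expect_equal(engine, unname(oracle))
})

test_that("mirrored respiratory disturbances classify symmetrically", {
  for (delta in c(10, 15, 20, 25)) {
    pco2_up <- 40 + delta
    hco3_up <- 24 + delta / 10 # acute compensation
    ph_up <- 9 - log10(24 * pco2_up / hco3_up)
    pco2_dn <- 40 - delta
    hco3_dn <- 24 - 2 * delta / 10
    ph_dn <- 9 - log10(24 * pco2_dn / hco3_dn)
    up <- abg_classify(data.frame(ph = ph_up, pco2 = pco2_up, hco3 = hco3_up))
    dn <- abg_classify(data.frame(ph = ph_dn, pco2 = pco2_dn, hco3 = hco3_dn))
    expect_equal(up$category_code, 2L, label = sprintf("delta %g up", delta))
    expect_equal(dn$category_code, 1L, label = sprintf("delta %g down", delta))
    # the acute band always contains the constructed value; where the acute
    # and chronic bands overlap, the fit is reported indeterminate
    expect_true(up$chronicity %in% c("acute", "indeterminate"))
    expect_true(dn$chronicity %in% c("acute", "indeterminate"))
  }
})

test_that("lactate adds a cause but never changes the category", {
  base <- data.frame(ph = 7.25, pco2 = 29, hco3 = 14, lactate = 1.0)
  high <- base
  high$lactate <- 6.0
  a <- abg_classify(base)
  b <- abg_classify(high)
  expect_equal(a$category_code, b$category_code)
  expect_false(any(grepl("lactic", a$causes[[1]])))
  expect_true(any(grepl("lactic", b$causes[[1]])))
})

test_that("SBE disagreement is noted but HCO3 governs", {
  d <- data.frame(ph = 7.41, pco2 = 39, hco3 = 24.9, sbe = 5)
  res <- abg_classify(d)
  expect_equal(res$category_code, 0L)
  expect_true(res$sbe_discrepant)
  expect_match(res$narrative, "SBE disagrees")
})

test_that("per-patient anion-gap baseline can change the delta-ratio verdict", {
  base <- data.frame(
    ph = 7.25, pco2 = 29, hco3 = 14, na = 140, cl = 104, albumin = 4
  )
  default_baseline <- abg_classify(base)
  expect_equal(default_baseline$category_code, 3L)
  expect_equal(default_baseline$anion_gap, 22)
  expect_equal(default_baseline$delta_ratio, 1.0)
  expect_match(default_baseline$delta_ratio_interpretation, "pure high-gap")

  patient <- base
  patient$baseline_ag <- 16
  with_baseline <- abg_classify(patient)
  expect_equal(with_baseline$delta_ratio, 0.6)
  expect_match(with_baseline$delta_ratio_interpretation, "mixed")
})
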