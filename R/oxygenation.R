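#' PaO2/FiO2 ratio
#'
#' @param po2 Arterial O2 tension, mmHg.
#' @param fio2 Inspired oxygen fraction in \[0.21, 1.0\] (percent accepted,
#'   see [normalize_fio2()]).
#' @return The PF ratio in mmHg.
#' @examples
#' pf_ratio(106, 0.40) # 265
#' @export
pf_ratio <- function(po2, fio2) {
  fio2 <- normalize_fio2(fio2)
  po2 / fio2
}

#' Berlin ARDS severity band from the PF ratio
#'
#' Assessable only on mechanical ventilation with PEEP >= 5 cmH2O. Bands with
#' inclusive upper edges: severe <= 100, moderate <= 200, mild <= 300 mmHg,
#' otherwise none.
#'
#' @param pf PF ratio, mmHg.
#' @param ventilated Logical: on mechanical ventilation?
#' @param peep PEEP in cmH2O.
#' @return Character vector: `"none"`, `"mild"`, `"moderate"`, `"severe"` or
#'   `"not-assessable"`.
#' @examples
#' ards_band(265, TRUE, 5) # mild
#' ards_band(265, FALSE, NA) # not-assessable
#' @export
ards_band <- function(pf, ventilated, peep) {
  dplyr::case_when(
    is.na(pf) ~ "not-assessable",
    is.na(ventilated) | !ventilated ~ "not-assessable",
    is.na(peep) | peep < 5 ~ "not-assessable",
    pf <= 100 ~ "severe",
    pf <= 200 ~ "moderate",
    pf <= 300 ~ "mild",
    TRUE ~ "none"
  )
}

#' Alveolar oxygen tension and alveolar-arterial gradient
#'
#' Alveolar gas equation: PAO2 = FiO2 x (Pb - PH2O) - pCO2 / RQ, with sea-level
#' defaults Pb 760 mmHg, PH2O 47 mmHg, RQ 0.8. The gradient is PAO2 - PaO2; a
#' negative gradient is still returned (it suggests measurement error and is
#' noted downstream).
#'
#' @param po2,pco2 Arterial tensions, mmHg.
#' @param fio2 Inspired oxygen fraction.
#' @param config An [abg_config()]; `config$atmosphere` holds the constants.
#' @return A tibble with columns `alveolar_po2` and `aa_gradient` (mmHg).
#' @examples
#' aa_gradient(95, 40, 0.21) # PAO2 99.73, gradient 4.73
#' @export
aa_gradient <- function(po2, pco2, fio2, config = NULL) {
  config <- as_config(config)
  atm <- config$atmosphere
  if (any(po2 <= 0 | pco2 <= 0, na.rm = TRUE)) {
    stop("tensions must be positive", call. = FALSE)
  }
  fio2 <- normalize_fio2(fio2)
  pao2 <- fio2 * (atm$barometric_pressure - atm$water_vapour_pressure) -
    pco2 / atm$respiratory_quotient
  tibble::tibble(alveolar_po2 = pao2, aa_gradient = pao2 - po2)
}

#' Oxygenation stage assessment
#'
#' Ventilated patients: PF ratio plus Berlin ARDS banding (PEEP >= 5 required
#' for a band). Spontaneously breathing patients: the pO2 is checked against
#' the age-expected value (102 - 0.33 x age mmHg) and, when below it, the A-a
#' gradient is computed and compared with the age-adjusted normal limit
#' (age/4 + 4 mmHg). Missing age leaves the age comparison not assessable but
#' still computes the gradient. Ages under 1 year are flagged not assessable
#' (no paediatric reference).
#'
#' @inheritParams abg_validate
#' @return The input tibble with added columns `pf_ratio`, `ards_band`,
#'   `alveolar_po2`, `aa_gradient`, `aa_gradient_normal_limit`,
#'   `expected_po2`, `oxygenation_verdict`.
#' @examples
#' assess_oxygenation(data.frame(
#'   ph = 7.4, pco2 = 40, hco3 = 24, po2 = 60, fio2 = 0.21, age_years = 80,
#'   mechanically_ventilated = FALSE
#' ))
#' @export
assess_oxygenation <- function(data, config = NULL) {
  config <- as_config(config)
  data <- as_abg_tbl(data)
  ox <- config$oxygenation

  data$pf_ratio <- ifelse(
    is.na(data$fio2) | is.na(data$po2), NA_real_,
    data$po2 / data$fio2
  )
  data$ards_band <- ards_band(
    data$pf_ratio, data$mechanically_ventilated, data$peep
  )

  gradable <- !is.na(data$po2) & !is.na(data$pco2) & !is.na(data$fio2)
  data$alveolar_po2 <- NA_real_
  data$aa_gradient <- NA_real_
  if (any(gradable)) {
    g <- aa_gradient(
      data$po2[gradable], data$pco2[gradable], data$fio2[gradable], config
    )
    data$alveolar_po2[gradable] <- g$alveolar_po2
    data$aa_gradient[gradable] <- g$aa_gradient
  }

  age_ok <- !is.na(data$age_years) & data$age_years >= ox$min_age_years
  data$expected_po2 <- ifelse(
    age_ok, ox$age_po2_intercept - ox$age_po2_slope * data$age_years, NA_real_
  )
  data$aa_gradient_normal_limit <- ifelse(
    age_ok, ox$aa_limit_intercept + ox$aa_limit_slope * data$age_years,
    NA_real_
  )

  ventilated <- !is.na(data$mechanically_ventilated) & data$mechanically_ventilated
  data$oxygenation_verdict <- dplyr::case_when(
    is.na(data$po2) ~ "not assessable: pO2 missing",
    ventilated & data$ards_band == "not-assessable" ~ sprintf(
      "ventilated: PF ratio %.0f mmHg; ARDS banding requires PEEP >= 5 cmH2O",
      data$pf_ratio
    ),
    ventilated & data$ards_band == "none" ~ sprintf(
      "ventilated: PF ratio %.0f mmHg, no ARDS-range hypoxaemia", data$pf_ratio
    ),
    ventilated ~ sprintf(
      "ventilated: PF ratio %.0f mmHg, %s ARDS range (Berlin) - rule out ARDS",
      data$pf_ratio, data$ards_band
    ),
    !is.na(data$aa_gradient) & data$aa_gradient < 0 ~
      "negative A-a gradient: check data quality (suggests measurement error)",
    !age_ok & !is.na(data$aa_gradient) ~ sprintf(
      "spontaneous: age comparison not assessable; A-a gradient %.1f mmHg",
      data$aa_gradient
    ),
    age_ok & data$po2 >= data$expected_po2 ~
      "spontaneous: pO2 adequate for age",
    age_ok & !is.na(data$aa_gradient) &
      data$aa_gradient > data$aa_gradient_normal_limit ~ sprintf(
      "spontaneous: hypoxaemia for age with raised A-a gradient (%.1f > limit %.1f mmHg)",
      data$aa_gradient, data$aa_gradient_normal_limit
    ),
    age_ok & !is.na(data$aa_gradient) ~ sprintf(
      "spontaneous: pO2 below age-expected but A-a gradient normal (%.1f <= limit %.1f mmHg)",
      data$aa_gradient, data$aa_gradient_normal_limit
    ),
    TRUE ~ "not assessable: insufficient inputs"
  )
  data
}
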