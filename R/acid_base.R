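#' Candidate primary acid-base disorders from value directions
#'
#' Direction logic of the physiological approach: acidaemia with a high pCO2
#' suggests respiratory acidosis; acidaemia with a low HCO3 (or low SBE)
#' suggests metabolic acidosis; the alkalaemic mirror likewise. A normal pH
#' with pCO2 and HCO3 abnormal in opposing acid-base directions yields both
#' mixed candidates; fully normal values yield an empty set.
#'
#' @param ph,pco2,hco3,sbe Numeric vectors (sbe may be `NA`).
#' @param config An [abg_config()].
#' @return A list (one element per input position) of character vectors drawn
#'   from `"respiratory acidosis"`, `"respiratory alkalosis"`,
#'   `"metabolic acidosis"`, `"metabolic alkalosis"`.
#' @examples
#' primary_disorders(7.30, 60, 28, 2.5)[[1]]
#' @export
primary_disorders <- function(ph, pco2, hco3, sbe = NA_real_, config = NULL) {
  config <- as_config(config)
  n <- max(length(ph), length(pco2), length(hco3), length(sbe))
  ph <- rep_len(ph, n)
  pco2 <- rep_len(pco2, n)
  hco3 <- rep_len(hco3, n)
  sbe <- rep_len(sbe, n)
  ph_f <- range_flag(ph, config$ranges$ph)
  p_f <- range_flag(pco2, config$ranges$pco2)
  h_f <- range_flag(hco3, config$ranges$hco3)
  s_f <- range_flag(sbe, config$ranges$sbe)
  met_low <- h_f == "low" | (!is.na(s_f) & s_f == "low")
  met_high <- h_f == "high" | (!is.na(s_f) & s_f == "high")
  purrr::pmap(
    list(ph_f, p_f, met_low, met_high),
    function(phf, pf, mlo, mhi) {
      out <- character()
      if (phf == "low") {
        if (pf == "high") out <- c(out, "respiratory acidosis")
        if (mlo) out <- c(out, "metabolic acidosis")
      } else if (phf == "high") {
        if (pf == "low") out <- c(out, "respiratory alkalosis")
        if (mhi) out <- c(out, "metabolic alkalosis")
      } else {
        # normal pH: opposing abnormalities give mixed candidates
        if (pf == "high" && mhi) {
          out <- c("respiratory acidosis", "metabolic alkalosis")
        }
        if (pf == "low" && mlo) {
          out <- c("respiratory alkalosis", "metabolic acidosis")
        }
      }
      out
    }
  )
}

#' Expected range of the compensating variable
#'
#' For a metabolic primary disorder, the expected pCO2 band; for a respiratory
#' primary, the expected HCO3 band at the stated chronicity. Rules (defaults,
#' configurable via [abg_config()]): metabolic acidosis, Winter's
#' pCO2 = 1.5 x HCO3 + 8 +/- 2 mmHg; metabolic alkalosis,
#' pCO2 = 40 + 0.7 x (HCO3 - 24) +/- 5; respiratory acidosis, HCO3 rises 1
#' (acute) or 3.5 (chronic) mmol/L per 10 mmHg pCO2 +/- 2; respiratory
#' alkalosis, HCO3 falls 2 (acute) or 4 (chronic) per 10 mmHg +/- 2.
#'
#' @param primary One of `"metabolic acidosis"`, `"metabolic alkalosis"`,
#'   `"respiratory acidosis"`, `"respiratory alkalosis"`.
#' @param pco2,hco3 The observed values (only the one defining the primary is
#'   used).
#' @param chronicity `"acute"` or `"chronic"`; ignored for metabolic primaries.
#' @param config An [abg_config()].
#' @return Numeric length-2 vector `c(low, high)` of the expected band.
#' @examples
#' expected_compensation("metabolic acidosis", hco3 = 14) # Winter's 27-31
#' @export
expected_compensation <- function(primary, pco2 = NULL, hco3 = NULL,
                                  chronicity = c("acute", "chronic"),
                                  config = NULL) {
  config <- as_config(config)
  chronicity <- match.arg(chronicity)
  cc <- config$compensation
  switch(primary,
    "metabolic acidosis" = {
      stopifnot(!is.null(hco3))
      mid <- cc$winters_slope * hco3 + cc$winters_intercept
      c(mid - cc$winters_tol, mid + cc$winters_tol)
    },
    "metabolic alkalosis" = {
      stopifnot(!is.null(hco3))
      mid <- cc$pco2_mid + cc$metalk_slope * (hco3 - cc$hco3_mid)
      c(mid - cc$metalk_tol, mid + cc$metalk_tol)
    },
    "respiratory acidosis" = {
      stopifnot(!is.null(pco2))
      rate <- if (chronicity == "acute") cc$resp_acute_acid else cc$resp_chronic_acid
      mid <- cc$hco3_mid + rate * (pco2 - cc$pco2_mid) / 10
      c(mid - cc$resp_tol, mid + cc$resp_tol)
    },
    "respiratory alkalosis" = {
      stopifnot(!is.null(pco2))
      rate <- if (chronicity == "acute") cc$resp_acute_alk else cc$resp_chronic_alk
      mid <- cc$hco3_mid + rate * (pco2 - cc$pco2_mid) / 10
      c(mid - cc$resp_tol, mid + cc$resp_tol)
    },
    stop("unknown primary disorder: ", primary, call. = FALSE)
  )
}

#' Anion gap and albumin-corrected anion gap
#'
#' `anion_gap()` is Na - Cl - HCO3 (mmol/L); any missing constituent yields
#' `NA` (gap analysis is skipped, not an error). `corrected_anion_gap()` adds
#' 2.5 mmol/L per g/dL of albumin below 4.0; no correction at or above 4.0.
#'
#' @param na,cl,hco3 Concentrations in mmol/L.
#' @param ag Anion gap, mmol/L.
#' @param albumin Serum albumin, g/dL.
#' @return Numeric vector, mmol/L.
#' @examples
#' anion_gap(139, 107, 24.9) # 7.1
#' corrected_anion_gap(7.1, 2.2) # 11.6
#' @export
anion_gap <- function(na, cl, hco3) {
  na - cl - hco3
}

#' @rdname anion_gap
#' @export
corrected_anion_gap <- function(ag, albumin) {
  ifelse(is.na(albumin), ag, ag + 2.5 * pmax(4.0 - albumin, 0))
}

#' Delta ratio of a high-anion-gap metabolic acidosis
#'
#' (AG - baseline AG) / (baseline HCO3 - HCO3). Baselines default to
#' AG 12, HCO3 24 mmol/L when no per-patient values are known; providing the
#' patient's own baselines can change the verdict, which is the point of
#' tracking them. `NA` when the HCO3 denominator is zero (not assessable).
#'
#' @param ag Current (corrected) anion gap, mmol/L.
#' @param hco3 Current bicarbonate, mmol/L.
#' @param baseline_ag,baseline_hco3 Patient baselines, mmol/L.
#' @return The delta ratio (unitless).
#' @examples
#' delta_ratio(24, 12) # 1.0: pure high-gap
#' delta_ratio(24, 12, baseline_ag = 16) # 0.67: mixed picture
#' @export
delta_ratio <- function(ag, hco3, baseline_ag = 12, baseline_hco3 = 24) {
  baseline_ag <- ifelse(is.na(baseline_ag), 12, baseline_ag)
  baseline_hco3 <- ifelse(is.na(baseline_hco3), 24, baseline_hco3)
  denom <- baseline_hco3 - hco3
  ifelse(denom == 0, NA_real_, (ag - baseline_ag) / denom)
}

delta_ratio_interpretation <- function(dr, bands = c(0.4, 0.8, 2.0)) {
  dplyr::case_when(
    is.na(dr) ~ NA_character_,
    dr < bands[1] ~ "pure normal-gap metabolic acidosis",
    dr <= bands[2] ~ "mixed high-gap and normal-gap metabolic acidosis",
    dr <= bands[3] ~ "pure high-gap metabolic acidosis",
    TRUE ~ "high-gap metabolic acidosis with concurrent metabolic alkalosis"
  )
}

# Vectorized classification core: (ph, pco2, hco3) -> code 0-8 with
# compensation status and chronicity. The decision logic of the physiological
# approach; dual categories arise either from two same/opposite-direction
# abnormalities or from a compensating variable outside its expected band.
classify_core <- function(ph, pco2, hco3, config) {
  cc <- config$compensation
  ph_f <- range_flag(ph, config$ranges$ph)
  p_f <- range_flag(pco2, config$ranges$pco2)
  h_f <- range_flag(hco3, config$ranges$hco3)

  # respiratory expected-HCO3 bands (direction taken from the pCO2 flag)
  resp_acid <- p_f == "high"
  acute_rate <- ifelse(resp_acid, cc$resp_acute_acid, cc$resp_acute_alk)
  chronic_rate <- ifelse(resp_acid, cc$resp_chronic_acid, cc$resp_chronic_alk)
  acute_mid <- cc$hco3_mid + acute_rate * (pco2 - cc$pco2_mid) / 10
  chronic_mid <- cc$hco3_mid + chronic_rate * (pco2 - cc$pco2_mid) / 10
  acute_lo <- acute_mid - cc$resp_tol
  acute_hi <- acute_mid + cc$resp_tol
  chronic_lo <- chronic_mid - cc$resp_tol
  chronic_hi <- chronic_mid + cc$resp_tol
  env_lo <- pmin(acute_lo, chronic_lo)
  env_hi <- pmax(acute_hi, chronic_hi)

  # metabolic expected-pCO2 bands (direction from the HCO3 flag)
  met_acid <- h_f == "low"
  met_mid <- ifelse(met_acid,
    cc$winters_slope * hco3 + cc$winters_intercept,
    cc$pco2_mid + cc$metalk_slope * (hco3 - cc$hco3_mid)
  )
  met_tol <- ifelse(met_acid, cc$winters_tol, cc$metalk_tol)
  met_lo <- met_mid - met_tol
  met_hi <- met_mid + met_tol

  # which pathway resolves each sample
  path <- dplyr::case_when(
    ph_f == "normal" & p_f == "normal" & h_f == "normal" ~ "normal",
    ph_f == "normal" & p_f == "high" & h_f == "high" ~ "dual8",
    ph_f == "normal" & p_f == "low" & h_f == "low" ~ "dual7",
    ph_f == "normal" & p_f == "high" & h_f == "low" ~ "dual6",
    ph_f == "normal" & p_f == "low" & h_f == "high" ~ "dual5",
    ph_f == "normal" & p_f != "normal" ~ "resp",
    ph_f == "normal" ~ "met",
    ph_f == "low" & p_f == "high" & h_f == "low" ~ "dual6",
    ph_f == "low" & p_f == "low" & h_f == "high" ~ "dual5",
    ph_f == "low" & p_f == "high" ~ "resp",
    ph_f == "low" & h_f == "low" ~ "met",
    ph_f == "low" ~ "dual6",
    ph_f == "high" & p_f == "low" & h_f == "high" ~ "dual5",
    ph_f == "high" & p_f == "high" & h_f == "low" ~ "dual6",
    ph_f == "high" & p_f == "low" ~ "resp",
    ph_f == "high" & h_f == "high" ~ "met",
    TRUE ~ "dual5"
  )

  resp_code <- dplyr::case_when(
    hco3 < env_lo & resp_acid ~ 6L, # insufficient metabolic response
    hco3 < env_lo & !resp_acid ~ 7L, # metabolic acidosis on top
    hco3 > env_hi & resp_acid ~ 8L, # metabolic alkalosis on top
    hco3 > env_hi & !resp_acid ~ 5L, # insufficient response to alkalosis
    resp_acid ~ 2L,
    TRUE ~ 1L
  )
  resp_comp <- dplyr::case_when(
    hco3 >= env_lo & hco3 <= env_hi ~ "appropriate",
    resp_acid & hco3 < env_lo ~ "inadequate",
    resp_acid & hco3 > env_hi ~ "excessive",
    !resp_acid & hco3 > env_hi ~ "inadequate",
    TRUE ~ "excessive"
  )
  in_acute <- hco3 >= acute_lo & hco3 <= acute_hi
  in_chronic <- hco3 >= chronic_lo & hco3 <= chronic_hi
  resp_chron <- dplyr::case_when(
    resp_code %in% c(1L, 2L) & in_acute & !in_chronic ~ "acute",
    resp_code %in% c(1L, 2L) & in_chronic & !in_acute ~ "chronic",
    resp_code %in% c(1L, 2L) ~ "indeterminate",
    TRUE ~ "n/a"
  )

  met_code <- dplyr::case_when(
    pco2 > met_hi & met_acid ~ 6L, # CO2 retained on top of acidosis
    pco2 > met_hi & !met_acid ~ 8L, # under-compensated alkalosis: resp acidosis
    pco2 < met_lo & met_acid ~ 7L, # over-ventilation: resp alkalosis on top
    pco2 < met_lo & !met_acid ~ 5L,
    met_acid ~ 3L,
    TRUE ~ 4L
  )
  met_comp <- dplyr::case_when(
    pco2 >= met_lo & pco2 <= met_hi ~ "appropriate",
    met_acid & pco2 > met_hi ~ "inadequate",
    met_acid & pco2 < met_lo ~ "excessive",
    !met_acid & pco2 < met_lo ~ "inadequate",
    TRUE ~ "excessive"
  )

  code <- dplyr::case_when(
    path == "normal" ~ 0L,
    path == "dual5" ~ 5L,
    path == "dual6" ~ 6L,
    path == "dual7" ~ 7L,
    path == "dual8" ~ 8L,
    path == "resp" ~ resp_code,
    TRUE ~ met_code
  )
  compensation <- dplyr::case_when(
    path == "resp" ~ resp_comp,
    path == "met" ~ met_comp,
    TRUE ~ "not-assessable"
  )
  chronicity <- dplyr::case_when(
    path == "resp" ~ resp_chron,
    TRUE ~ "n/a"
  )
  tibble::tibble(code = code, compensation_status = compensation, chronicity = chronicity)
}

#' Classify samples into the nine acid-base categories
#'
#' The physiological approach: identify the primary disorder(s) from the
#' directions of pH, pCO2 and HCO3 against the reference ranges, test the
#' compensating variable against its expected band (see
#' [expected_compensation()]), and emit exactly one category 0-8 per sample.
#' A compensating variable outside its expected band declares a second,
#' concurrent disorder (a dual category 5-8); a normal pH with opposing
#' abnormalities is reported as the corresponding dual category rather than
#' electing a primary. Anion gap (albumin-corrected when albumin is known,
#' against the patient's own baseline when known) and the delta ratio refine
#' metabolic acidosis; SBE is used as a cross-check on the HCO3 direction and
#' any disagreement is noted in the narrative, with HCO3 governing.
#'
#' The engine is deterministic and never returns code 9 ("I am not sure"),
#' which only human raters may produce.
#'
#' @inheritParams abg_validate
#' @param cause_map A data frame like [abg_cause_map()] mapping
#'   (`code`, `gap_status`) to causes.
#' @return The input tibble with added columns `category_code`,
#'   `category_label`, `subcategory`, `anion_gap`, `corrected_anion_gap`,
#'   `gap_status`, `delta_ratio`, `delta_ratio_interpretation`,
#'   `compensation_status`, `chronicity`, `interpret_with_caution`,
#'   `narrative` and a `causes` list-column.
#' @examples
#' abg_classify(data.frame(ph = 7.25, pco2 = 29, hco3 = 14, na = 140, cl = 104))
#' @export
abg_classify <- function(data, config = NULL, cause_map = abg_cause_map()) {
  config <- as_config(config)
  data <- as_abg_tbl(data)
  findings <- abg_validate(data, config) # hard-errors on missing mandatory fields

  core <- classify_core(data$ph, data$pco2, data$hco3, config)
  data$category_code <- core$code
  data$category_label <- abg_category_label(core$code)
  data$compensation_status <- core$compensation_status
  data$chronicity <- core$chronicity

  data$anion_gap <- anion_gap(data$na, data$cl, data$hco3)
  data$corrected_anion_gap <- corrected_anion_gap(data$anion_gap, data$albumin)
  gap_threshold <- ifelse(
    is.na(data$baseline_ag), config$anion_gap_normal[2], data$baseline_ag
  )
  data$gap_status <- dplyr::case_when(
    is.na(data$corrected_anion_gap) ~ "not-assessed",
    data$corrected_anion_gap > gap_threshold ~ "high-gap",
    TRUE ~ "normal-gap"
  )

  met_acidosis_present <- data$category_code %in% c(3L, 6L, 7L)
  data$delta_ratio <- ifelse(
    met_acidosis_present & data$gap_status == "high-gap",
    delta_ratio(
      data$corrected_anion_gap, data$hco3,
      data$baseline_ag, data$baseline_hco3
    ),
    NA_real_
  )
  data$delta_ratio_interpretation <-
    delta_ratio_interpretation(data$delta_ratio, config$delta_ratio_bands)

  cons <- check_internal_consistency(data, config = config)
  data$interpret_with_caution <- !cons$consistent

  sbe_f <- range_flag(data$sbe, config$ranges$sbe)
  hco3_f <- range_flag(data$hco3, config$ranges$hco3)
  data$sbe_discrepant <- !is.na(sbe_f) & sbe_f != hco3_f

  data$subcategory <- paste(
    paste0("cat", data$category_code),
    ifelse(met_acidosis_present, data$gap_status, "gap-n/a"),
    data$chronicity,
    data$compensation_status,
    sep = "|"
  )

  data$causes <- purrr::pmap(
    list(data$category_code, data$gap_status, data$lactate),
    function(code, gap, lactate) {
      hit <- cause_map$code == code &
        (is.na(cause_map$gap_status) | cause_map$gap_status == gap)
      causes <- cause_map$cause[hit]
      if (!is.na(lactate) && lactate > config$lactate_cause_threshold &&
        !any(grepl("lactic", causes))) {
        causes <- c(causes, "lactic acidosis")
      }
      causes
    }
  )

  data$narrative <- build_narrative(data)
  data
}

build_narrative <- function(data) {
  base <- sprintf(
    "%s (pH %.2f, pCO2 %.0f mmHg, HCO3 %.1f mmol/L).",
    data$category_label, data$ph, data$pco2, data$hco3
  )
  comp <- ifelse(
    data$compensation_status == "not-assessable", "",
    sprintf(
      " Compensation %s%s.", data$compensation_status,
      ifelse(data$chronicity %in% c("acute", "chronic", "indeterminate"),
        paste0(", chronicity ", data$chronicity), ""
      )
    )
  )
  gap <- ifelse(
    is.na(data$corrected_anion_gap), "",
    sprintf(
      " Anion gap %.1f (albumin-corrected %.1f) mmol/L, %s.",
      data$anion_gap, data$corrected_anion_gap, data$gap_status
    )
  )
  dr <- ifelse(
    is.na(data$delta_ratio), "",
    sprintf(
      " Delta ratio %.2f: %s.", data$delta_ratio,
      data$delta_ratio_interpretation
    )
  )
  sbe <- ifelse(
    data$sbe_discrepant,
    " Note: SBE disagrees with the HCO3 direction; HCO3 governs this reading.",
    ""
  )
  caution <- ifelse(
    data$interpret_with_caution,
    " Internal consistency check failed: interpret with caution.",
    ""
  )
  paste0(base, comp, gap, dr, sbe, caution)
}
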