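#' Hydrogen ion concentration from pH
#'
#' @param ph Numeric vector of arterial pH values in \[6.5, 8.0\].
#' @return \[H+\] in nmol/L: `10^(9 - ph)`.
#' @examples
#' hplus_from_ph(7.40) # 39.81 nmol/L
#' @export
hplus_from_ph <- function(ph) {
  bad <- !is.na(ph) & (ph < 6.5 | ph > 8.0)
  if (any(bad)) {
    stop("pH outside [6.5, 8.0]: ", paste(ph[bad], collapse = ", "),
      call. = FALSE
    )
  }
  10^(9 - ph)
}

#' Expected hydrogen ion concentration from the Henderson relation
#'
#' The bedside Henderson approximation \[H+\] = 24 x pCO2 / HCO3 (nmol/L with
#' pCO2 in mmHg and HCO3 in mmol/L), used to cross-check the measured pH.
#'
#' @param pco2 Arterial CO2 tension, mmHg (> 0).
#' @param hco3 Bicarbonate, mmol/L (> 0).
#' @return Expected \[H+\] in nmol/L.
#' @examples
#' expected_hplus_henderson(40, 24) # 40 nmol/L, i.e. pH ~7.40
#' @export
expected_hplus_henderson <- function(pco2, hco3) {
  if (any(pco2 <= 0 | hco3 <= 0, na.rm = TRUE)) {
    stop("pCO2 and HCO3 must be positive", call. = FALSE)
  }
  24 * pco2 / hco3
}

consistency_advice <- c(
  "machine calibration",
  "sample taken with a tourniquet",
  "sample taken from a patient on dialysis with an A-V fistula with a tourniquet in place",
  "advise repeating the sample"
)

#' Internal-consistency check of pH, pCO2 and HCO3
#'
#' Compares the measured hydrogen ion concentration (from pH) with the value
#' the Henderson relation expects from pCO2 and HCO3. A sample is consistent
#' when the relative discrepancy does not exceed the configured tolerance;
#' inconsistent samples carry advice on likely pre-analytical error sources and
#' a recommendation to repeat the sample.
#'
#' @inheritParams abg_validate
#' @param tolerance Relative discrepancy tolerated; defaults to
#'   `config$tolerance` (0.15).
#' @return A tibble with one row per sample: `sample_id`, `measured_hplus`,
#'   `expected_hplus` (nmol/L), `relative_discrepancy`, `consistent` and an
#'   `advice` list-column (empty when consistent).
#' @examples
#' check_internal_consistency(data.frame(ph = 7.20, pco2 = 40, hco3 = 24))
#' @export
check_internal_consistency <- function(data, tolerance = NULL, config = NULL) {
  config <- as_config(config)
  if (is.null(tolerance)) tolerance <- config$tolerance
  stopifnot(is.numeric(tolerance), tolerance >= 0)
  data <- as_abg_tbl(data)
  for (field in c("ph", "pco2", "hco3")) {
    if (anyNA(data[[field]])) {
      stop("`", field, "` required for the consistency check", call. = FALSE)
    }
  }
  measured <- hplus_from_ph(data$ph)
  expected <- expected_hplus_henderson(data$pco2, data$hco3)
  disc <- abs(measured - expected) / expected
  consistent <- disc <= tolerance
  tibble::tibble(
    sample_id = data$sample_id,
    measured_hplus = measured,
    expected_hplus = expected,
    relative_discrepancy = disc,
    consistent = consistent,
    advice = purrr::map(consistent, function(ok) {
      if (ok) character() else consistency_advice
    })
  )
}

# screened analytes in severity order (most immediately lethal first)
critical_order <- c("ph", "k", "na", "ca_ionized", "glucose", "lactate")

critical_alert_names <- c(
  ph = "critical pH (acidaemia/alkalaemia)",
  k = "critical potassium (hypo/hyperkalaemia)",
  na = "critical sodium (hypo/hypernatraemia)",
  ca_ionized = "critical ionized calcium",
  glucose = "critical glucose (hypo/hyperglycaemia)",
  lactate = "critical lactate"
)

#' Screen for imminent life-threatening values
#'
#' Checks pH, potassium, sodium, ionized calcium, glucose and lactate against
#' the configured critical thresholds. Absent analytes are silently skipped;
#' alerts are ordered by severity (pH first, then K, Na, Ca, glucose,
#' lactate).
#'
#' @inheritParams abg_validate
#' @return A tibble with columns `sample_id`, `analyte`, `value`, `threshold`,
#'   `direction` (`"below"`/`"above"`), `alert`; zero rows when nothing is
#'   critical.
#' @examples
#' screen_life_threatening(data.frame(ph = 7.30, pco2 = 40, hco3 = 19, k = 7.2))
#' @export
screen_life_threatening <- function(data, config = NULL) {
  config <- as_config(config)
  data <- as_abg_tbl(data)
  rows <- purrr::map(critical_order, function(analyte) {
    v <- data[[analyte]]
    thr <- config$critical[[analyte]]
    below <- !is.na(v) & !is.na(thr[1]) & v < thr[1]
    above <- !is.na(v) & !is.na(thr[2]) & v > thr[2]
    hit <- below | above
    if (!any(hit)) {
      return(NULL)
    }
    tibble::tibble(
      sample_id = data$sample_id[hit],
      analyte = analyte,
      value = v[hit],
      threshold = ifelse(below[hit], thr[1], thr[2]),
      direction = ifelse(below[hit], "below", "above"),
      alert = unname(critical_alert_names[analyte])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      sample_id = character(), analyte = character(), value = numeric(),
      threshold = numeric(), direction = character(), alert = character()
    )
  }
  out
}

#' Run the full safety stage
#'
#' Combines the Henderson internal-consistency check with life-threat
#' screening, one row per sample.
#'
#' @inheritParams check_internal_consistency
#' @return A tibble: consistency columns of [check_internal_consistency()]
#'   plus `n_alerts` and an `alerts` list-column of per-sample alert tibbles.
#' @export
assess_safety <- function(data, tolerance = NULL, config = NULL) {
  config <- as_config(config)
  data <- as_abg_tbl(data)
  cons <- check_internal_consistency(data, tolerance = tolerance, config = config)
  alerts <- screen_life_threatening(data, config = config)
  split_alerts <- split(alerts, factor(alerts$sample_id, levels = data$sample_id))
  cons$alerts <- unname(split_alerts)
  cons$n_alerts <- vapply(split_alerts, nrow, integer(1), USE.NAMES = FALSE)
  cons
}
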