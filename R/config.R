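#' Acid-base disorder categories
#'
#' The nine-category taxonomy of acid-base status used throughout the package,
#' plus code 9 ("I am not sure"), which is accepted on input of human rater
#' labels but never produced by the classification engine.
#'
#' @return A tibble with columns `code` (integer 0-9) and `label` (character).
#' @examples
#' abg_categories()
#' @export
abg_categories <- function() {
  tibble::tibble(
    code = 0:9L,
    label = c(
      "Normal acid-base status",
      "Respiratory alkalosis",
      "Respiratory acidosis",
      "Metabolic acidosis",
      "Metabolic alkalosis",
      "Respiratory alkalosis and metabolic alkalosis",
      "Respiratory acidosis and metabolic acidosis",
      "Respiratory alkalosis and metabolic acidosis",
      "Respiratory acidosis and metabolic alkalosis",
      "I am not sure"
    )
  )
}

#' Look up the label for an acid-base category code
#'
#' @param code Integer vector of category codes (0-9).
#' @return Character vector of category labels.
#' @examples
#' abg_category_label(c(0, 6))
#' @export
abg_category_label <- function(code) {
  stopifnot(all(code %in% 0:9 | is.na(code)))
  abg_categories()$label[match(code, abg_categories()$code)]
}

#' Interpretation configuration
#'
#' Bundles every tunable used by the interpretation stages: the normal arterial
#' reference ranges, the Henderson consistency tolerance, critical life-threat
#' thresholds, compensation-rule constants, atmospheric constants for the
#' alveolar gas equation, anion-gap baselines and the renal cut-offs. Defaults
#' are the conventional bedside values; every element can be overridden.
#'
#' @param ... Named overrides of any default element, e.g. `tolerance = 0.10`
#'   or `ranges = list(ph = c(7.30, 7.50))`. List elements (`ranges`,
#'   `critical`, `compensation`, `atmosphere`, `renal`, `baselines`) are merged
#'   element-wise with the defaults.
#'
#' @return A list of class `abg_config`.
#'
#' @details
#' Reference ranges (inclusive endpoints): pH 7.35-7.45; pCO2 35-45 mmHg;
#' HCO3 22-30 mmol/L; SBE -2 to +2 mmol/L; lactate 0.5-2.0 mmol/L.
#' Compensation rules (all expected bands on the compensating variable):
#' metabolic acidosis, expected pCO2 = 1.5 x HCO3 + 8 +/- 2 (Winter);
#' metabolic alkalosis, expected pCO2 = 40 + 0.7 x dHCO3 +/- 5;
#' respiratory acidosis, expected HCO3 = 24 + 1 (acute) / 3.5 (chronic) per
#' 10 mmHg dpCO2 +/- 2; respiratory alkalosis, 24 - 2 (acute) / 4 (chronic)
#' per 10 mmHg +/- 2.
#'
#' @examples
#' cfg <- abg_config(tolerance = 0.10)
#' cfg$ranges$ph
#' @export
abg_config <- function(...) {
  defaults <- list(
    ranges = list(
      ph = c(7.35, 7.45),
      pco2 = c(35, 45),
      hco3 = c(22, 30),
      sbe = c(-2, 2),
      lactate = c(0.5, 2.0)
    ),
    # Henderson consistency: relative discrepancy tolerated between measured
    # and expected [H+]; absorbs the 24-coefficient approximation error.
    tolerance = 0.15,
    # Critical (life-threat) thresholds; NA means no bound on that side.
    critical = list(
      ph = c(7.10, 7.60),
      k = c(2.5, 6.5),
      na = c(120, 160),
      ca_ionized = c(0.8, 1.6),
      glucose = c(40, 600),
      lactate = c(NA, 4.0)
    ),
    compensation = list(
      winters_slope = 1.5, winters_intercept = 8, winters_tol = 2,
      metalk_slope = 0.7, metalk_tol = 5,
      resp_acute_acid = 1.0, resp_chronic_acid = 3.5,
      resp_acute_alk = 2.0, resp_chronic_alk = 4.0,
      resp_tol = 2,
      pco2_mid = 40, hco3_mid = 24
    ),
    atmosphere = list(
      barometric_pressure = 760,
      water_vapour_pressure = 47,
      respiratory_quotient = 0.8
    ),
    oxygenation = list(
      # expected pO2 = 102 - 0.33 x age (mmHg); A-a limit = age/4 + 4 (mmHg)
      age_po2_intercept = 102, age_po2_slope = 0.33,
      aa_limit_intercept = 4, aa_limit_slope = 0.25,
      min_age_years = 1
    ),
    renal = list(
      bcr_low = 10, bcr_high = 20,
      urr_adequate = 65
    ),
    baselines = list(anion_gap = 12, hco3 = 24),
    anion_gap_normal = c(4, 12),
    delta_ratio_bands = c(0.4, 0.8, 2.0),
    lactate_cause_threshold = 2.0
  )
  overrides <- list(...)
  if (length(overrides) == 0L) {
    return(structure(defaults, class = "abg_config"))
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) {
    stop("unknown abg_config element(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  for (r in defaults$ranges) {
    if (r[1] >= r[2]) stop("reference range low must be < high", call. = FALSE)
  }
  structure(defaults, class = "abg_config")
}

#' @export
print.abg_config <- function(x, ...) {
  cat("<abg_config>\n")
  cat("  consistency tolerance:", x$tolerance, "\n")
  cat(
    "  ranges: pH", paste(x$ranges$ph, collapse = "-"),
    "| pCO2", paste(x$ranges$pco2, collapse = "-"), "mmHg",
    "| HCO3", paste(x$ranges$hco3, collapse = "-"), "mmol/L\n"
  )
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) {
    abg_config()
  } else if (inherits(config, "abg_config")) {
    config
  } else {
    stop("`config` must be NULL or an abg_config object", call. = FALSE)
  }
}

#' Default cause map
#'
#' A minimal, configurable map from acid-base classification facets to lists of
#' candidate causes, attached to classification narratives. Keyed by category
#' code and (optionally) the anion-gap status for metabolic acidosis.
#'
#' @return A tibble with columns `code`, `gap_status` (NA when not applicable)
#'   and `cause`.
#' @examples
#' abg_cause_map()
#' @export
abg_cause_map <- function() {
  tibble::tribble(
    ~code, ~gap_status, ~cause,
    1L, NA, "hyperventilation (pain, anxiety, hypoxaemia, sepsis)",
    1L, NA, "salicylate toxicity",
    2L, NA, "hypoventilation (CNS depression, neuromuscular weakness)",
    2L, NA, "obstructive airway disease",
    3L, "high-gap", "lactic acidosis",
    3L, "high-gap", "ketoacidosis",
    3L, "high-gap", "toxic ingestion (methanol, ethylene glycol, salicylate)",
    3L, "high-gap", "uraemia",
    3L, "normal-gap", "gastrointestinal bicarbonate loss (diarrhoea)",
    3L, "normal-gap", "renal tubular acidosis",
    4L, NA, "vomiting or nasogastric losses",
    4L, NA, "diuretic therapy",
    4L, NA, "mineralocorticoid excess",
    5L, NA, "combined alkalinising processes (e.g. ventilation + vomiting)",
    6L, NA, "combined acidifying processes (e.g. cardiac arrest, severe sepsis)",
    7L, NA, "salicylate toxicity; sepsis with lactic acidosis",
    8L, NA, "chronic lung disease with diuretics or vomiting"
  )
}
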