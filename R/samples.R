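#' Column schema for blood gas sample tables
#'
#' Every user-facing function takes a data frame with one row per arterial
#' sample. Recognised columns (all others are carried through untouched):
#'
#' * identifiers: `sample_id`, `patient_id`
#' * blood gas: `fio2` (fraction or percent), `ph`, `pco2` (mmHg),
#'   `po2` (mmHg), `hco3` (mmol/L), `sbe` (mmol/L), `lactate` (mmol/L)
#' * biochemistry: `na`, `k`, `cl`, `ca_ionized` (mmol/L), `glucose`, `urea`,
#'   `creatinine`, `urea_pre`, `urea_post` (mg/dL), `albumin` (g/dL)
#' * context: `age_years`, `mechanically_ventilated`, `peep` (cmH2O),
#'   `on_dialysis`, `baseline_ag`, `baseline_hco3`,
#'   `dialysis_session_hours`, `ultrafiltrate_volume` (L), `post_weight` (kg)
#'
#' `as_abg_tbl()` coerces a data frame to this schema: adds any missing
#' optional columns as `NA`, normalizes FiO2 to a fraction, generates
#' sample ids when absent.
#'
#' @param data A data frame of samples.
#' @return A tibble with the full column set.
#' @examples
#' as_abg_tbl(data.frame(ph = 7.40, pco2 = 40, hco3 = 24))
#' @export
as_abg_tbl <- function(data) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  numeric_cols <- c(
    "fio2", "ph", "pco2", "po2", "hco3", "sbe", "lactate",
    "na", "k", "cl", "glucose", "ca_ionized", "albumin", "urea",
    "creatinine", "urea_pre", "urea_post", "age_years", "peep",
    "baseline_ag", "baseline_hco3", "dialysis_session_hours",
    "ultrafiltrate_volume", "post_weight"
  )
  flag_cols <- c("mechanically_ventilated", "on_dialysis")
  for (col in numeric_cols) {
    if (!col %in% names(data)) {
      data[[col]] <- NA_real_
    } else {
      data[[col]] <- as.numeric(data[[col]])
    }
  }
  for (col in flag_cols) {
    if (!col %in% names(data)) {
      data[[col]] <- NA
    } else {
      data[[col]] <- as.logical(data[[col]])
    }
  }
  if (!"sample_id" %in% names(data)) {
    data$sample_id <- sprintf("S%04d", seq_len(nrow(data)))
  }
  data$sample_id <- as.character(data$sample_id)
  if (!"patient_id" %in% names(data)) data$patient_id <- NA_character_
  data$patient_id <- as.character(data$patient_id)
  data$fio2 <- normalize_fio2(data$fio2)
  # canonical column order: the schema columns first, extras after
  dplyr::relocate(data, dplyr::any_of(names(csv_schema)))
}

# mapping internal column names -> on-disk CSV schema
csv_schema <- c(
  sample_id = "sample_id", patient_id = "patient_id", fio2 = "fio2",
  ph = "ph", pco2 = "pco2_mmhg", po2 = "po2_mmhg", hco3 = "hco3",
  sbe = "sbe", lactate = "lactate", na = "na", k = "k", cl = "cl",
  glucose = "glucose_mgdl", ca_ionized = "ca_ionized",
  albumin = "albumin_gdl", urea = "urea_mgdl",
  creatinine = "creatinine_mgdl", urea_pre = "urea_pre_mgdl",
  urea_post = "urea_post_mgdl", age_years = "age_years",
  mechanically_ventilated = "mechanically_ventilated",
  peep = "peep_cmh2o", on_dialysis = "on_dialysis",
  baseline_ag = "baseline_ag", baseline_hco3 = "baseline_hco3",
  dialysis_session_hours = "dialysis_session_hours",
  ultrafiltrate_volume = "ultrafiltrate_volume_l",
  post_weight = "post_weight_kg"
)

#' Read and write blood gas sample CSV files
#'
#' The on-disk schema carries explicit units in its column names
#' (`pco2_mmhg`, `glucose_mgdl`, `peep_cmh2o`, ...); missing values are empty
#' cells. `read_abg_csv()` maps it onto the internal schema of [as_abg_tbl()];
#' `write_abg_csv()` is its inverse, so a round trip is lossless.
#'
#' @param path File path.
#' @param data A data frame of samples (internal schema).
#' @return `read_abg_csv()` returns a tibble in the internal schema;
#'   `write_abg_csv()` returns `data` invisibly.
#' @export
read_abg_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  present <- csv_schema[csv_schema %in% names(raw)]
  out <- raw
  names(out)[match(present, names(out))] <- names(present)
  as_abg_tbl(out)
}

#' @rdname read_abg_csv
#' @export
write_abg_csv <- function(data, path) {
  data <- as_abg_tbl(data)
  out <- data[, names(csv_schema)]
  names(out) <- unname(csv_schema)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(data)
}

#' Validate blood gas samples against physiological plausibility bounds
#'
#' Returns one finding per violated plausibility invariant (empty tibble for
#' plausible input). A missing mandatory field (`ph`, `pco2`, `hco3`) is a hard
#' error, distinct from plausibility findings. The input is never modified.
#'
#' @param data A data frame of samples (see [as_abg_tbl()]).
#' @param config An [abg_config()] (unused bounds are the fixed plausibility
#'   limits: pH 6.5-8.0, FiO2 0.21-1.0, positive tensions/concentrations).
#' @return A tibble with columns `sample_id`, `field`, `value`, `message`.
#' @examples
#' abg_validate(data.frame(ph = 7.41, pco2 = 39, hco3 = 24.9))
#' @export
abg_validate <- function(data, config = NULL) {
  data <- as_abg_tbl(data)
  for (field in c("ph", "pco2", "hco3")) {
    if (anyNA(data[[field]])) {
      stop(
        "mandatory field `", field, "` missing for sample(s): ",
        paste(data$sample_id[is.na(data[[field]])], collapse = ", "),
        call. = FALSE
      )
    }
  }
  bounds <- list(
    ph = c(6.5, 8.0),
    fio2 = c(0.21, 1.0),
    pco2 = c(1e-9, Inf),
    po2 = c(1e-9, Inf),
    hco3 = c(1e-9, Inf),
    lactate = c(1e-9, Inf)
  )
  findings <- purrr::imap(bounds, function(b, field) {
    v <- data[[field]]
    bad <- !is.na(v) & (v < b[1] | v > b[2])
    if (!any(bad)) {
      return(NULL)
    }
    tibble::tibble(
      sample_id = data$sample_id[bad],
      field = field,
      value = v[bad],
      message = sprintf(
        "%s = %g outside plausible bounds [%g, %g]",
        field, v[bad], b[1], b[2]
      )
    )
  })
  out <- dplyr::bind_rows(findings)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      sample_id = character(), field = character(),
      value = numeric(), message = character()
    )
  }
  out
}

#' Flag analytes against the normal reference ranges
#'
#' Flags each of pH, pCO2, HCO3, SBE and lactate as `"low"`, `"normal"` or
#' `"high"` against the configured reference ranges. Band endpoints are
#' inclusive: a value exactly on either endpoint is `"normal"`. Missing values
#' flag as `NA`.
#'
#' @inheritParams abg_validate
#' @return The input tibble with added character columns `ph_flag`,
#'   `pco2_flag`, `hco3_flag`, `sbe_flag`, `lactate_flag`.
#' @examples
#' abg_flag_ranges(data.frame(ph = 7.40, pco2 = 46, hco3 = 24))
#' @export
abg_flag_ranges <- function(data, config = NULL) {
  config <- as_config(config)
  data <- as_abg_tbl(data)
  for (field in c("ph", "pco2", "hco3", "sbe", "lactate")) {
    data[[paste0(field, "_flag")]] <-
      range_flag(data[[field]], config$ranges[[field]])
  }
  data
}

range_flag <- function(x, band) {
  dplyr::case_when(
    is.na(x) ~ NA_character_,
    x < band[1] ~ "low",
    x > band[2] ~ "high",
    TRUE ~ "normal"
  )
}
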