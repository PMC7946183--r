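#' Unit conversions for blood gas and biochemistry quantities
#'
#' Canonical internal units are mmHg for gas tensions, mmol/L for electrolytes
#' and bicarbonate, mg/dL for glucose/urea/creatinine and g/dL for albumin.
#' These converters move between those and the SI alternatives.
#'
#' `kpa_to_mmhg()` multiplies by 7.5; `mmhg_to_kpa()` divides by 7.5.
#' `glucose_mmol_to_mgdl()` multiplies by 18. `urea_to_bun()` divides urea
#' (mg/dL) by 2.14, the urea-to-urea-nitrogen molecular weight ratio.
#'
#' @param x Numeric vector of values to convert (must be non-negative for the
#'   pressure converters).
#' @return Numeric vector of converted values.
#' @examples
#' kpa_to_mmhg(6) # 45 mmHg
#' mmhg_to_kpa(kpa_to_mmhg(5.3)) # round trip
#' urea_to_bun(49) # ~22.9 mg/dL BUN
#' @name units
NULL

KPA_PER_MMHG <- 7.5
UREA_TO_BUN <- 2.14

#' @rdname units
#' @export
kpa_to_mmhg <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("pressure must be non-negative", call. = FALSE)
  }
  x * KPA_PER_MMHG
}

#' @rdname units
#' @export
mmhg_to_kpa <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("pressure must be non-negative", call. = FALSE)
  }
  x / KPA_PER_MMHG
}

#' @rdname units
#' @export
glucose_mmol_to_mgdl <- function(x) x * 18

#' @rdname units
#' @export
glucose_mgdl_to_mmol <- function(x) x / 18

#' @rdname units
#' @export
urea_to_bun <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) stop("urea must be positive", call. = FALSE)
  x / UREA_TO_BUN
}

#' Normalize inspired oxygen fraction
#'
#' Accepts FiO2 as a fraction (0.21-1.0) or a percentage (21-100); values
#' greater than 1 are interpreted as percent and divided by 100.
#'
#' @param fio2 Numeric vector.
#' @return Numeric vector of FiO2 as a fraction.
#' @examples
#' normalize_fio2(c(0.4, 40)) # both 0.40
#' @export
normalize_fio2 <- function(fio2) {
  out <- ifelse(!is.na(fio2) & fio2 > 1, fio2 / 100, fio2)
  bad <- !is.na(out) & (out < 0.21 | out > 1)
  if (any(bad)) {
    stop(
      "FiO2 outside [0.21, 1.00] after normalization: ",
      paste(signif(out[bad], 3), collapse = ", "),
      call. = FALSE
    )
  }
  out
}
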