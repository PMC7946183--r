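#' Interpret arterial blood gas samples
#'
#' Runs the four interpretation stages in fixed order — safety (internal
#' consistency + life-threat screening), oxygenation, acid-base
#' classification, renal — and renders a deterministic narrative report per
#' sample. Safety failures annotate the acid-base reading ("interpret with
#' caution") but never abort downstream stages; stages whose inputs are
#' absent are marked not assessable rather than omitted.
#'
#' @inheritParams abg_validate
#' @param tolerance Henderson consistency tolerance override.
#' @param cause_map See [abg_classify()].
#' @return A tibble with one row per sample, in input order: identifiers, the
#'   per-stage columns of [assess_safety()], [assess_oxygenation()],
#'   [abg_classify()] and [assess_renal()], and `rendered_text`.
#' @examples
#' abg_interpret(data.frame(
#'   ph = 7.41, pco2 = 39, po2 = 106, hco3 = 24.9, sbe = 0.05,
#'   lactate = 1.16, fio2 = 0.40, mechanically_ventilated = TRUE, peep = 5
#' ))$rendered_text
#' @export
abg_interpret <- function(data, config = NULL, tolerance = NULL,
                          cause_map = abg_cause_map()) {
  config <- as_config(config)
  data <- as_abg_tbl(data)
  findings <- abg_validate(data, config) # hard error on missing mandatory
  if (nrow(findings) > 0L) {
    warning(
      "implausible values in sample(s) ",
      paste(unique(findings$sample_id), collapse = ", "),
      "; see abg_validate()",
      call. = FALSE
    )
  }
  safety <- assess_safety(data, tolerance = tolerance, config = config)
  out <- assess_oxygenation(data, config = config)
  out <- abg_classify(out, config = config, cause_map = cause_map)
  out <- assess_renal(out, config = config)
  out$consistent <- safety$consistent
  out$relative_discrepancy <- safety$relative_discrepancy
  out$safety_advice <- safety$advice
  out$alerts <- safety$alerts
  out$n_alerts <- safety$n_alerts
  out$rendered_text <- render_report(out)
  out
}

render_report <- function(out) {
  purrr::pmap_chr(
    list(seq_len(nrow(out))),
    function(i) {
      row <- out[i, ]
      alerts <- row$alerts[[1]]
      lines <- c(
        sprintf("== ABG interpretation: sample %s ==", row$sample_id),
        "-- Safety --",
        if (row$consistent) {
          sprintf(
            "Internal consistency: OK (measured vs expected [H+] differ by %.1f%%).",
            100 * row$relative_discrepancy
          )
        } else {
          c(
            sprintf(
              "Internal consistency: FAILED (discrepancy %.1f%%). Check: %s.",
              100 * row$relative_discrepancy,
              paste(row$safety_advice[[1]], collapse = "; ")
            )
          )
        },
        if (nrow(alerts) > 0) {
          sprintf(
            "LIFE-THREAT ALERT: %s (%s = %g, threshold %g).",
            alerts$alert, alerts$analyte, alerts$value, alerts$threshold
          )
        } else {
          "No life-threatening values on the screened analytes."
        },
        "-- Oxygenation --",
        row$oxygenation_verdict,
        "-- Acid-base --",
        row$narrative,
        if (length(row$causes[[1]]) > 0) {
          paste0("Possible causes: ", paste(row$causes[[1]], collapse = "; "), ".")
        },
        "-- Renal --",
        if (is.na(row$bcr)) {
          "BUN:creatinine ratio not assessable (urea/creatinine missing)."
        } else {
          sprintf(
            "BUN %.1f mg/dL, BUN:creatinine ratio %.1f: %s pattern.%s",
            row$bun, row$bcr, row$bcr_pattern,
            if (length(row$renal_causes[[1]]) > 0) {
              paste0(
                " Consider: ",
                paste(row$renal_causes[[1]], collapse = "; "), "."
              )
            } else {
              ""
            }
          )
        },
        if (!is.na(row$urr)) {
          sprintf(
            "Dialysis: URR %.1f%% (%s), Kt/V %.2f.",
            row$urr, ifelse(row$urr_adequate, "adequate", "inadequate"),
            row$kt_v
          )
        }
      )
      paste(lines, collapse = "\n")
    }
  )
}

#' Write interpretation reports as JSON
#'
#' Serializes the output of [abg_interpret()] into a JSON array with stable
#' per-stage keys (`safety`, `oxygenation`, `acid_base`, `renal`) plus the
#' rendered text. Full numeric precision is retained.
#'
#' @param reports Output of [abg_interpret()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(reports, path) {
  payload <- purrr::map(seq_len(nrow(reports)), function(i) {
    row <- reports[i, ]
    list(
      sample_id = row$sample_id,
      safety = list(
        consistent = row$consistent,
        measured_hplus = hplus_from_ph(row$ph),
        expected_hplus = expected_hplus_henderson(row$pco2, row$hco3),
        relative_discrepancy = row$relative_discrepancy,
        advice = row$safety_advice[[1]],
        life_threat_alerts = row$alerts[[1]]
      ),
      oxygenation = list(
        pf_ratio = row$pf_ratio,
        ards_band = row$ards_band,
        alveolar_po2 = row$alveolar_po2,
        aa_gradient = row$aa_gradient,
        aa_gradient_normal_limit = row$aa_gradient_normal_limit,
        verdict = row$oxygenation_verdict
      ),
      acid_base = list(
        category_code = row$category_code,
        category_label = row$category_label,
        subcategory = row$subcategory,
        anion_gap = row$anion_gap,
        corrected_anion_gap = row$corrected_anion_gap,
        delta_ratio = row$delta_ratio,
        compensation_status = row$compensation_status,
        chronicity = row$chronicity,
        narrative = row$narrative,
        causes = row$causes[[1]]
      ),
      renal = list(
        bun = row$bun, bcr = row$bcr, bcr_pattern = row$bcr_pattern,
        urr = row$urr, urr_adequate = row$urr_adequate, kt_v = row$kt_v,
        causes = row$renal_causes[[1]]
      ),
      rendered_text = row$rendered_text
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
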