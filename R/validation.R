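#' Agreement analysis of a rater-study table
#'
#' Runs the three-rater adjudication ([adjudicate()]) and computes observed
#' agreement and Cohen's kappa of the software against rater A, rater B and
#' the adjudicated consensus ("clinicians result"). Samples where the compared
#' human label is 9 ("I am not sure"), or where no consensus exists, are
#' excluded from the corresponding comparison (configurable).
#'
#' @param data A data frame with columns `label_a`, `label_b`, `software` and
#'   optionally `label_c` and `sample_id`.
#' @param exclude_unsure Drop pairs in which the human label is 9 (default
#'   `TRUE`).
#' @param confidence Confidence level for the kappa intervals.
#' @return An object of class `abg_agreement`: a list with the adjudicated
#'   `records` tibble and a `comparisons` list of `abg_kappa` objects keyed
#'   `clinician_a`, `clinician_b`, `consensus`.
#' @examples
#' recs <- data.frame(label_a = c(1, 2, 0), label_b = c(1, 2, 0),
#'                    software = c(1, 2, 3))
#' agr <- abg_agreement(recs)
#' glance(agr)
#' @export
abg_agreement <- function(data, exclude_unsure = TRUE, confidence = 0.95) {
  records <- adjudicate(data)
  compare <- function(labels) {
    keep <- !is.na(labels)
    if (exclude_unsure) keep <- keep & labels != 9L
    cohen_kappa(labels[keep], records$software[keep], confidence = confidence)
  }
  comparisons <- list(
    clinician_a = compare(records$label_a),
    clinician_b = compare(records$label_b),
    consensus = compare(records$consensus)
  )
  structure(
    list(records = records, comparisons = comparisons),
    class = "abg_agreement"
  )
}

#' @export
print.abg_agreement <- function(x, ...) {
  cat("Rater-study agreement analysis (", nrow(x$records), " records)\n",
    sep = ""
  )
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.abg_agreement <- function(x, ...) {
  purrr::imap_dfr(x$comparisons, function(k, nm) {
    tibble::tibble(
      comparison = nm, n = k$n,
      observed_agreement = k$observed_agreement,
      kappa = k$kappa, conf.low = k$ci[1], conf.high = k$ci[2],
      p.value = k$p_value
    )
  })
}

#' @export
glance.abg_agreement <- function(x, ...) {
  k <- x$comparisons$consensus
  tibble::tibble(
    n = k$n, observed_agreement = k$observed_agreement, kappa = k$kappa,
    conf.low = k$ci[1], conf.high = k$ci[2], p.value = k$p_value,
    concordant = sum(x$records$status == "concordant"),
    partial_congruent = sum(x$records$status == "partial-congruent"),
    discordant = sum(x$records$status == "discordant")
  )
}

#' Per-category one-vs-rest diagnostic accuracy
#'
#' For every category present (or the supplied set), dichotomizes the
#' reference vs the software labels one-vs-rest and computes the accuracy
#' statistic set of [accuracy_stats()] with Wilson intervals and likelihood
#' ratios. Pairs where either label is 9 or the reference is `NA` are
#' excluded.
#'
#' @param data A data frame holding the two label columns.
#' @param reference,software Column names (strings) of the reference
#'   (adjudicated/true) and software labels. Defaults `"consensus"` and
#'   `"software"`.
#' @param categories Integer vector of category codes to tabulate; defaults to
#'   all codes present in the reference.
#' @param confidence Confidence level.
#' @return An object of class `abg_accuracy`: a tibble with one row per
#'   category (`category`, `label`, the counts and all statistics).
#' @examples
#' d <- data.frame(consensus = c(0, 0, 1, 1), software = c(0, 0, 1, 0))
#' abg_diagnostic_accuracy(d)
#' @export
abg_diagnostic_accuracy <- function(data, reference = "consensus",
                                    software = "software",
                                    categories = NULL, confidence = 0.95) {
  stopifnot(reference %in% names(data), software %in% names(data))
  ref <- as.integer(data[[reference]])
  soft <- as.integer(data[[software]])
  keep <- !is.na(ref) & !is.na(soft) & ref != 9L & soft != 9L
  ref <- ref[keep]
  soft <- soft[keep]
  if (is.null(categories)) categories <- sort(unique(ref))
  rows <- purrr::map_dfr(categories, function(k) {
    counts <- one_vs_rest_counts(ref, soft, k)
    stats <- accuracy_stats(counts$tp, counts$fp, counts$fn, counts$tn,
      confidence = confidence
    )
    dplyr::bind_cols(
      tibble::tibble(category = k, label = abg_category_label(k)), stats
    )
  })
  structure(rows, class = c("abg_accuracy", class(rows)))
}

#' @export
tidy.abg_accuracy <- function(x, ...) {
  long <- tibble::as_tibble(x) |>
    dplyr::select(
      "category", "label", "sensitivity", "sensitivity_low",
      "sensitivity_high", "specificity", "specificity_low",
      "specificity_high", "accuracy", "accuracy_low", "accuracy_high",
      "ppv", "ppv_low", "ppv_high", "npv", "npv_low", "npv_high",
      "prevalence", "prevalence_low", "prevalence_high"
    ) |>
    tidyr::pivot_longer(
      -c("category", "label"),
      names_to = c("statistic", "bound"),
      names_pattern = "^(sensitivity|specificity|accuracy|ppv|npv|prevalence)(_low|_high)?$"
    ) |>
    dplyr::mutate(
      bound = dplyr::if_else(.data$bound == "", "estimate",
        sub("^_", "", .data$bound)
      )
    ) |>
    tidyr::pivot_wider(names_from = "bound", values_from = "value")
  long
}

#' @export
glance.abg_accuracy <- function(x, ...) {
  tibble::tibble(
    n_categories = nrow(x),
    n = max(x$n),
    mean_sensitivity = mean(x$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$specificity, na.rm = TRUE),
    min_accuracy = min(x$accuracy, na.rm = TRUE)
  )
}

#' Forest plot of per-category accuracy statistics
#'
#' @param object An `abg_accuracy` object.
#' @param statistics Which statistics to facet (default sensitivity,
#'   specificity, accuracy).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abg_accuracy <- function(object,
                                  statistics = c(
                                    "sensitivity", "specificity", "accuracy"
                                  ),
                                  ...) {
  long <- tidy(object) |>
    dplyr::filter(.data$statistic %in% statistics)
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$estimate, y = stats::reorder(.data$label, .data$category),
      xmin = .data$low, xmax = .data$high
    )
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::labs(
      x = "percent (Wilson 95% CI)", y = NULL,
      title = "Per-category diagnostic accuracy (one-vs-rest)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Run a full rater-study validation and write its tables
#'
#' Reads (or accepts) a validation table with columns `sample_id`, `label_a`,
#' `label_b`, `label_c`, `software`, runs [abg_agreement()] and
#' [abg_diagnostic_accuracy()] against the adjudicated consensus, and
#' optionally writes the agreement table, the per-category accuracy table and
#' the likelihood-ratio / predictive-value tables as CSV plus a combined JSON
#' file. Reported numbers are rounded to one decimal in the CSV layer; full
#' precision is retained in the returned objects and the JSON.
#'
#' @param data A data frame or a path to a CSV file in the validation schema.
#' @param output_dir Directory to write `agreement.csv`, `accuracy.csv`,
#'   `likelihood_ratios.csv`, `predictive_values.csv` and `validation.json`;
#'   `NULL` (default) writes nothing.
#' @param confidence Confidence level.
#' @return A list with elements `agreement` (`abg_agreement`) and `accuracy`
#'   (`abg_accuracy`).
#' @export
run_validation <- function(data, output_dir = NULL, confidence = 0.95) {
  if (is.character(data)) {
    data <- readr::read_csv(data, show_col_types = FALSE, progress = FALSE)
  }
  agreement <- abg_agreement(data, confidence = confidence)
  accuracy <- abg_diagnostic_accuracy(
    agreement$records,
    reference = "consensus", software = "software", confidence = confidence
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    fmt1 <- function(df) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], round, digits = 1)
      df
    }
    readr::write_csv(
      fmt1(tidy(agreement)), file.path(output_dir, "agreement.csv"),
      progress = FALSE
    )
    acc_tbl <- tibble::as_tibble(accuracy)
    readr::write_csv(
      fmt1(dplyr::select(
        acc_tbl, "category", "label", "n", "tp", "fp", "fn", "tn",
        dplyr::starts_with("sensitivity"), dplyr::starts_with("specificity"),
        dplyr::starts_with("accuracy")
      )),
      file.path(output_dir, "accuracy.csv"),
      progress = FALSE
    )
    readr::write_csv(
      fmt1(dplyr::select(
        acc_tbl, "category", "label", "lr_positive", "lr_negative",
        "lr_inverse_negative"
      )),
      file.path(output_dir, "likelihood_ratios.csv"),
      progress = FALSE
    )
    readr::write_csv(
      fmt1(dplyr::select(
        acc_tbl, "category", "label", dplyr::starts_with("ppv"),
        dplyr::starts_with("npv"), dplyr::starts_with("prevalence")
      )),
      file.path(output_dir, "predictive_values.csv"),
      progress = FALSE
    )
    jsonlite::write_json(
      list(
        agreement = tidy(agreement),
        accuracy = acc_tbl
      ),
      file.path(output_dir, "validation.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  list(agreement = agreement, accuracy = accuracy)
}
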