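#' Cohort specification for the synthetic generator
#'
#' Bundles the design of a simulated validation study: cohort size, category
#' prevalences (defaults: the per-category case counts of the validation
#' study, renormalised), per-rater probability of reproducing the true label,
#' and the misclassification kernel used when a rater errs.
#'
#' @param n_samples Number of samples.
#' @param prevalences Numeric vector of 9 category prevalences (codes 0-8);
#'   normalised to sum to 1.
#' @param rater_accuracy Named numeric vector with elements `a`, `b`, `c` in
#'   (0, 1]: each rater's probability of reproducing the true label. The
#'   defaults for raters a and b emulate the per-rater observed agreement of
#'   the validation study (81.7 and 74.6 percent against a software whose
#'   labels match the truth); no per-rater figure exists for the third
#'   adjudicating rater, taken as 0.85.
#' @param confusion_kernel A 9x9 row-stochastic matrix with zero diagonal:
#'   row i gives the distribution of the wrong label emitted when the true
#'   category is i. Default: uniform over the other eight categories.
#' @param seed Integer seed recorded in the spec and used by
#'   [generate_cohort()].
#' @return A list of class `abg_cohort_spec`.
#' @examples
#' abg_cohort_spec(n_samples = 50, seed = 1)
#' @export
abg_cohort_spec <- function(n_samples = 346,
                            prevalences = c(60, 34, 18, 33, 36, 48, 51, 31, 31),
                            rater_accuracy = c(a = 0.817, b = 0.746, c = 0.85),
                            confusion_kernel = NULL,
                            seed = 1L) {
  stopifnot(n_samples >= 0, length(prevalences) == 9, all(prevalences >= 0))
  prevalences <- prevalences / sum(prevalences)
  stopifnot(
    all(c("a", "b", "c") %in% names(rater_accuracy)),
    all(rater_accuracy > 0 & rater_accuracy <= 1)
  )
  if (is.null(confusion_kernel)) {
    confusion_kernel <- matrix(1 / 8, 9, 9)
    diag(confusion_kernel) <- 0
  }
  stopifnot(
    identical(dim(confusion_kernel), c(9L, 9L)),
    all(abs(rowSums(confusion_kernel) - 1) < 1e-8),
    all(diag(confusion_kernel) == 0)
  )
  structure(
    list(
      n_samples = as.integer(n_samples), prevalences = prevalences,
      rater_accuracy = rater_accuracy, confusion_kernel = confusion_kernel,
      seed = as.integer(seed)
    ),
    class = "abg_cohort_spec"
  )
}

# category geometry: (pCO2, HCO3) sampling boxes per category; the metabolic
# and respiratory primaries embed the expected-compensation band so that the
# derived pH lands in the right region and rejection is rare.
sample_geometry <- function(code, n, config) {
  cc <- config$compensation
  runifn <- function(lo, hi) stats::runif(n, lo, hi)
  if (code == 0L) {
    pco2 <- runifn(36, 44)
    hco3 <- runifn(22.5, 29.5)
  } else if (code == 1L) {
    pco2 <- runifn(22, 33)
    rate <- ifelse(stats::runif(n) < 0.5, cc$resp_acute_alk, cc$resp_chronic_alk)
    hco3 <- cc$hco3_mid + rate * (pco2 - cc$pco2_mid) / 10 + runifn(-1.5, 1.5)
  } else if (code == 2L) {
    pco2 <- runifn(48, 70)
    rate <- ifelse(stats::runif(n) < 0.5, cc$resp_acute_acid, cc$resp_chronic_acid)
    hco3 <- cc$hco3_mid + rate * (pco2 - cc$pco2_mid) / 10 + runifn(-1.5, 1.5)
  } else if (code == 3L) {
    hco3 <- runifn(8, 18)
    pco2 <- cc$winters_slope * hco3 + cc$winters_intercept + runifn(-1.8, 1.8)
  } else if (code == 4L) {
    hco3 <- runifn(31, 40)
    pco2 <- cc$pco2_mid + cc$metalk_slope * (hco3 - cc$hco3_mid) + runifn(-4.5, 4.5)
  } else if (code == 5L) {
    pco2 <- runifn(24, 34)
    hco3 <- runifn(31, 40)
  } else if (code == 6L) {
    pco2 <- runifn(50, 70)
    hco3 <- runifn(12, 20)
  } else if (code == 7L) {
    pco2 <- runifn(16, 22)
    hco3 <- runifn(9, 14)
  } else if (code == 8L) {
    pco2 <- runifn(63, 78)
    hco3 <- runifn(42, 50)
  } else {
    stop("category must be 0-8", call. = FALSE)
  }
  tibble::tibble(pco2 = pco2, hco3 = hco3)
}

#' Generate Henderson-consistent samples of a given acid-base category
#'
#' Draws pCO2 and HCO3 from category-specific geometry (the compensation
#' bands are built into the boxes), derives the pH from the Henderson relation
#' so the triple is internally consistent by construction, jitters HCO3
#' within the consistency tolerance, then rejection-samples until the
#' classification engine returns the requested category — so label fidelity
#' is exact. Electrolytes and context are filled with noise scaled to the
#' marginal medians/IQRs of an adult critical-care cohort.
#'
#' @param category Category code 0-8.
#' @param n Number of samples.
#' @param config An [abg_config()].
#' @param inconsistent If `TRUE`, the reported pH is displaced so the triple
#'   violates the Henderson consistency check (for testing the safety stage);
#'   the classification-fidelity rejection is skipped.
#' @param max_attempts Rejection budget per accepted sample.
#' @return A tibble of `n` samples in the [as_abg_tbl()] schema plus a
#'   `true_category` column.
#' @examples
#' set.seed(1)
#' simulate_abg_samples(3, n = 2)
#' @export
simulate_abg_samples <- function(category, n = 1, config = NULL,
                                 inconsistent = FALSE, max_attempts = 1000) {
  config <- as_config(config)
  stopifnot(length(category) == 1, category %in% 0:8)
  accepted <- NULL
  attempts <- 0
  while (is.null(accepted) || nrow(accepted) < n) {
    need <- n - if (is.null(accepted)) 0 else nrow(accepted)
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop(
        "rejection budget exceeded while generating category ", category,
        ": the geometry box is ill-configured for the current config",
        call. = FALSE
      )
    }
    draw <- sample_geometry(category, max(2 * need, 10), config)
    draw$hco3 <- draw$hco3 * (1 + stats::runif(nrow(draw), -0.02, 0.02))
    ph <- 9 - log10(24 * draw$pco2 / draw$hco3)
    draw$ph <- round(ph, 2)
    draw$pco2 <- round(draw$pco2, 1)
    draw$hco3 <- round(draw$hco3, 1)
    ok <- draw$ph >= 6.8 & draw$ph <= 7.8
    draw <- draw[ok, , drop = FALSE]
    if (nrow(draw) == 0) next
    if (inconsistent) {
      shift <- sample(c(-1, 1), nrow(draw), replace = TRUE) *
        stats::runif(nrow(draw), 0.15, 0.30)
      draw$ph <- pmin(pmax(round(draw$ph + shift, 2), 6.8), 7.8)
    } else {
      code <- classify_core(draw$ph, draw$pco2, draw$hco3, config)$code
      keep <- code == category
      # pure respiratory draws are frankly acidaemic/alkalaemic; the fully
      # compensated normal-pH corner is excluded from the geometry
      if (category == 1L) keep <- keep & draw$ph > config$ranges$ph[2]
      if (category == 2L) keep <- keep & draw$ph < config$ranges$ph[1]
      draw <- draw[keep, , drop = FALSE]
    }
    if (nrow(draw) == 0) next
    accepted <- dplyr::bind_rows(accepted, utils::head(draw, need))
  }
  out <- accepted
  m <- nrow(out)
  out$sbe <- round(out$hco3 - 24 + stats::runif(m, -1, 1), 2)
  out$lactate <- round(pmin(stats::rlnorm(m, log(1.16), 0.55), 12), 2)
  out$po2 <- round(pmin(pmax(stats::rlnorm(m, log(106), 0.38), 40), 400), 0)
  out$fio2 <- round(pmin(pmax(stats::rlnorm(m, log(0.4), 0.3), 0.21), 1), 2)
  out$na <- round(stats::rnorm(m, 139, 4.4), 0)
  out$k <- round(pmax(stats::rnorm(m, 4.1, 0.6), 2.6), 1)
  # the anion gap, not chloride, is the physiologically primitive quantity:
  # metabolic-acidosis samples split between high-gap and normal-gap pictures
  gap <- if (category %in% c(3L, 6L, 7L)) {
    ifelse(stats::runif(m) < 0.5, stats::runif(m, 16, 28), stats::runif(m, 6, 12))
  } else {
    stats::rnorm(m, 8, 2)
  }
  out$cl <- round(out$na - out$hco3 - gap, 0)
  out$glucose <- round(pmax(stats::rnorm(m, 142, 40), 45), 0)
  out$ca_ionized <- round(stats::rnorm(m, 1.15, 0.07), 2)
  out$albumin <- round(pmin(pmax(stats::rnorm(m, 3.3, 0.4), 1.5), 5), 1)
  out$urea <- round(stats::rlnorm(m, log(49), 0.55), 0)
  out$creatinine <- round(stats::rlnorm(m, log(0.82), 0.5), 2)
  out$age_years <- round(stats::runif(m, 18, 88), 0)
  out$mechanically_ventilated <- stats::runif(m) < 0.46
  out$peep <- ifelse(out$mechanically_ventilated,
    sample(5:12, m, replace = TRUE), NA_real_
  )
  out$on_dialysis <- stats::runif(m) < 0.05
  urr_target <- stats::rnorm(m, 65, 5)
  out$urea_pre <- ifelse(out$on_dialysis, out$urea, NA_real_)
  out$urea_post <- ifelse(out$on_dialysis,
    round(out$urea * (1 - pmin(pmax(urr_target, 30), 85) / 100), 0), NA_real_
  )
  out$dialysis_session_hours <- ifelse(out$on_dialysis, 4, NA_real_)
  out$ultrafiltrate_volume <- ifelse(out$on_dialysis,
    round(stats::runif(m, 0.5, 3), 1), NA_real_
  )
  out$post_weight <- ifelse(out$on_dialysis,
    round(stats::rnorm(m, 75, 12), 1), NA_real_
  )
  out$true_category <- category
  as_abg_tbl(out) |> dplyr::mutate(true_category = category)
}

#' Simulate imperfect raters for a labelled cohort
#'
#' Each rater independently keeps the true label with its configured accuracy
#' and otherwise draws a wrong label from the confusion kernel. The software
#' column carries the supplied software labels (by default the true labels,
#' matching a classifier with exact label fidelity). Rater C is elicited only
#' where the adjudication design demands it: when the software agrees with
#' exactly one of A and B.
#'
#' @param true_labels Integer vector of true category codes (0-8).
#' @param spec An [abg_cohort_spec()].
#' @param software Software labels; defaults to `true_labels`.
#' @return A tibble with columns `sample_id`, `label_a`, `label_b`, `label_c`
#'   (`NA` where not elicited) and `software`.
#' @examples
#' set.seed(1)
#' simulate_raters(c(0, 0, 3, 6), abg_cohort_spec(rater_accuracy =
#'   c(a = 1, b = 1, c = 1)))
#' @export
simulate_raters <- function(true_labels, spec = abg_cohort_spec(),
                            software = true_labels) {
  n <- length(true_labels)
  stopifnot(all(true_labels %in% 0:8), length(software) == n)
  draw_rater <- function(accuracy) {
    keep <- stats::runif(n) < accuracy
    wrong <- vapply(true_labels, function(tc) {
      sample(0:8, 1, prob = spec$confusion_kernel[tc + 1L, ])
    }, integer(1))
    ifelse(keep, as.integer(true_labels), wrong)
  }
  a <- draw_rater(spec$rater_accuracy[["a"]])
  b <- draw_rater(spec$rater_accuracy[["b"]])
  cc <- draw_rater(spec$rater_accuracy[["c"]])
  s <- as.integer(software)
  partial <- (s == a) != (s == b)
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    label_a = a, label_b = b,
    label_c = ifelse(partial, cc, NA_integer_),
    software = s
  )
}

#' Generate a full labelled cohort with simulated raters
#'
#' Allocates categories multinomially by the spec prevalences, generates
#' Henderson-consistent samples for each ([simulate_abg_samples()]), attaches
#' software labels (exact by construction) and simulated rater labels, and
#' optionally writes the three CSV files (samples, truth, rater records).
#' Deterministic given `spec$seed`.
#'
#' @param spec An [abg_cohort_spec()].
#' @param output_dir Directory for `samples.csv`, `truth.csv`, `raters.csv`;
#'   `NULL` writes nothing.
#' @param config An [abg_config()].
#' @return A list with tibbles `samples`, `truth`
#'   (`sample_id`, `true_category`) and `raters` (validation schema).
#' @examples
#' cohort <- generate_cohort(abg_cohort_spec(n_samples = 20, seed = 42))
#' table(cohort$truth$true_category)
#' @export
generate_cohort <- function(spec = abg_cohort_spec(), output_dir = NULL,
                            config = NULL) {
  config <- as_config(config)
  set.seed(spec$seed)
  empty <- simulate_abg_samples(0, n = 1, config = config)[0, ]
  if (spec$n_samples == 0L) {
    samples <- empty
  } else {
    cats <- sample(0:8, spec$n_samples, replace = TRUE, prob = spec$prevalences)
    samples <- purrr::map_dfr(0:8, function(k) {
      nk <- sum(cats == k)
      if (nk == 0) {
        return(NULL)
      }
      simulate_abg_samples(k, n = nk, config = config)
    })
    samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  }
  truth <- tibble::tibble(
    sample_id = samples$sample_id, true_category = samples$true_category
  )
  raters <- simulate_raters(samples$true_category, spec)
  raters$sample_id <- samples$sample_id
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_abg_csv(
      dplyr::select(samples, -"true_category"),
      file.path(output_dir, "samples.csv")
    )
    readr::write_csv(truth, file.path(output_dir, "truth.csv"), na = "", progress = FALSE)
    readr::write_csv(raters, file.path(output_dir, "raters.csv"), na = "", progress = FALSE)
  }
  list(samples = samples, truth = truth, raters = raters, spec = spec)
}
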