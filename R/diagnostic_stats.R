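#' Wilson score interval for a binomial proportion
#'
#' The score-based interval, well-behaved near 0 and 1 (it never escapes
#' \[0, 100\] and is never degenerate), reported as percents.
#'
#' @param successes Number of successes (vectorized).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level as a fraction (default 0.95).
#' @return A tibble with columns `estimate`, `low`, `high`, all in percent.
#' @examples
#' wilson_interval(31, 34) # 91.2 (77.0 to 97.0)
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(successes < 0 | successes > n)) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(
    estimate = 100 * p,
    low = 100 * (centre - half),
    high = 100 * (centre + half)
  )
}

#' Observed agreement between two label sequences
#'
#' @param labels_x,labels_y Equal-length vectors of category codes.
#' @return Percent of positions with identical codes.
#' @examples
#' observed_agreement(c(1, 2, 3, 4), c(1, 2, 3, 0)) # 75
#' @export
observed_agreement <- function(labels_x, labels_y) {
  if (length(labels_x) != length(labels_y)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  if (length(labels_x) == 0L) stop("empty label sequences", call. = FALSE)
  100 * mean(labels_x == labels_y)
}

#' Unweighted Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement between two categorical raters over the full
#' cross-tabulation. The confidence interval uses the Fleiss-Cohen-Everitt
#' large-sample variance; the two-sided p-value for kappa = 0 uses the
#' null-hypothesis variance.
#'
#' @inheritParams observed_agreement
#' @param confidence Confidence level (default 0.95).
#' @return An object of class `abg_kappa`: a list with `n`,
#'   `observed_agreement` (percent), `expected_agreement` (percent), `kappa`,
#'   `se`, `ci` (length 2), `p_value` and the cross-tabulation `table`.
#'   Degenerate input (a single category across both sequences) returns
#'   `kappa = NA` (not calculable).
#' @examples
#' k <- cohen_kappa(rep(c(1, 1, 1, 2), 25), rep(c(1, 1, 2, 2), 25))
#' k$kappa
#' @export
cohen_kappa <- function(labels_x, labels_y, confidence = 0.95) {
  if (length(labels_x) != length(labels_y)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  n <- length(labels_x)
  if (n < 2L) stop("need at least two paired labels", call. = FALSE)
  levels <- sort(unique(c(labels_x, labels_y)))
  tab <- table(
    factor(labels_x, levels = levels),
    factor(labels_y, levels = levels)
  )
  p <- tab / n
  po <- sum(diag(p))
  prow <- rowSums(p)
  pcol <- colSums(p)
  pe <- sum(prow * pcol)
  if (length(levels) < 2L || isTRUE(all.equal(pe, 1))) {
    out <- list(
      n = n, observed_agreement = 100 * po, expected_agreement = 100 * pe,
      kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
      p_value = NA_real_, table = tab, confidence = confidence
    )
    return(structure(out, class = "abg_kappa"))
  }
  kappa <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt large-sample variance of kappa-hat
  k_levels <- length(levels)
  a <- 0
  for (i in seq_len(k_levels)) {
    a <- a + p[i, i] * (1 - (prow[i] + pcol[i]) * (1 - kappa))^2
  }
  b <- 0
  for (i in seq_len(k_levels)) {
    for (j in seq_len(k_levels)) {
      if (i != j) b <- b + p[i, j] * (pcol[i] + prow[j])^2
    }
  }
  b <- b * (1 - kappa)^2
  cterm <- (kappa - pe * (1 - kappa))^2
  var_k <- (a + b - cterm) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))

  # null-variance form for the test of kappa = 0
  var0 <- (pe + pe^2 - sum(prow * pcol * (prow + pcol))) / (n * (1 - pe)^2)
  z0 <- kappa / sqrt(var0)
  p_value <- 2 * stats::pnorm(-abs(z0))

  z <- stats::qnorm(1 - (1 - confidence) / 2)
  out <- list(
    n = n, observed_agreement = 100 * po, expected_agreement = 100 * pe,
    kappa = kappa, se = se,
    ci = c(max(-1, kappa - z * se), min(1, kappa + z * se)),
    p_value = p_value, table = tab, confidence = confidence
  )
  structure(out, class = "abg_kappa")
}

#' @export
print.abg_kappa <- function(x, ...) {
  cat("Cohen's kappa (unweighted)\n")
  cat(sprintf(
    "  n = %d, observed agreement %.1f%%\n", x$n, x$observed_agreement
  ))
  if (is.na(x$kappa)) {
    cat("  kappa not calculable (single-category input)\n")
  } else {
    cat(sprintf(
      "  kappa %.2f (%.0f%% CI %.2f to %.2f), p %s\n",
      x$kappa, 100 * x$confidence, x$ci[1], x$ci[2],
      ifelse(x$p_value < 0.001, "< 0.001", sprintf("= %.3f", x$p_value))
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.abg_kappa <- function(x, ...) {
  tibble::tibble(
    estimate = x$kappa, std.error = x$se,
    conf.low = x$ci[1], conf.high = x$ci[2], p.value = x$p_value
  )
}

#' @export
glance.abg_kappa <- function(x, ...) {
  tibble::tibble(
    n = x$n, observed_agreement = x$observed_agreement,
    expected_agreement = x$expected_agreement, kappa = x$kappa,
    conf.low = x$ci[1], conf.high = x$ci[2], p.value = x$p_value
  )
}

#' Three-rater adjudication of software labels
#'
#' The study-design questionnaire logic: the software label is concordant when
#' it coincides with both primary raters A and B; when it agrees with exactly
#' one of them, a third independent rater C is required and the record is
#' partially congruent exactly when C sides with the software; otherwise the
#' record is discordant. The consensus label is A when A = B, else the
#' majority of A, B and C (`NA` when the three are pairwise distinct and no
#' majority exists).
#'
#' @param data A data frame with columns `label_a`, `label_b`, `software` and
#'   optionally `label_c` (category codes 0-9; `label_c` may be `NA` where not
#'   elicited, but is required whenever the software agrees with exactly one
#'   of A and B).
#' @return The input tibble with added columns `status` (`"concordant"`,
#'   `"partial-congruent"`, `"discordant"`), `congruent` (logical: software
#'   matched the adjudicated opinion) and `consensus`.
#' @examples
#' adjudicate(data.frame(label_a = 1, label_b = 2, software = 1, label_c = 1))
#' @export
adjudicate <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("label_a", "label_b", "software")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"label_c" %in% names(data)) data$label_c <- NA_integer_
  a <- as.integer(data$label_a)
  b <- as.integer(data$label_b)
  s <- as.integer(data$software)
  cc <- as.integer(data$label_c)
  if (anyNA(a) || anyNA(b) || anyNA(s)) {
    stop("label_a, label_b and software must be complete", call. = FALSE)
  }

  partial <- (s == a) != (s == b) # software agrees with exactly one
  needs_c <- partial & is.na(cc)
  if (any(needs_c)) {
    stop(
      "label_c required when the software agrees with exactly one of A and B ",
      "(rows: ", paste(which(needs_c), collapse = ", "), ")",
      call. = FALSE
    )
  }
  status <- dplyr::case_when(
    s == a & s == b ~ "concordant",
    partial & cc == s ~ "partial-congruent",
    TRUE ~ "discordant"
  )
  majority3 <- function(a, b, cc) {
    dplyr::case_when(
      a == b ~ a,
      !is.na(cc) & cc == a ~ a,
      !is.na(cc) & cc == b ~ b,
      TRUE ~ NA_integer_
    )
  }
  consensus <- dplyr::case_when(
    a == b ~ a,
    partial & cc == s ~ s,
    TRUE ~ majority3(a, b, cc)
  )
  data$status <- status
  data$congruent <- status %in% c("concordant", "partial-congruent")
  data$consensus <- consensus
  data
}

#' One-vs-rest confusion counts for one category
#'
#' Dichotomizes a multi-category comparison into "category k" vs "any other":
#' tp when both the reference and the software equal the category, fp when only
#' the software does, fn when only the reference does, tn when neither.
#'
#' @param reference,software Aligned vectors of category codes.
#' @param category The category code to dichotomize on.
#' @return A one-row tibble with integer columns `tp`, `fp`, `fn`, `tn`.
#' @examples
#' one_vs_rest_counts(c(1, 1, 2, 3), c(1, 2, 2, 3), 1)
#' @export
one_vs_rest_counts <- function(reference, software, category) {
  if (length(reference) != length(software)) {
    stop("sequences must be aligned", call. = FALSE)
  }
  rpos <- reference == category
  spos <- software == category
  tibble::tibble(
    tp = sum(rpos & spos), fp = sum(!rpos & spos),
    fn = sum(rpos & !spos), tn = sum(!rpos & !spos)
  )
}

#' Diagnostic accuracy statistics from a 2x2 confusion table
#'
#' Sensitivity, specificity, global accuracy, positive and negative predictive
#' values and prevalence, each as a percent with its Wilson interval computed
#' on its own denominator, plus the likelihood ratios of
#' [likelihood_ratios()]. A zero denominator yields `NA` (not calculable).
#'
#' @param tp,fp,fn,tn Confusion counts (non-negative integers).
#' @param confidence Confidence level for the Wilson intervals.
#' @return A one-row tibble: the counts, `n`, then for each statistic the
#'   point estimate and `_low`/`_high` bounds in percent, then `lr_positive`,
#'   `lr_negative`, `lr_inverse_negative`.
#' @examples
#' accuracy_stats(54, 8, 6, 276)
#' @export
accuracy_stats <- function(tp, fp, fn, tn, confidence = 0.95) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  n <- tp + fp + fn + tn
  if (n < 1) stop("empty confusion counts", call. = FALSE)
  stat <- function(successes, denom) {
    if (denom == 0) {
      return(tibble::tibble(estimate = NA_real_, low = NA_real_, high = NA_real_))
    }
    wilson_interval(successes, denom, confidence)
  }
  sens <- stat(tp, tp + fn)
  spec <- stat(tn, tn + fp)
  acc <- stat(tp + tn, n)
  ppv_ci <- stat(tp, tp + fp)
  npv_ci <- stat(tn, tn + fn)
  prev_ci <- stat(tp + fn, n)
  lrs <- likelihood_ratios(tp, fp, fn, tn)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    sensitivity = sens$estimate, sensitivity_low = sens$low,
    sensitivity_high = sens$high,
    specificity = spec$estimate, specificity_low = spec$low,
    specificity_high = spec$high,
    accuracy = acc$estimate, accuracy_low = acc$low, accuracy_high = acc$high,
    ppv = ppv_ci$estimate, ppv_low = ppv_ci$low, ppv_high = ppv_ci$high,
    npv = npv_ci$estimate, npv_low = npv_ci$low, npv_high = npv_ci$high,
    prevalence = prev_ci$estimate, prevalence_low = prev_ci$low,
    prevalence_high = prev_ci$high,
    lr_positive = lrs$lr_positive, lr_negative = lrs$lr_negative,
    lr_inverse_negative = lrs$lr_inverse_negative
  )
}

#' Likelihood ratios from a 2x2 confusion table
#'
#' LR+ = sensitivity / (1 - specificity), not calculable (`NA`) when there are
#' no false positives; LR- = (1 - sensitivity) / specificity; the inverse
#' negative likelihood ratio is 1 / LR-, not calculable when there are no
#' false negatives. All computed from unrounded proportions.
#'
#' @inheritParams accuracy_stats
#' @return A one-row tibble with columns `lr_positive`, `lr_negative`,
#'   `lr_inverse_negative`.
#' @examples
#' likelihood_ratios(54, 8, 6, 276) # LR+ 32.0, inverse LR- 9.7
#' likelihood_ratios(31, 0, 3, 310) # LR+ not calculable
#' @export
likelihood_ratios <- function(tp, fp, fn, tn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  lr_pos <- if (is.na(sens) || is.na(spec) || fp == 0) {
    NA_real_ # no false positives: not calculable
  } else {
    sens / (1 - spec)
  }
  lr_neg <- if (is.na(sens) || is.na(spec) || spec == 0) {
    NA_real_
  } else {
    (1 - sens) / spec
  }
  lr_inv_neg <- if (is.na(lr_neg) || fn == 0) NA_real_ else 1 / lr_neg
  tibble::tibble(
    lr_positive = lr_pos, lr_negative = lr_neg,
    lr_inverse_negative = lr_inv_neg
  )
}
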