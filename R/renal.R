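#' BUN:creatinine ratio with pattern
#'
#' BUN is derived from urea (mg/dL) by dividing by 2.14 ([urea_to_bun()]).
#' Pattern bounds (configurable): ratio > 20 prerenal, 10-20 normal,
#' < 10 intrinsic.
#'
#' @param bun Blood urea nitrogen, mg/dL.
#' @param creatinine Serum creatinine, mg/dL.
#' @param config An [abg_config()].
#' @return A tibble with columns `bcr` and `bcr_pattern`.
#' @examples
#' bcr(22.9, 0.82) # ~27.9, prerenal
#' @export
bcr <- function(bun, creatinine, config = NULL) {
  config <- as_config(config)
  rn <- config$renal
  ratio <- ifelse(
    is.na(bun) | is.na(creatinine) | creatinine <= 0, NA_real_,
    bun / creatinine
  )
  tibble::tibble(
    bcr = ratio,
    bcr_pattern = dplyr::case_when(
      is.na(ratio) ~ "not-assessable",
      ratio > rn$bcr_high ~ "prerenal",
      ratio < rn$bcr_low ~ "intrinsic",
      TRUE ~ "normal"
    )
  )
}

bcr_causes <- list(
  prerenal = c(
    "hypovolaemia / dehydration", "gastrointestinal bleeding",
    "high protein load or catabolic state", "low renal perfusion (heart failure)"
  ),
  intrinsic = c(
    "intrinsic renal injury (acute tubular necrosis)",
    "low protein intake or malnutrition", "liver disease", "rhabdomyolysis"
  ),
  normal = character()
)

#' Urea reduction ratio across a dialysis session
#'
#' URR = 100 x (pre - post) / pre, in percent; unit-invariant in the urea
#' scale. A post value above pre suggests a sample swap and is an error.
#'
#' @param urea_pre,urea_post Pre- and post-dialysis urea (any consistent
#'   unit, conventionally mg/dL).
#' @param config An [abg_config()]; `config$renal$urr_adequate` (default 65)
#'   is the adequacy threshold in percent.
#' @return A tibble with columns `urr` (percent) and `urr_adequate`.
#' @examples
#' urr(100, 37) # 63 percent
#' @export
urr <- function(urea_pre, urea_post, config = NULL) {
  config <- as_config(config)
  if (any(urea_post > urea_pre, na.rm = TRUE)) {
    stop("post-dialysis urea exceeds pre-dialysis urea: check for sample swap",
      call. = FALSE
    )
  }
  if (any(urea_post <= 0 | urea_pre <= 0, na.rm = TRUE)) {
    stop("urea values must be positive", call. = FALSE)
  }
  pct <- 100 * (urea_pre - urea_post) / urea_pre
  tibble::tibble(urr = pct, urr_adequate = pct >= config$renal$urr_adequate)
}

#' Single-pool Kt/V (Daugirdas second-generation formula)
#'
#' Kt/V = -ln(R - 0.008 t) + (4 - 3.5 R) x UF / W, with R the post/pre urea
#' ratio, t the session length in hours, UF the ultrafiltrate volume in litres
#' and W the post-dialysis weight in kg. Reproduces the conventional anchor
#' that a Kt/V of 1.2 corresponds to a URR of about 63 percent. `NA` when
#' R - 0.008 t <= 0 (not assessable).
#'
#' @param urea_pre,urea_post Pre-/post-dialysis urea (same unit).
#' @param session_hours Session length, hours.
#' @param ultrafiltrate Ultrafiltrate volume, litres.
#' @param post_weight Post-dialysis weight, kg.
#' @return Numeric Kt/V (unitless).
#' @examples
#' kt_v_daugirdas(100, 37, 4, 2.1, 70) # ~1.17
#' @export
kt_v_daugirdas <- function(urea_pre, urea_post, session_hours = 4,
                           ultrafiltrate = 0, post_weight = NA_real_) {
  if (any(urea_pre <= 0 | urea_post <= 0, na.rm = TRUE)) {
    stop("urea values must be positive", call. = FALSE)
  }
  r <- urea_post / urea_pre
  if (any(r > 1, na.rm = TRUE)) {
    stop("post/pre urea ratio exceeds 1: check for sample swap", call. = FALSE)
  }
  inner <- r - 0.008 * session_hours
  uf_term <- ifelse(
    !is.na(ultrafiltrate) & ultrafiltrate > 0,
    (4 - 3.5 * r) * ultrafiltrate / post_weight,
    0
  )
  ifelse(inner <= 0, NA_real_, -log(inner) + uf_term)
}

#' Renal stage assessment
#'
#' BUN:creatinine ratio with side-specific candidate causes; for patients
#' flagged `on_dialysis` with pre/post urea available, the URR with its
#' adequacy flag and the Daugirdas Kt/V.
#'
#' @inheritParams abg_validate
#' @return The input tibble with added columns `bun`, `bcr`, `bcr_pattern`,
#'   `urr`, `urr_adequate`, `kt_v` and a `renal_causes` list-column.
#' @examples
#' assess_renal(data.frame(
#'   ph = 7.4, pco2 = 40, hco3 = 24, urea = 49, creatinine = 0.82
#' ))
#' @export
assess_renal <- function(data, config = NULL) {
  config <- as_config(config)
  data <- as_abg_tbl(data)
  data$bun <- ifelse(is.na(data$urea), NA_real_, data$urea / UREA_TO_BUN)
  ratio <- bcr(data$bun, data$creatinine, config)
  data$bcr <- ratio$bcr
  data$bcr_pattern <- ratio$bcr_pattern
  data$renal_causes <- purrr::map(data$bcr_pattern, function(p) {
    if (p %in% names(bcr_causes)) bcr_causes[[p]] else character()
  })

  dialysis <- !is.na(data$on_dialysis) & data$on_dialysis &
    !is.na(data$urea_pre) & !is.na(data$urea_post)
  data$urr <- NA_real_
  data$urr_adequate <- NA
  data$kt_v <- NA_real_
  if (any(dialysis)) {
    u <- urr(data$urea_pre[dialysis], data$urea_post[dialysis], config)
    data$urr[dialysis] <- u$urr
    data$urr_adequate[dialysis] <- u$urr_adequate
    hours <- ifelse(
      is.na(data$dialysis_session_hours[dialysis]), 4,
      data$dialysis_session_hours[dialysis]
    )
    data$kt_v[dialysis] <- kt_v_daugirdas(
      data$urea_pre[dialysis], data$urea_post[dialysis],
      session_hours = hours,
      ultrafiltrate = data$ultrafiltrate_volume[dialysis],
      post_weight = data$post_weight[dialysis]
    )
  }
  data
}
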