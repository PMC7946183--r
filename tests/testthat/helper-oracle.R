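# Independent brute-force reference for the acid-base classifier.
#
# Scalar decision tree written separately from the vectorized engine:
# it flags each axis, then walks an explicit per-branch table, recomputing
# the compensation bands from the documented constants on its own.

oracle_flag <- function(x, lo, hi) {
  if (x < lo) "low" else if (x > hi) "high" else "normal"
}

# expected HCO3 band envelope for a respiratory primary; returns the acute
# band, chronic band and their envelope
oracle_resp_bands <- function(pco2) {
  if (pco2 > 45) {
    acute <- 24 + 1.0 * (pco2 - 40) / 10
    chronic <- 24 + 3.5 * (pco2 - 40) / 10
  } else {
    acute <- 24 + 2.0 * (pco2 - 40) / 10
    chronic <- 24 + 4.0 * (pco2 - 40) / 10
  }
  list(
    acute = c(acute - 2, acute + 2),
    chronic = c(chronic - 2, chronic + 2),
    envelope = c(min(acute, chronic) - 2, max(acute, chronic) + 2)
  )
}

oracle_met_band <- function(hco3) {
  if (hco3 < 22) {
    mid <- 1.5 * hco3 + 8
    c(mid - 2, mid + 2)
  } else {
    mid <- 40 + 0.7 * (hco3 - 24)
    c(mid - 5, mid + 5)
  }
}

oracle_resp_resolve <- function(pco2, hco3) {
  bands <- oracle_resp_bands(pco2)
  acid <- pco2 > 45
  if (hco3 < bands$envelope[1]) {
    return(if (acid) 6L else 7L)
  }
  if (hco3 > bands$envelope[2]) {
    return(if (acid) 8L else 5L)
  }
  if (acid) 2L else 1L
}

oracle_met_resolve <- function(pco2, hco3) {
  band <- oracle_met_band(hco3)
  acid <- hco3 < 22
  if (pco2 > band[2]) {
    return(if (acid) 6L else 8L)
  }
  if (pco2 < band[1]) {
    return(if (acid) 7L else 5L)
  }
  if (acid) 3L else 4L
}

oracle_classify <- function(ph, pco2, hco3) {
  phf <- oracle_flag(ph, 7.35, 7.45)
  pf <- oracle_flag(pco2, 35, 45)
  hf <- oracle_flag(hco3, 22, 30)

  if (phf == "normal") {
    if (pf == "normal" && hf == "normal") {
      return(0L)
    }
    if (pf == "high" && hf == "high") {
      return(8L)
    }
    if (pf == "low" && hf == "low") {
      return(7L)
    }
    if (pf == "high" && hf == "low") {
      return(6L)
    }
    if (pf == "low" && hf == "high") {
      return(5L)
    }
    if (pf != "normal") {
      return(oracle_resp_resolve(pco2, hco3))
    }
    return(oracle_met_resolve(pco2, hco3))
  }
  if (phf == "low") {
    if (pf == "high" && hf == "low") {
      return(6L)
    }
    if (pf == "low" && hf == "high") {
      return(5L)
    }
    if (pf == "high") {
      return(oracle_resp_resolve(pco2, hco3))
    }
    if (hf == "low") {
      return(oracle_met_resolve(pco2, hco3))
    }
    return(6L)
  }
  # alkalaemia
  if (pf == "low" && hf == "high") {
    return(5L)
  }
  if (pf == "high" && hf == "low") {
    return(6L)
  }
  if (pf == "low") {
    return(oracle_resp_resolve(pco2, hco3))
  }
  if (hf == "high") {
    return(oracle_met_resolve(pco2, hco3))
  }
  5L
}

# classification grid used by equivalence tests
oracle_grid <- function(ph_step = 0.05, pco2_step = 5, hco3_step = 4) {
  expand.grid(
    ph = seq(6.9, 7.8, by = ph_step),
    pco2 = seq(15, 90, by = pco2_step),
    hco3 = seq(4, 50, by = hco3_step)
  )
}

# the study's median arterial sample and biochemistry panel
median_sample <- function() {
  data.frame(
    sample_id = "median", ph = 7.41, pco2 = 39, po2 = 106, hco3 = 24.9,
    sbe = 0.05, lactate = 1.16, fio2 = 0.40,
    na = 139, k = 4.1, cl = 107, glucose = 142, ca_ionized = 1.15,
    albumin = 2.2, urea = 49, creatinine = 0.82
  )
}

# build aligned reference/software label vectors realising a one-vs-rest
# confusion table (tp, fp, fn, tn) for category `k` against filler category
build_labels <- function(tp, fp, fn, tn, k = 1L, other = 0L) {
  reference <- c(rep(k, tp + fn), rep(other, fp + tn))
  software <- c(rep(k, tp), rep(other, fn), rep(k, fp), rep(other, tn))
  list(reference = reference, software = software)
}
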