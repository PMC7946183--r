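---
title: "Methods: blood gas interpretation and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood gas interpretation and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodgas)
```

This vignette is the package's own account of the science it implements:
the interpretation model and its assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The interpretation pipeline

`abg_interpret()` runs four stages in fixed order — safety, oxygenation,
acid-base, renal — on a data frame with one row per arterial sample. A
failed safety check never aborts the downstream stages: an inconsistent
sample is still classified, flagged "interpret with caution", because at the
bedside a provisional reading with a warning is more useful than no reading.
Stages whose inputs are absent are reported *not assessable* rather than
omitted, so the report shape is stable.

### Safety: Henderson consistency and life threats

pH, pCO₂ and HCO₃⁻ are not independent: the bedside Henderson approximation
ties them together as [H⁺] = 24 × pCO₂ / HCO₃⁻ (nmol/L, mmHg, mmol/L).
Since measured pH gives [H⁺] = 10^(9−pH) directly, the relative discrepancy
between the two is a cheap internal-consistency check on the analyser and
the sampling technique (tourniquet use, A-V fistula contamination, stale
samples). The default tolerance is **15%** relative discrepancy. The
coefficient 24 is itself an approximation (it drifts a few percent across
the clinical pH range because the true relation involves the pK and CO₂
solubility at body temperature), so the tolerance must absorb both genuine
approximation error and rounding of reported values; 15% does that while
still catching single-digit transcription errors, which typically produce
discrepancies of 30% and more. The verdict is monotone in the tolerance —
lowering it can only flag more samples — and this is asserted as a property
test.

The life-threat screen compares pH, K⁺, Na⁺, ionized Ca²⁺, glucose and
lactate against critical bounds (defaults: pH outside 7.10–7.60,
K outside 2.5–6.5, Na outside 120–160, Ca²⁺ outside 0.8–1.6 mmol/L,
glucose outside 40–600 mg/dL, lactate above 4 mmol/L). These defaults are
conventional critical-value thresholds, chosen here and configurable in
`abg_config()`; absent analytes are skipped silently, and alerts are
ordered most-immediately-lethal first (pH, K, Na, Ca, glucose, lactate).

### Acid-base: the physiological approach

The classifier uses the physiological (Boston) approach, not the Stewart
strong-ion framework: primary disorders are named by the direction of the
abnormality and every primary is expected to provoke a quantifiable
secondary response. The normal ranges are pH 7.35–7.45, pCO₂ 35–45 mmHg,
HCO₃⁻ 22–30 mmol/L, SBE −2 to +2 mmol/L, lactate 0.5–2.0 mmol/L, with
**inclusive endpoints** — a value exactly on a bound is normal. The
inclusive convention is a deliberate choice (the boundary is already the
edge of "normal" by definition of a reference range) and is pinned by
boundary tests on every analyte.

The expected-compensation rules, all configurable:

| primary | expected compensating value | band |
|---|---|---|
| metabolic acidosis | pCO₂ = 1.5 × HCO₃ + 8 (Winter) | ± 2 mmHg |
| metabolic alkalosis | pCO₂ = 40 + 0.7 × (HCO₃ − 24) | ± 5 mmHg |
| respiratory acidosis | HCO₃ = 24 + 1 (acute) / 3.5 (chronic) per 10 mmHg ΔpCO₂ | ± 2 mmol/L |
| respiratory alkalosis | HCO₃ = 24 − 2 (acute) / 4 (chronic) per 10 mmHg ΔpCO₂ | ± 2 mmol/L |

The respiratory bands use ± 2 mmol/L, matching Winter's ± 2: with a wider
band the engine would accept, say, HCO₃⁻ 23 as adequate compensation for an
acute pCO₂ of 60 (expected ≈ 26), where the acidaemia of pH 7.20 plainly
indicates a concurrent metabolic acidosis. A compensating variable below its
band envelope declares the acid-direction second disorder, above it the
alkaline-direction one; inside the acute band only, chronicity is *acute*,
inside the chronic band only, *chronic*, and where the two bands overlap (or
the value falls between them) the engine reports *indeterminate* rather than
guessing — clinicians cannot reliably identify the order of presentation,
and neither should a rule engine.

Two tie-breaks are worth stating. At normal pH with pCO₂ and HCO₃⁻ abnormal
in opposing acid-base directions, the engine reports the dual category
rather than electing a primary: calculation begins as soon as any value
leaves its range, and a normal pH with two opposing abnormalities *is* two
disorders. And when SBE disagrees with the HCO₃⁻ direction, HCO₃⁻ governs
and the narrative notes the discrepancy; SBE is retained purely as a
cross-check because the two are near-collinear in practice.

Anion gap Na − Cl − HCO₃ is albumin-corrected (+2.5 mmol/L per g/dL below
4.0) because hypoalbuminaemia — near universal in the acutely unwell —
masks real gaps. The high-gap threshold is the patient's own baseline gap
when known, else 12 mmol/L; the delta ratio
(AG − baseline AG)/(baseline HCO₃ − HCO₃) is computed only for high-gap
metabolic acidosis, with bands < 0.4 pure normal-gap, 0.4–0.8 mixed,
0.8–2.0 pure high-gap, > 2.0 concurrent metabolic alkalosis. Supplying
per-patient baselines can change the verdict — that is precisely why they
are tracked. Lactate never changes the category; above 2 mmol/L it adds
"lactic acidosis" to the cause list only.

The nine-category output (normal, four simple, four dual disorders) is
exhaustive and exclusive — a property test sweeps a pH × pCO₂ × HCO₃ grid
of over 10⁴ points and checks the vectorized engine against an
independently written scalar decision tree. Code 9 ("I am not sure") is
accepted on input of human rater labels but never produced by the engine.
The finer subcategory string (category × gap status × chronicity ×
compensation adequacy) spans the taxonomy's 36 leaves and is configurable,
as is the cause map.

### Oxygenation

On mechanical ventilation the PaO₂/FiO₂ ratio is banded by the Berlin
definition (mild ≤ 300, moderate ≤ 200, severe ≤ 100 mmHg), *only* when
PEEP ≥ 5 cmH₂O — the bands are undefined off ventilation, and the
assessment says so instead of guessing. Breathing spontaneously, pO₂ is
compared with the age-expected value 102 − 0.33 × age mmHg and, when below
it, the alveolar–arterial gradient FiO₂ × (760 − 47) − pCO₂/0.8 − pO₂ is
compared with the age-adjusted limit age/4 + 4 mmHg. Both age rules are
conventional bedside formulas chosen here (no published table accompanies
the design they operationalize) and are configurable, as are the
atmospheric constants for altitude. Ages under 1 year are reported not
assessable — no paediatric reference is bundled. A negative gradient is
returned, not clipped: it indicates a measurement problem and the verdict
says so.

### Renal

BUN = urea / 2.14 (molecular-weight ratio); BCR bounds 10/20 are the
conventional prerenal/intrinsic cut-offs. For dialysis patients the URR and
the Daugirdas second-generation single-pool
Kt/V = −ln(R − 0.008 t) + (4 − 3.5 R) UF/W are reported. The Daugirdas form
was chosen because it reproduces the conventional anchor (Kt/V 1.2 ≈
URR 63%): at t = 4 h the closed form gives 1.085 with no ultrafiltration,
rising through 1.17 at a typical UF/W of 0.03 to 1.22 at 0.05 — "roughly
1.2" across the plausible session range — whereas the naive −ln(1 − URR)
gives 0.99. The URR adequacy floor defaults to 65%, the conventional
minimum-dose criterion. Note the naive bound "[1.1, 1.3] for all UF/W in
[0, 0.05]" does not quite hold: the UF/W = 0 endpoint is 1.085, and the
tests assert the exact closed-form values instead.

## Validation statistics

The package treats the classifier as a diagnostic test. The adjudication
design: two primary raters A and B label each sample; if the software
matches both, the record is concordant; if it matches exactly one, a third
independent rater C is elicited and the record is partially congruent
exactly when C sides with the software; otherwise it is discordant. The
consensus label is A when A = B, else the majority of {A, B, C} (no
majority → no consensus, and the record drops out of accuracy
denominators). Records in which the compared human label is 9 are excluded
from agreement and accuracy denominators — non-committal labels cannot
score either way — and this exclusion is configurable.

Agreement is summarised by observed agreement and unweighted Cohen's κ over
the full cross-tabulation, with the Fleiss–Cohen–Everitt large-sample
variance for the confidence interval and the null-variance form for the
test of κ = 0. Per-category accuracy dichotomizes one-vs-rest into a 2×2
table; sensitivity, specificity, global accuracy, PPV, NPV and prevalence
each get a Wilson score interval **on their own denominator** (Wilson
because several cells are at or near 0/100%, where Wald intervals collapse
and Clopper–Pearson over-covers). Likelihood ratios are computed from
unrounded proportions — this matters: LR⁺ for the normal category is
(54/60)/(8/284) = 31.95 → 32.0, while pre-rounded inputs would give
90.0/2.8 = 32.1 — and LR⁺ is reported not-calculable when there are no
false positives (division by zero specificity complement), likewise the
inverse LR⁻ with no false negatives. Reported tables round to one decimal;
full precision is kept in the returned objects and JSON.

## The synthetic cohort generator

`generate_cohort()` emulates a validation study: categories are allocated
multinomially (default prevalences proportional to 60, 34, 18, 33, 36, 48,
51, 31, 31 across codes 0–8, the case mix of a real 346-sample
critical-care validation set), each sample's (pCO₂, HCO₃⁻) pair is drawn
from a category-specific geometry with the compensation bands built in, and
pH is derived from the Henderson relation — so every triple is internally
consistent by construction. HCO₃⁻ is then jittered within ± 2% (well inside
the 15% tolerance) and values are rounded to reporting precision.
Rejection sampling on the classifier guarantees exact label fidelity; the
pure respiratory categories additionally reject the fully compensated
normal-pH corner so their draws are frankly acidaemic/alkalaemic.
Electrolytes are drawn around the marginal medians of an adult
critical-care cohort (Na 139, K 4.1, glucose 142 mg/dL, albumin 3.3 g/dL,
urea 49 mg/dL, creatinine 0.82 mg/dL) with IQR-scaled noise; chloride is
derived from a sampled anion gap rather than drawn independently, because
the gap, not chloride, is the physiologically constrained quantity.
A dedicated `inconsistent = TRUE` flag produces Henderson-violating triples
for testing the safety stage.

Simulated raters keep the true label with their configured accuracy
(defaults 0.817 and 0.746 for the two primary raters, emulating the
observed per-rater agreement of the validation study against a
label-faithful classifier; 0.85 for the adjudicator, for which no published
figure exists) and otherwise draw a wrong label from a configurable
confusion kernel, uniform by default. With accuracy *p* and a uniform
kernel, two raters agree with probability p² + (1−p)²/8 — a closed form the
tests check — and the κ between a rater and a label-faithful classifier has
an analytic value whose 95% CI should cover it in ~95% of replicates;
parameter recovery is asserted at ≥ 90 of 100 seeded replicates of n = 346.

**What the generator does not emulate.** Within-patient correlation (the
real study drew 346 samples from 64 patients; the statistics treat them as
exchangeable, and so does the generator), category-specific electrolyte
case mix beyond the metabolic-acidosis gap split, rater errors that
correlate with case difficulty (the kernel is independent of the sample's
values, only of its category), and any drift or device effects. Passing
tests on synthetic cohorts therefore demonstrate the *machinery* —
classification geometry, adjudication, estimators — not field performance
on real patients.

## Numerical and scale choices

Canonical units are mmHg, mmol/L, mg/dL (glucose, urea, creatinine) and
g/dL (albumin); kPa and SI glucose/urea converters use the factors 7.5, 18
and 2.14. FiO₂ above 1 on input is interpreted as a percentage. The
problem sizes used by the test suite and the acceptance script — a > 10⁴
point classifier grid, cohorts of 346, 100 κ-recovery replicates — were
chosen so the full suite runs in well under a minute while every asserted
property is exercised at the scale of the study it emulates. All
stochastic tests fix seeds; the acceptance script derives every seed from
its `--seed` argument.

## Known limitations

The classifier is a rule engine: it reproduces the physiological approach's
textbook constants, not a fitted model, and its tolerance bands are
conventions, not estimates. The adjudication consensus in simulation agrees
with a label-faithful classifier almost always (partial congruence resolves
toward the software by design), so simulated consensus κ runs higher than
any real study's would; per-rater κ is the more informative simulated
figure. No treatment advice is produced, and no Stewart-approach quantities
(strong ion difference, strong ion gap) are computed.
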