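# bloodgas

Automated interpretation of arterial blood gas (ABG) samples, and the
statistical machinery to validate such an interpreter against human experts.

## Who this is for

Point-of-care ABG analysers print numbers — pH, pCO₂, pO₂, HCO₃⁻, base
excess, lactate — but interpreting them (is this a mixed acid-base disorder?
is the compensation appropriate? is the patient oxygenating for their age?)
takes experience and time. `bloodgas` implements a rule-based interpreter in
four fixed stages and, because any such interpreter must be validated as a
diagnostic test, it also ships the full diagnostic-accuracy toolkit
(three-rater adjudication, Cohen's κ, Wilson score intervals, predictive
values, likelihood ratios) plus a seeded generator of physiologically
coherent labelled cohorts so everything is testable without patient data.

## The model

**Safety.** Measured hydrogen ion concentration, [H⁺] = 10^(9−pH) nmol/L, is
cross-checked against the bedside Henderson relation
[H⁺] = 24 × pCO₂ / HCO₃⁻. A relative discrepancy above the tolerance
(default 15%) flags a probable pre-analytical error. Critical values of pH,
K⁺, Na⁺, ionized Ca²⁺, glucose and lactate raise life-threat alerts.

**Oxygenation.** Ventilated patients: PaO₂/FiO₂ ratio with Berlin ARDS bands
(mild ≤ 300, moderate ≤ 200, severe ≤ 100 mmHg, valid at PEEP ≥ 5 cmH₂O).
Spontaneous breathing: pO₂ against the age-expected value
(102 − 0.33 × age), then the alveolar–arterial gradient
PAO₂ = FiO₂ (P_b − P_H₂O) − pCO₂/RQ against the age-adjusted limit
(age/4 + 4 mmHg).

**Acid-base.** The physiological approach. The directions of pH, pCO₂ and
HCO₃⁻ against the normal ranges (pH 7.35–7.45, pCO₂ 35–45 mmHg,
HCO₃⁻ 22–30 mmol/L) identify the primary disorder(s); the compensating
variable is tested against its expected band (Winter's formula
pCO₂ = 1.5 × HCO₃ + 8 ± 2 for metabolic acidosis; ΔpCO₂ = 0.7 ΔHCO₃ ± 5 for
metabolic alkalosis; ΔHCO₃ per 10 mmHg ΔpCO₂ of +1/+3.5 acute/chronic in
respiratory acidosis and −2/−4 in respiratory alkalosis, ± 2). A
compensating variable outside its band declares a second concurrent
disorder. Every sample maps to exactly one of nine categories (normal, the
four simple disorders, the four dual disorders); anion gap
(albumin-corrected, against per-patient baselines when known) and the delta
ratio ΔAG/ΔHCO₃ refine metabolic acidosis.

**Renal.** BUN:creatinine ratio (BUN = urea/2.14; > 20 prerenal, < 10
intrinsic) and, on dialysis, the urea reduction ratio
URR = 100 (pre − post)/pre with the Daugirdas second-generation
Kt/V = −ln(R − 0.008 t) + (4 − 3.5 R) · UF/W, which reproduces the
conventional anchor Kt/V 1.2 ≈ URR 63%.

## Worked example

```r
library(bloodgas)

sample <- data.frame(
  ph = 7.41, pco2 = 39, po2 = 106, hco3 = 24.9, sbe = 0.05, lactate = 1.16,
  fio2 = 40, na = 139, k = 4.1, cl = 107, glucose = 142, ca_ionized = 1.15,
  albumin = 2.2, urea = 49, creatinine = 0.82,
  mechanically_ventilated = TRUE, peep = 5
)
cat(abg_interpret(sample)$rendered_text)
```

```
== ABG interpretation: sample S0001 ==
-- Safety --
Internal consistency: OK (measured vs expected [H+] differ by 3.5%).
No life-threatening values on the screened analytes.
-- Oxygenation --
ventilated: PF ratio 265 mmHg, mild ARDS range (Berlin) - rule out ARDS
-- Acid-base --
Normal acid-base status (pH 7.41, pCO2 39 mmHg, HCO3 24.9 mmol/L). Anion gap 7.1 (albumin-corrected 11.6) mmol/L, normal-gap.
-- Renal --
BUN 22.9 mg/dL, BUN:creatinine ratio 27.9: prerenal pattern. Consider: hypovolaemia / dehydration; gastrointestinal bleeding; high protein load or catabolic state; low renal perfusion (heart failure).
```

Reading the report: the Henderson cross-check passes (pH 7.41 implies
[H⁺] ≈ 38.9 nmol/L vs 24 × 39 / 24.9 ≈ 37.6 expected, a 3.5% discrepancy,
well under the 15% tolerance); the PaO₂/FiO₂ ratio 106/0.40 = 265 mmHg sits
in the mild Berlin band on ventilation at PEEP 5; all acid-base values are
in range, and the albumin-corrected anion gap 7.1 + 2.5 × (4 − 2.2) = 11.6
is still normal; the BUN:creatinine ratio (49/2.14)/0.82 ≈ 27.9 exceeds 20,
a prerenal pattern.

A simulated validation study end to end:

```r
cohort <- generate_cohort(abg_cohort_spec(n_samples = 346, seed = 2026))
val <- run_validation(cohort$raters)
tidy(val$agreement)
#>   comparison      n observed_agreement kappa conf.low conf.high   p.value
#> 1 clinician_a   346               81.2 0.786    0.739     0.833 0
#> 2 clinician_b   346               73.1 0.694    0.641     0.747 1.06e-271
#> 3 consensus     313               98.7 0.985    0.971     1.000 0
```

The simulated raters reproduce the true label with probability 0.817 (A) and
0.746 (B), so their observed agreement with the (label-faithful) classifier
lands near those figures; the adjudicated consensus agrees far more often,
by construction of the adjudication design. `val$accuracy` holds the
per-category one-vs-rest table with Wilson 95% CIs, predictive values and
likelihood ratios; `autoplot(val$accuracy)` draws the forest plot.

A thin CLI mirroring these functions lives in `inst/cli/abg.R`
(`interpret`, `validate`, `simulate` subcommands).

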