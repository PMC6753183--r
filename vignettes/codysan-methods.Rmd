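---
title: "Methods: the staged CDA screening algorithm and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the staged CDA screening algorithm and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codysan)
```

## The screening model

Congenital dyserythropoietic anemias (CDA) present as chronic anemia whose
reticulocyte response is lower than the degree of anemia would predict
(ineffective erythropoiesis), with distinctive erythroblast morphology in
the bone marrow. The screen implemented here is a deterministic, staged
decision procedure over routine hematology plus a small set of clinical
findings. It deliberately stops at *clinical suspicion of a CDA type plus
the genes to test*; it performs no variant interpretation and is not a
diagnosis — every outcome carries the standing disclaimer.

The four stages are:

1. **Hemoglobin gate** — Hb against the (sex, age-stratum) reference
   interval; within → `no_anemia`, above → `hyperhemoglobinemia`, below →
   continue.
2. **Flag derivation** — MCV, reticulocyte and platelet counts flagged
   against their intervals; MCV flag determines morphology
   (below/within/above → micro/normo/macrocytic); platelets below range is
   thrombocytopenia.
3. **Exclusion gate** — at least one alternative cause of anemia must have
   been excluded (the causes offered depend on morphology), otherwise the
   procedure stops with a reasoned rejection rather than a suspicion.
4. **Rule engine** — a versioned, externalized rule set evaluated
   first-match in ascending priority over the derived flags, the sex, and
   the reported clinical features.

### Reference intervals

The packaged table holds 4 parameters × 2 sexes × 3 age strata = 24
intervals in canonical units (Hb g/dL, MCV fL, counts 1e9/L), adapted from
general hematological reference books. The three strata — under 6 months,
6 months to under 12 years, 12 years and older — are half-open on the
right, so a boundary age (exactly 6 months, exactly 12 years) joins the
older group. A value exactly equal to an interval bound counts as
*within*: whether boundary values are normal is not stated by the source
material, and the inclusive reading is the conservative clinical one (a
boundary Hb raises no anemia alarm). MCV and platelet rows are
sex-identical but stored per sex so the table schema is uniform and a
replacement table (via `reference_ranges(path)`) can stratify them.

### Unit canonicalization

Registered conversions are exact arithmetic on fixed factors: Hb g/L → g/dL
(×0.1), Hb mmol/L → g/dL (×1.6114, monomer convention), counts 1e3/µL ≡
1e9/L (×1). Reticulocytes reported as a percentage require the red-cell
count explicitly (`percent/100 × RBC[1e12/L] × 1000` → 1e9/L); assuming a
default RBC would silently fabricate a count, so its absence is an error.
Round-trips through any registered unit recover the value to < 1e-12
relative error (tested).

### Operationalizing "reticulocytosis not corresponding to the degree of anemia"

No quantitative corrected-reticulocyte formula accompanies the published
algorithm, so the package operationalizes inadequate reticulocytosis with
the reference-interval flag: in the presence of anemia, a reticulocyte
count that is *not above* its normal interval (flag `below` or `within`)
is an inadequate marrow response. This is the default
(`reticulocyte_rule = "not_elevated"`); the stricter `"below_only"`
variant is available for sensitivity analyses. A count above range routes
to a hemolytic-anemia explanation (`NOT_CDA`), consistent with CDA being a
hyporegenerative anemia.

### The default rule set

The decision tree is data, not code: `inst/extdata/rules_default.yaml`
(version `codysan-default-1.0`), validated at load time (unique ids and
priorities, known predicate fields and codes, a mandatory catch-all).
The shipped tree encodes, in priority order:

| priority | pattern | outcome |
|---|---|---|
| 10 | anemia, inadequate reticulocytosis, thrombocytopenia | XLDAT (XL, *GATA1*) |
| 20 | macro/normocytic, inadequate, multinucleated erythroblasts | CDA III (AD, *KIF23*) |
| 30 | macrocytic, inadequate, binucleated erythroblasts / EM features / skeletal-limb malformations | CDA I (AR, *CDAN1*, *C15orf41*) |
| 40 | normocytic, inadequate, binucleated erythroblasts / EM features | CDA II (AR, *SEC23B*) |
| 900 | reticulocytes elevated | NOT_CDA (hemolytic explanation) |
| 950 | microcytic | NOT_CDA (iron deficiency / thalassemia / sideroblastic workup) |
| 1000 | catch-all | NOT_CDA |

Design choices that were genuinely open:

* **Branches without a documented resolution default to `NOT_CDA`** —
  fail-safe toward "consult an expert center" rather than toward a
  suspicion. In particular the microcytic branch raises no CDA suspicion,
  and CDA IV is a valid rule outcome (with its AD/*KLF1* annotation) but
  is not emitted by the default rules: no routine laboratory or morphology
  feature in the input vocabulary distinguishes it, and inventing one
  would manufacture suspicions the source procedure does not support. A
  site with access to, e.g., HbF quantification can add a CDA IV rule in a
  custom document.
* **First-match by explicit priority; duplicate priorities are a load-time
  error**, never broken silently — rule shadowing should be visible in
  review, not resolved by list order.
* **Suspicion structurally requires an excluded alternative cause**: the
  exclusion gate precedes the rule engine, so no rule can fire on a record
  with an empty exclusion set (fuzz-tested over 10,000 random records).
  Any registered cause (including `other`, with a note) satisfies the
  gate; requiring the morphology-matched cause specifically would make the
  gate depend on a flag the user has not yet seen in a step-by-step
  workflow.
* **An insufficient-exclusions stop is reported as category `not_cda`**
  with an explanatory message and trace line, keeping the outcome
  vocabulary to the four published result kinds rather than adding a fifth.

The test suite contains an independent brute-force transcription of the
same tree as nested if/else and checks the engine against it exhaustively
over all 3⁴ flag combinations × exclusion presence × all 2⁷ feature
subsets (20,736 cases).

## The cohort simulator

The simulator emulates the *structure* of the two study cohorts — a
43-patient design set (18 CDA II, 4 CDA Ia, 1 CDA Ib, 1 XLDAT, 8
hereditary spherocytosis, 4 pyruvate kinase deficiency, 1 PK + β-thal
trait, 1 AK1 deficiency, 1 X-linked sideroblastic anemia, 3 DHS1, 1 DHS2)
and a 23-patient all-CDA-II validation set — not the unpublished
individual patients. Per-condition counts are exact, the output order is a
seed-determined shuffle, and identical (composition, profiles, seed) give
identical cohorts.

Each condition profile samples laboratory values from truncated normal
distributions (inverse-CDF sampling) with truncation at physiologic
bounds: Hb ∈ [3, 25] g/dL, MCV ∈ [50, 140] fL, reticulocytes ∈ [1, 600]
× 10⁹/L, platelets ∈ [5, 1000] × 10⁹/L. The default means and standard
deviations are authored from the published phenotype descriptions, chosen
once as clinically typical values:

* CDA profiles: Hb mean 8.5–9.3 g/dL (clearly anemic in every adult
  stratum), reticulocytes centered inside the normal range (the
  hyporegenerative pattern), CDA I macrocytic (MCV 106 ± 7 fL), CDA II
  normocytic (90 ± 6 fL), XLDAT with platelets 55 ± 25 × 10⁹/L; feature
  probabilities below 1 (e.g. binucleated erythroblasts 0.9 for CDA II,
  0.7 for CDA I) because marrow findings are not reported for every real
  patient.
* Hemolytic confounders (HS, PK, AK1, DHS): milder anemia with marked
  reticulocytosis (means 230–280 × 10⁹/L), the regenerative pattern that
  the tree routes away from CDA.
* Microcytic confounders: XLSA (MCV 65 ± 5 fL, male-only, low-normal
  reticulocytes) and PK + β-thal trait (68 ± 5 fL, reticulocytosis).
* Ages uniform on [2, 70] years, sex balanced except the X-linked
  conditions (male), and the morphology-appropriate excluded cause emitted
  with probability 1 by default — simulator studies measure the rule
  logic, not form compliance; the `p_workup` knob exposes the latter.

What the simulator does **not** emulate: correlations between analytes
within a patient, age-dependent disease severity, measurement repeats and
day-to-day analytical variability, transfusion effects, and the real
feature-ascertainment process. Passing simulator-based tests therefore
shows the engine implements the intended logic under its own assumptions,
not that the published real-patient operating point is reproduced; the
real design- and validation-set percentages rest on unpublished individual
values and are out of reach of any re-implementation.

## Evaluation harness

`evaluate_cohort()` classifies every record and tabulates a binary
confusion matrix with "CDA suspicion of any type" as the positive class —
a suspicion of the wrong CDA type still counts as a positive, matching how
a mixed-type design set is scored with a single sensitivity/specificity
pair; the per-type breakdown is reported separately. Sensitivity is
TP/(TP+FN), specificity TN/(TN+FP); a metric whose denominator is empty
(specificity on an all-CDA validation cohort) is reported as `NA` and
printed as "undefined" rather than as a number.

## Problem sizes and reproducibility

The shipped checks use the design composition (n = 43), the validation
composition (n = 23), a 10× design cohort (n = 430) with pathognomonic
feature probabilities set to 1, a 10,000-triple hemoglobin-gate
comparison, a 10,000-record no-exclusions fuzz, and the exhaustive
20,736-case rule-grid enumeration; all are seeded and complete in seconds.
`scripts/acceptance.R` re-runs the cohort pipeline end to end from a
single `--seed` and writes the computed percentages as JSON.

## Known limitations

* The reference table is a snapshot of standard reference books; local
  laboratories should substitute their own intervals via
  `reference_ranges(path)`.
* The three age strata are coarse by design; no continuous age
  interpolation is attempted.
* The screen is rule-based and score-free: there are no thresholds to
  sweep and no ROC analysis to perform.
* `other` as an exclusion is accepted for any morphology, so the gate is
  permissive by construction.
* The packaged genetic-testing laboratory registry is a synthetic
  placeholder table; point `gene_labs(path = ...)` at a maintained export
  for real lookups.
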