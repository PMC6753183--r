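# codysan

Rule-based diagnostic support for congenital dyserythropoietic anemia (CDA).

CDAs are rare inherited disorders of red-cell production: chronic anemia
with a reticulocyte response that does not match the degree of anemia
(ineffective erythropoiesis) and characteristic erythroblast abnormalities
in the bone marrow. Five types are recognized — CDA I (*CDAN1*,
*C15orf41*; autosomal recessive), CDA II (*SEC23B*; AR), CDA III
(*KIF23*; autosomal dominant), CDA IV (*KLF1*; AD) and XLDAT (*GATA1*;
X-linked) — with overlapping presentations, so patients are frequently
under- or mis-diagnosed. This package implements the CoDysAn staged
screening algorithm as a library plus command-line tool, for hematologists
and clinical-informatics developers who want the decision logic testable,
versioned and auditable rather than buried in a web form.

## The algorithm

A patient record carries age, sex, hemoglobin (Hb), MCV, reticulocyte and
platelet counts (each canonicalized to g/dL, fL and 1e9/L), a set of
excluded alternative causes of anemia, and a set of clinical features.
Classification proceeds in four stages:

1. **Hemoglobin gate.** Hb is compared against the age- and sex-stratified
   reference interval (three age strata: under 6 months, 6 months to under
   12 years, 12 years and older). Hb within range → *no anemia*; above →
   *hyperhemoglobinemia*; below → anemia, continue.
2. **Derived flags.** MCV, reticulocytes and platelets are flagged
   below/within/above their intervals. MCV yields the morphology
   (microcytic / normocytic / macrocytic); reticulocytes not elevated
   despite anemia define *inadequate reticulocytosis*; platelets below
   range define thrombocytopenia.
3. **Exclusion gate.** At least one morphology-appropriate alternative
   cause of anemia (B12/folate deficiency or HPFH; iron deficiency or
   thalassemia; hemolytic membrane or enzyme defects) must be excluded to
   proceed.
4. **Rule engine.** An externalized, versioned YAML rule set is evaluated
   first-match in priority order over the flags and clinical features,
   returning a CDA-type suspicion (annotated with inheritance mode and the
   genes to test, sensitivity TP/(TP+FN) and specificity TN/(TN+FP) being
   the evaluation metrics with "CDA suspicion of any type" as the positive
   class) or a reasoned `NOT_CDA` with an explanation.

A seeded synthetic cohort simulator reproduces the structure of the
43-patient design set (24 CDA: 18 CDA II, 4 CDA Ia, 1 CDA Ib, 1 XLDAT; 19
non-CDA hereditary anemias) and the 23-patient all-CDA-II validation set,
so the classifier and metrics are exercised without patient data.

## Worked example

```r
library(codysan)

rec <- patient_record(
  age = 30, sex = "F",
  hb  = canonicalize("hemoglobin", 100, "g/L"),   # 10 g/dL
  mcv = 88, reticulocytes = 50, platelets = 300,
  exclusions = "hemolytic_membrane_defect",
  features   = "binucleated_erythroblasts")
classify(rec)
```

```
CDA diagnostic outcome
  category: cda_suspicion 
  suspicion: CDA_II (AR; genes: SEC23B)
  message: Normocytic hyporegenerative anemia with binucleated erythroblasts or
    characteristic electron-microscopy features: clinical suspicion of CDA type II.
    Genetic testing of SEC23B is suggested.
  trace:
    - input: age 30 y (over_12y), sex F, Hb 10 g/dL 
    - hemoglobin gate: proceed_anemia 
    - flags: MCV within (normocytic), reticulocytes within (inadequate: TRUE),
      platelets within (thrombocytopenia: FALSE) 
    - exclusion gate: proceed (excluded: hemolytic_membrane_defect) 
    - rules: fired 'cda2_normocytic_binucleated' (priority 40) -> CDA_II 
  rule set: codysan-default-1.0 
  This is a preliminary diagnostic screen, not a diagnosis; expert medical
  doctors should be contacted for a conclusive diagnosis.
```

The Hb of 10 g/dL is below the adult-female interval (12–16 g/dL), the
normal MCV makes the anemia normocytic, reticulocytes of 50 × 10⁹/L are in
the normal 27–91 interval — i.e. not elevated despite anemia, the
hyporegenerative pattern — and with an excluded hemolytic cause and
binucleated erythroblasts the CDA II rule fires, pointing at *SEC23B*.

A simulated design cohort, scored end to end:

```r
cohort <- simulate_cohort(design_composition(), seed = 1)
evaluate_cohort(cohort)
#> Cohort evaluation (positive class: CDA suspicion)
#>   n = 43; TP 24, FP 0, TN 19, FN 0
#>   sensitivity: 100.0%
#>   specificity: 100.0%
#>   ...
```

The command-line interface wraps the same functions
(`Rscript inst/cli/codysan.R ranges`, `... classify --input patients.csv`,
`... simulate --seed 7 --out cohort.csv`, `... evaluate --input cohort.csv`,
`... labs --gene SEC23B`; the packaged laboratory registry is a synthetic
placeholder).

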