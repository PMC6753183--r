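# Default CoDysAn rule set: staged decision tree over derived flags.
# Evaluated first-match in ascending priority; the engine requires a
# catch-all rule (empty `when`) so every flag combination has an outcome.
version: codysan-default-1.0
rules:
  - id: xldat_anemia_thrombocytopenia
    priority: 10
    when:
      inadequate_reticulocytosis: true
      thrombocytopenia: true
    outcome: XLDAT
    message: >-
      Anemia with inadequate reticulocyte response and thrombocytopenia:
      clinical suspicion of X-linked dyserythropoietic anemia with
      thrombocytopenia (XLDAT). Genetic testing of GATA1 is suggested.
  - id: cda3_multinucleated_erythroblasts
    priority: 20
    when:
      morphology: [macrocytic, normocytic]
      inadequate_reticulocytosis: true
      features_any: [multinucleated_erythroblasts]
    outcome: CDA_III
    message: >-
      Hyporegenerative anemia with giant multinucleated erythroblasts:
      clinical suspicion of CDA type III. Genetic testing of KIF23 is
      suggested.
  - id: cda1_macrocytic_dyserythropoiesis
    priority: 30
    when:
      morphology: [macrocytic]
      inadequate_reticulocytosis: true
      features_any:
        - binucleated_erythroblasts
        - em_features
        - skeletal_or_limb_malformations
    outcome: CDA_I
    message: >-
      Macrocytic hyporegenerative anemia with dyserythropoietic marrow
      morphology, ultrastructural features or skeletal/limb malformations:
      clinical suspicion of CDA type I. Genetic testing of CDAN1 and
      C15orf41 is suggested.
  - id: cda2_normocytic_binucleated
    priority: 40
    when:
      morphology: [normocytic]
      inadequate_reticulocytosis: true
      features_any: [binucleated_erythroblasts, em_features]
    outcome: CDA_II
    message: >-
      Normocytic hyporegenerative anemia with binucleated erythroblasts or
      characteristic electron-microscopy features: clinical suspicion of
      CDA type II. Genetic testing of SEC23B is suggested.
  - id: not_cda_adequate_reticulocytosis
    priority: 900
    when:
      inadequate_reticulocytosis: false
    outcome: NOT_CDA
    message: >-
      The reticulocyte count is elevated, indicating a regenerative marrow
      response; CDA presents with reticulocytosis not corresponding to the
      degree of anemia. A hemolytic anemia (e.g. membrane or enzyme defect)
      is the more likely explanation.
  - id: not_cda_microcytic
    priority: 950
    when:
      morphology: [microcytic]
    outcome: NOT_CDA
    message: >-
      Microcytic anemia without further distinguishing findings is not
      suggestive of CDA; iron deficiency, thalassemia or sideroblastic
      anemia should be investigated.
  - id: not_cda_default
    priority: 1000
    when: {}
    outcome: NOT_CDA
    message: >-
      The provided findings do not match any CDA suspicion pattern. If the
      anemia remains unexplained, consult an expert hematology center.
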