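make_rec <- function(...) patient_record(...)

test_that("the hemoglobin gate separates anemia, normal and hyperhemoglobinemia", {
  expect_identical(
    hemoglobin_gate(make_rec(age = 30, sex = "F", hb = 11)),
    "proceed_anemia")
  expect_identical(
    hemoglobin_gate(make_rec(age = 30, sex = "M", hb = 20)),
    "hyperhemoglobinemia")
  expect_identical(
    hemoglobin_gate(make_rec(age = 0.25, sex = "M", hb = 10)),
    "no_anemia")
})

test_that("lowering hemoglobin never turns anemia back into no-anemia", {
  set.seed(3)
  for (i in 1:200) {
    age <- runif(1, 0, 80)
    sex <- sample(c("M", "F"), 1)
    hb2 <- runif(1, 4, 22)
    hb1 <- hb2 - runif(1, 0.1, 3)
    if (hb1 <= 0) next
    g2 <- hemoglobin_gate(make_rec(age = age, sex = sex, hb = hb2))
    g1 <- hemoglobin_gate(make_rec(age = age, sex = sex, hb = hb1))
    if (g2 == "proceed_anemia") expect_identical(g1, "proceed_anemia")
  }
})

test_that("derived flags encode morphology, reticulocyte adequacy and thrombocytopenia", {
  rec <- make_rec(age = 40, sex = "M", hb = 10, mcv = 105,
                  reticulocytes = 60, platelets = 90)
  fl <- derive_flags(rec)
  expect_identical(fl$morphology, "macrocytic")
  expect_true(fl$inadequate_reticulocytosis)  # 60 in [29, 95], not elevated
  expect_true(fl$thrombocytopenia)            # 90 < 145

  rec <- make_rec(age = 30, sex = "F", hb = 10, mcv = 88,
                  reticulocytes = 60, platelets = 300)
  fl <- derive_flags(rec)
  expect_identical(fl$morphology, "normocytic")
  expect_true(fl$inadequate_reticulocytosis)  # within [27, 91]
  expect_false(fl$thrombocytopenia)
  # stricter rule: within-range reticulocytes no longer count as inadequate
  fl2 <- derive_flags(rec, reticulocyte_rule = "below_only")
  expect_false(fl2$inadequate_reticulocytosis)

  expect_error(derive_flags(make_rec(age = 30, sex = "F", hb = 10)),
               "`mcv`")
})

test_that("the exclusion gate demands at least one excluded cause", {
  rec0 <- make_rec(age = 30, sex = "F", hb = 10)
  expect_identical(exclusion_gate(rec0, "normocytic"), "insufficient")
  rec1 <- make_rec(age = 30, sex = "F", hb = 10,
                   exclusions = "b12_or_folate_deficiency")
  expect_identical(exclusion_gate(rec1, "macrocytic"), "proceed")
  rec2 <- make_rec(age = 30, sex = "F", hb = 10,
                   exclusions = "iron_deficiency")
  expect_identical(exclusion_gate(rec2, "microcytic"), "proceed")
  # morphology-specific offerings
  expect_setequal(morphology_exclusions("macrocytic"),
                  c("b12_or_folate_deficiency", "hpfh", "other"))
  expect_setequal(morphology_exclusions("microcytic"),
                  c("iron_deficiency", "thalassemia", "other"))
  expect_setequal(morphology_exclusions("normocytic"),
                  c("hemolytic_membrane_defect", "enzyme_defect", "other"))
})

test_that("the default rules recover the type-specific suspicion patterns", {
  # normocytic, inadequate retics, no thrombocytopenia, binucleated -> CDA II
  rec <- make_rec(age = 30, sex = "F", hb = 10, mcv = 88,
                  reticulocytes = 50, platelets = 300,
                  exclusions = "hemolytic_membrane_defect",
                  features = "binucleated_erythroblasts")
  out <- classify(rec)
  expect_identical(out$category, "cda_suspicion")
  expect_identical(out$cda_type$code, "CDA_II")
  expect_identical(out$cda_type$inheritance, "AR")

  # anemia + inadequate retics + thrombocytopenia -> XLDAT
  rec <- make_rec(age = 8, sex = "M", hb = 9, mcv = 80,
                  reticulocytes = 40, platelets = 70,
                  exclusions = "other")
  out <- classify(rec)
  expect_identical(out$category, "cda_suspicion")
  expect_identical(out$cda_type$code, "XLDAT")
  expect_identical(out$cda_type$inheritance, "XL")
  expect_identical(out$cda_type$genes, "GATA1")

  # macrocytic with EM features -> CDA I
  rec <- make_rec(age = 25, sex = "M", hb = 10, mcv = 110,
                  reticulocytes = 40, platelets = 300,
                  exclusions = "b12_or_folate_deficiency",
                  features = "em_features")
  expect_identical(classify(rec)$cda_type$code, "CDA_I")

  # multinucleated erythroblasts -> CDA III
  rec <- make_rec(age = 25, sex = "F", hb = 10, mcv = 90,
                  reticulocytes = 40, platelets = 300,
                  exclusions = "other",
                  features = "multinucleated_erythroblasts")
  expect_identical(classify(rec)$cda_type$code, "CDA_III")

  # normocytic with no features -> reasoned NOT_CDA
  rec <- make_rec(age = 30, sex = "F", hb = 10, mcv = 88,
                  reticulocytes = 50, platelets = 300,
                  exclusions = "enzyme_defect")
  out <- classify(rec)
  expect_identical(out$category, "not_cda")
  expect_match(out$message, ".+")
  expect_null(out$cda_type)

  # elevated reticulocytes route to the hemolytic explanation
  rec <- make_rec(age = 30, sex = "F", hb = 10, mcv = 88,
                  reticulocytes = 200, platelets = 300,
                  exclusions = "enzyme_defect",
                  features = "binucleated_erythroblasts")
  out <- classify(rec)
  expect_identical(out$category, "not_cda")
  expect_match(out$message, "[Hh]emolytic|regenerative")
})

test_that("classify short-circuits and traces every stage", {
  out <- classify(make_rec(age = 40, sex = "M", hb = 15))
  expect_identical(out$category, "no_anemia")
  expect_match(paste(out$trace, collapse = "\n"), "hemoglobin gate")

  out <- classify(make_rec(age = 30, sex = "F", hb = 10, mcv = 88,
                           reticulocytes = 50, platelets = 300))
  expect_identical(out$category, "not_cda")
  expect_match(out$message, "excluded")
  expect_match(paste(out$trace, collapse = "\n"), "exclusion gate")

  # fired-rule outcomes name the rule in the trace
  rec <- make_rec(age = 30, sex = "F", hb = 10, mcv = 88,
                  reticulocytes = 50, platelets = 300,
                  exclusions = "other",
                  features = "binucleated_erythroblasts")
  out <- classify(rec)
  expect_match(paste(out$trace, collapse = "\n"), "fired")
  expect_identical(out$rule_set_version, default_rule_set()$version)
  expect_match(out$disclaimer, "preliminary")
})

test_that("every CDA type carries its published inheritance mode and genes", {
  tab <- cda_types()
  expect_identical(tab$inheritance,
                   c(CDA_I = "AR", CDA_II = "AR", CDA_III = "AD",
                     CDA_IV = "AD", XLDAT = "XL")[tab$code],
                   ignore_attr = TRUE)
  genes <- strsplit(tab$genes, ";")
  names(genes) <- tab$code
  expect_setequal(genes$CDA_I, c("CDAN1", "C15orf41"))
  expect_identical(genes$CDA_II, "SEC23B")
  expect_identical(genes$CDA_III, "KIF23")
  expect_identical(genes$CDA_IV, "KLF1")
  expect_identical(genes$XLDAT, "GATA1")
})

test_that("rule-set validation rejects malformed documents at load time", {
  ok <- list(version = "t1", rules = list(
    list(id = "a", priority = 1, when = list(thrombocytopenia = TRUE),
         outcome = "XLDAT"),
    list(id = "z", priority = 99, when = list(), outcome = "NOT_CDA")))
  expect_s3_class(load_rule_set(ok), "cda_rule_set")

  dup <- ok
  dup$rules[[1]]$priority <- 99
  expect_error(load_rule_set(dup), "duplicate rule priorities")

  expect_error(load_rule_set(list(version = "t1", rules = list())),
               "empty")

  no_catch <- list(version = "t1", rules = ok$rules[1])
  expect_error(load_rule_set(no_catch), "catch-all")

  bad_pred <- ok
  bad_pred$rules[[1]]$when <- list(moon_phase = "full")
  expect_error(load_rule_set(bad_pred), "unknown predicate")

  bad_feat <- ok
  bad_feat$rules[[1]]$when <- list(features_any = list("ringed_sideroblasts"))
  expect_error(load_rule_set(bad_feat), "unknown feature")

  expect_error(load_rule_set(list(rules = ok$rules)), "version")
})

test_that("a custom rule set can emit CDA type IV and overrides the default", {
  rs <- load_rule_set(list(version = "custom-1", rules = list(
    list(id = "cda4", priority = 1,
         when = list(morphology = list("normocytic"),
                     inadequate_reticulocytosis = TRUE),
         outcome = "CDA_IV"),
    list(id = "fallback", priority = 100, when = list(),
         outcome = "NOT_CDA"))))
  rec <- make_rec(age = 30, sex = "F", hb = 10, mcv = 88,
                  reticulocytes = 50, platelets = 300,
                  exclusions = "other")
  out <- classify(rec, rules = rs)
  expect_identical(out$cda_type$code, "CDA_IV")
  expect_identical(out$cda_type$inheritance, "AD")
  expect_identical(out$rule_set_version, "custom-1")
})

test_that("records validate their enum codes and labs", {
  expect_error(patient_record(age = 30, sex = "X", hb = 10),
               "unrecognized sex")
  expect_error(patient_record(age = 30, sex = "F", hb = 10,
                              exclusions = "bad_code"),
               "unknown exclusion")
  expect_error(patient_record(age = 30, sex = "F", hb = 10,
                              features = "bad_feature"),
               "unknown clinical feature")
  expect_error(patient_record(age = -1, sex = "F", hb = 10), "age")
  expect_error(patient_record(age = 30, sex = "F", hb = -2), "hb")
})
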