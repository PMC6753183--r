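# Independent brute-force transcription of the staged decision tree, coded
# as nested if/else directly over flags; deliberately shares no code with
# the rule engine or the YAML rule set.
oracle_classify <- function(hb_flag, mcv_flag, retic_flag, plt_flag,
                            has_exclusion, feats) {
  if (hb_flag == "within") return(list(category = "no_anemia", type = NA))
  if (hb_flag == "above") {
    return(list(category = "hyperhemoglobinemia", type = NA))
  }
  if (!has_exclusion) return(list(category = "not_cda", type = NA))
  inadequate <- retic_flag != "above"
  if (inadequate && plt_flag == "below") {
    return(list(category = "cda_suspicion", type = "XLDAT"))
  }
  if (inadequate && mcv_flag != "below" &&
      "multinucleated_erythroblasts" %in% feats) {
    return(list(category = "cda_suspicion", type = "CDA_III"))
  }
  if (inadequate && mcv_flag == "above" &&
      any(c("binucleated_erythroblasts", "em_features",
            "skeletal_or_limb_malformations") %in% feats)) {
    return(list(category = "cda_suspicion", type = "CDA_I"))
  }
  if (inadequate && mcv_flag == "within" &&
      any(c("binucleated_erythroblasts", "em_features") %in% feats)) {
    return(list(category = "cda_suspicion", type = "CDA_II"))
  }
  list(category = "not_cda", type = NA)
}

# Laboratory values realizing each flag for a 30-year-old male
# (Hb [13, 17.5], MCV [80, 100], reticulocytes [29, 95], platelets
# [145, 450]).
adult_male_values <- list(
  hb = c(below = 10, within = 15, above = 19),
  mcv = c(below = 70, within = 90, above = 110),
  reticulocytes = c(below = 10, within = 60, above = 200),
  platelets = c(below = 90, within = 300, above = 600)
)

flag_record <- function(hb_flag, mcv_flag, retic_flag, plt_flag,
                        has_exclusion, feats) {
  patient_record(
    age = 30, sex = "M",
    hb = adult_male_values$hb[[hb_flag]],
    mcv = adult_male_values$mcv[[mcv_flag]],
    reticulocytes = adult_male_values$reticulocytes[[retic_flag]],
    platelets = adult_male_values$platelets[[plt_flag]],
    exclusions = if (has_exclusion) "other" else character(),
    features = feats)
}

# All subsets of the seven clinical features.
feature_subsets <- function() {
  feats <- clinical_features()
  lapply(0:(2^length(feats) - 1), function(mask) {
    feats[bitwAnd(mask, bitwShiftL(1L, seq_along(feats) - 1L)) != 0L]
  })
}
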