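# Published reference intervals, restated independently of the packaged CSV
# so golden tests compare two transcriptions.
expected_ranges_table <- function() {
  rows <- list(
    c("hemoglobin", "M", "infant_0_6m", 9.5, 18, "g/dL"),
    c("hemoglobin", "M", "child_6m_12y", 11, 15.5, "g/dL"),
    c("hemoglobin", "M", "over_12y", 13, 17.5, "g/dL"),
    c("hemoglobin", "F", "infant_0_6m", 9.5, 18, "g/dL"),
    c("hemoglobin", "F", "child_6m_12y", 11, 15.5, "g/dL"),
    c("hemoglobin", "F", "over_12y", 12, 16, "g/dL"),
    c("mcv", "M", "infant_0_6m", 77.5, 111.5, "fL"),
    c("mcv", "M", "child_6m_12y", 74, 89.5, "fL"),
    c("mcv", "M", "over_12y", 80, 100, "fL"),
    c("mcv", "F", "infant_0_6m", 77.5, 111.5, "fL"),
    c("mcv", "F", "child_6m_12y", 74, 89.5, "fL"),
    c("mcv", "F", "over_12y", 80, 100, "fL"),
    c("reticulocytes", "M", "infant_0_6m", 61, 134, "1e9/L"),
    c("reticulocytes", "M", "child_6m_12y", 24, 114, "1e9/L"),
    c("reticulocytes", "M", "over_12y", 29, 95, "1e9/L"),
    c("reticulocytes", "F", "infant_0_6m", 67, 142, "1e9/L"),
    c("reticulocytes", "F", "child_6m_12y", 40, 162, "1e9/L"),
    c("reticulocytes", "F", "over_12y", 27, 91, "1e9/L"),
    c("platelets", "M", "infant_0_6m", 145, 450, "1e9/L"),
    c("platelets", "M", "child_6m_12y", 145, 450, "1e9/L"),
    c("platelets", "M", "over_12y", 145, 450, "1e9/L"),
    c("platelets", "F", "infant_0_6m", 145, 450, "1e9/L"),
    c("platelets", "F", "child_6m_12y", 145, 450, "1e9/L"),
    c("platelets", "F", "over_12y", 145, 450, "1e9/L")
  )
  data.frame(
    parameter = vapply(rows, `[[`, character(1), 1),
    sex = vapply(rows, `[[`, character(1), 2),
    age_group = vapply(rows, `[[`, character(1), 3),
    low = as.numeric(vapply(rows, `[[`, character(1), 4)),
    high = as.numeric(vapply(rows, `[[`, character(1), 5)),
    unit = vapply(rows, `[[`, character(1), 6),
    stringsAsFactors = FALSE
  )
}
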