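#' Alternative causes of anemia that the workup can exclude
#'
#' Which causes are offered depends on the red-cell morphology: macrocytic
#' anemia lists B12/folate deficiency and hereditary persistence of fetal
#' hemoglobin (HPFH); microcytic lists iron deficiency and thalassemia;
#' normocytic lists hemolytic membrane and enzyme defects. `other` carries a
#' free-text note and is accepted for any morphology.
#'
#' @return Character vector of exclusion-cause codes.
#' @export
exclusion_causes <- function() {
  c("b12_or_folate_deficiency", "hpfh", "iron_deficiency", "thalassemia",
    "hemolytic_membrane_defect", "enzyme_defect", "other")
}

#' Clinical and biochemical features the final step can use
#'
#' @return Character vector of feature codes.
#' @export
clinical_features <- function() {
  c("binucleated_erythroblasts", "multinucleated_erythroblasts",
    "skeletal_or_limb_malformations", "em_features",
    "thrombocytopenia_history", "jaundice", "splenomegaly_or_hepatomegaly")
}

#' CDA types with inheritance mode and causal genes
#'
#' Types I and II are autosomal recessive (CDAN1/C15orf41 and SEC23B),
#' types III and IV autosomal dominant (KIF23 and KLF1), and XLDAT is
#' X-linked (GATA1).
#'
#' @return A data.frame with columns `code`, `inheritance` (`AR`, `AD` or
#'   `XL`) and `genes` (semicolon-separated symbols).
#' @export
#' @examples
#' cda_types()
cda_types <- function() {
  data.frame(
    code = c("CDA_I", "CDA_II", "CDA_III", "CDA_IV", "XLDAT"),
    inheritance = c("AR", "AR", "AD", "AD", "XL"),
    genes = c("CDAN1;C15orf41", "SEC23B", "KIF23", "KLF1", "GATA1"),
    stringsAsFactors = FALSE
  )
}

cda_type_info <- function(code) {
  if (is.null(.codysan$type_info)) {
    tab <- cda_types()
    .codysan$type_info <- stats::setNames(lapply(seq_len(nrow(tab)),
      function(i) list(code = tab$code[i], inheritance = tab$inheritance[i],
                       genes = strsplit(tab$genes[i], ";",
                                        fixed = TRUE)[[1]])),
      tab$code)
  }
  info <- .codysan$type_info[[code]]
  if (is.null(info)) stop("unknown CDA type: ", code, call. = FALSE)
  info
}

#' Standing medical disclaimer attached to every report
#'
#' @return Character scalar.
#' @export
cda_disclaimer <- function() {
  paste("This is a preliminary diagnostic screen, not a diagnosis;",
        "expert medical doctors should be contacted for a conclusive",
        "diagnosis.")
}

#' Construct a validated patient record
#'
#' Laboratory values must already be in canonical units ([canonicalize()]
#' converts them); MCV, reticulocytes and platelets may be omitted until
#' anemia is established, but [classify()] will demand them once the
#' hemoglobin gate proceeds.
#'
#' @param age Age in years, >= 0.
#' @param sex `"M"` or `"F"` (any spelling [normalize_sex()] accepts).
#' @param hb Hemoglobin in g/dL.
#' @param mcv Mean corpuscular volume in fL, or `NULL`.
#' @param reticulocytes Absolute reticulocyte count in 1e9/L, or `NULL`.
#' @param platelets Platelet count in 1e9/L, or `NULL`.
#' @param exclusions Character vector over [exclusion_causes()]; the
#'   alternative causes of anemia that have been ruled out.
#' @param features Character vector over [clinical_features()].
#' @param id Optional identifier.
#' @param other_note Free-text note accompanying an `other` exclusion.
#' @return An object of class `patient_record`.
#' @export
#' @examples
#' patient_record(age = 30, sex = "F", hb = 10, mcv = 88,
#'                reticulocytes = 50, platelets = 300,
#'                exclusions = "hemolytic_membrane_defect",
#'                features = "binucleated_erythroblasts")
patient_record <- function(age, sex, hb, mcv = NULL, reticulocytes = NULL,
                           platelets = NULL, exclusions = character(),
                           features = character(), id = NULL,
                           other_note = NULL) {
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age < 0) {
    stop("`age` must be a single finite number >= 0 (years)", call. = FALSE)
  }
  sex <- normalize_sex(sex)
  check_lab <- function(x, name, required = FALSE) {
    if (is.null(x)) {
      if (required) stop("`", name, "` is required", call. = FALSE)
      return(NULL)
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", name, "` must be a single finite positive number",
           call. = FALSE)
    }
    as.numeric(x)
  }
  hb <- check_lab(hb, "hb", required = TRUE)
  exclusions <- unique(as.character(exclusions))
  features <- unique(as.character(features))
  bad_excl <- setdiff(exclusions, exclusion_causes())
  if (length(bad_excl)) {
    stop("unknown exclusion cause(s): ", paste(bad_excl, collapse = ", "),
         call. = FALSE)
  }
  bad_feat <- setdiff(features, clinical_features())
  if (length(bad_feat)) {
    stop("unknown clinical feature(s): ", paste(bad_feat, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(id = id, age = as.numeric(age), sex = sex, hb = hb,
         mcv = check_lab(mcv, "mcv"),
         reticulocytes = check_lab(reticulocytes, "reticulocytes"),
         platelets = check_lab(platelets, "platelets"),
         exclusions = exclusions, features = features,
         other_note = other_note),
    class = "patient_record"
  )
}

#' First stage: evaluate hemoglobin against its reference interval
#'
#' @param record A [patient_record()].
#' @param table Reference table (defaults to the packaged one).
#' @return `"proceed_anemia"` if hemoglobin is below the stratum's normal
#'   range, `"no_anemia"` if within, `"hyperhemoglobinemia"` if above.
#' @export
hemoglobin_gate <- function(record, table = reference_ranges()) {
  if (is.null(record$hb)) {
    stop("incomplete record: hemoglobin is required", call. = FALSE)
  }
  rv <- lookup_range("hemoglobin", record$sex, get_age_group(record$age),
                     table = table)
  switch(flag_value(record$hb, rv),
         below = "proceed_anemia",
         within = "no_anemia",
         above = "hyperhemoglobinemia")
}

#' Second stage: derive the flags the rules operate on
#'
#' Flags every laboratory value against its (sex, age group) reference
#' interval and derives: morphology from the MCV flag (above = macrocytic,
#' within = normocytic, below = microcytic); `inadequate_reticulocytosis`,
#' true when the reticulocyte count is not elevated above its normal range
#' despite anemia (`reticulocyte_rule = "not_elevated"`, the default) or,
#' under the stricter `"below_only"` rule, only when it is below the range;
#' and `thrombocytopenia`, true when platelets are below range.
#'
#' @param record A [patient_record()] with mcv, reticulocytes and platelets
#'   present.
#' @param table Reference table.
#' @param reticulocyte_rule `"not_elevated"` or `"below_only"`.
#' @return A list of flags (class `cda_flags`).
#' @export
derive_flags <- function(record, table = reference_ranges(),
                         reticulocyte_rule = c("not_elevated", "below_only")) {
  reticulocyte_rule <- match.arg(reticulocyte_rule)
  for (lab in c("mcv", "reticulocytes", "platelets")) {
    if (is.null(record[[lab]])) {
      stop("incomplete record: `", lab, "` is required once anemia is ",
           "established", call. = FALSE)
    }
  }
  grp <- get_age_group(record$age)
  fl <- function(parameter, value) {
    flag_value(value, lookup_range(parameter, record$sex, grp, table = table))
  }
  hb_flag <- fl("hemoglobin", record$hb)
  mcv_flag <- fl("mcv", record$mcv)
  retic_flag <- fl("reticulocytes", record$reticulocytes)
  platelet_flag <- fl("platelets", record$platelets)
  inadequate <- if (reticulocyte_rule == "not_elevated") {
    retic_flag %in% c("below", "within")
  } else {
    retic_flag == "below"
  }
  structure(
    list(hb_flag = hb_flag, mcv_flag = mcv_flag, retic_flag = retic_flag,
         platelet_flag = platelet_flag,
         morphology = switch(mcv_flag, above = "macrocytic",
                             within = "normocytic", below = "microcytic"),
         inadequate_reticulocytosis = inadequate,
         thrombocytopenia = platelet_flag == "below"),
    class = "cda_flags"
  )
}

#' Exclusion causes offered for a morphology
#'
#' @param morphology `"macrocytic"`, `"normocytic"` or `"microcytic"`.
#' @return Character vector of the morphology-specific causes plus `other`.
#' @export
morphology_exclusions <- function(morphology) {
  morphology <- match.arg(morphology,
                          c("macrocytic", "normocytic", "microcytic"))
  specific <- switch(morphology,
    macrocytic = c("b12_or_folate_deficiency", "hpfh"),
    microcytic = c("iron_deficiency", "thalassemia"),
    normocytic = c("hemolytic_membrane_defect", "enzyme_defect")
  )
  c(specific, "other")
}

#' Third stage: require at least one excluded alternative cause
#'
#' At least one alternative cause of anemia must have been excluded for the
#' classification to proceed; any registered cause (including `other`)
#' satisfies the gate, whichever morphology produced it.
#'
#' @param record A [patient_record()].
#' @param morphology Morphology from [derive_flags()] (used for reporting
#'   which causes the workup should consider).
#' @return `"proceed"` or `"insufficient"`.
#' @export
exclusion_gate <- function(record, morphology) {
  if (length(record$exclusions) > 0L) "proceed" else "insufficient"
}

rule_predicates <- function() {
  c("morphology", "inadequate_reticulocytosis", "thrombocytopenia",
    "features_any", "features_all", "sex")
}

rule_outcomes <- function() c(cda_types()$code, "NOT_CDA")

#' Load and validate a rule-set document
#'
#' A rule set is a YAML (or JSON) document with a `version` tag and a list
#' of `rules`, each `{id, priority, when, outcome, message}`. `when` is a
#' conjunction of predicates over the derived flags, the record's features
#' and sex; an empty `when` always matches, and exactly such a catch-all
#' with outcome `NOT_CDA` is mandatory so every input reaches an outcome.
#' Rules are evaluated first-match in ascending priority; duplicate
#' priorities are a validation error, never broken silently.
#'
#' @param source Path to a YAML/JSON document, or an already-parsed list.
#' @return A `cda_rule_set` object (rules sorted by priority).
#' @export
#' @examples
#' rs <- default_rule_set()
#' rs$version
load_rule_set <- function(source) {
  doc <- if (is.character(source) && length(source) == 1L) {
    if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    source
  } else {
    stop("`source` must be a file path or a parsed list", call. = FALSE)
  }
  problems <- character()
  if (is.null(doc$version) || !nzchar(as.character(doc$version)[1])) {
    problems <- c(problems, "missing `version` tag")
  }
  rules <- doc$rules
  if (is.null(rules) || length(rules) == 0L) {
    problems <- c(problems, "rule list is empty")
  }
  flags_bool <- c("inadequate_reticulocytosis", "thrombocytopenia")
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    tag <- if (!is.null(r$id)) r$id else paste0("#", i)
    if (is.null(r$id) || !nzchar(r$id)) {
      problems <- c(problems, sprintf("rule %s: missing id", tag))
    }
    if (is.null(r$priority) || !is.numeric(r$priority)) {
      problems <- c(problems, sprintf("rule %s: missing numeric priority", tag))
    }
    if (is.null(r$outcome) || !(r$outcome %in% rule_outcomes())) {
      problems <- c(problems, sprintf(
        "rule %s: outcome must be one of %s", tag,
        paste(rule_outcomes(), collapse = ", ")))
    }
    w <- r$when
    if (is.null(w)) w <- list()
    unknown <- setdiff(names(w), rule_predicates())
    if (length(unknown)) {
      problems <- c(problems, sprintf("rule %s: unknown predicate field(s) %s",
                                      tag, paste(unknown, collapse = ", ")))
    }
    if (!is.null(w$morphology) &&
        !all(unlist(w$morphology) %in%
               c("macrocytic", "normocytic", "microcytic"))) {
      problems <- c(problems, sprintf("rule %s: bad morphology value", tag))
    }
    for (b in flags_bool) {
      if (!is.null(w[[b]]) && !is.logical(w[[b]])) {
        problems <- c(problems, sprintf("rule %s: `%s` must be boolean",
                                        tag, b))
      }
    }
    for (fk in c("features_any", "features_all")) {
      if (!is.null(w[[fk]]) &&
          !all(unlist(w[[fk]]) %in% clinical_features())) {
        problems <- c(problems, sprintf("rule %s: unknown feature in `%s`",
                                        tag, fk))
      }
    }
    if (!is.null(w$sex) && !all(unlist(w$sex) %in% cda_sexes())) {
      problems <- c(problems, sprintf("rule %s: bad sex value", tag))
    }
  }
  ids <- vapply(rules, function(r) as.character(r$id %||% NA_character_),
                character(1))
  prios <- vapply(rules, function(r) as.numeric(r$priority %||% NA_real_),
                  numeric(1))
  if (anyDuplicated(stats::na.omit(ids))) {
    problems <- c(problems, "duplicate rule ids")
  }
  if (anyDuplicated(stats::na.omit(prios))) {
    problems <- c(problems, "duplicate rule priorities")
  }
  is_catch_all <- vapply(rules, function(r) {
    length(r$when %||% list()) == 0L && identical(r$outcome, "NOT_CDA")
  }, logical(1))
  if (length(rules) && !any(is_catch_all)) {
    problems <- c(problems,
                  "no catch-all rule (empty `when`, outcome NOT_CDA)")
  }
  if (length(problems)) {
    stop("invalid rule set:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  rules <- rules[order(prios)]
  structure(list(version = as.character(doc$version), rules = rules),
            class = "cda_rule_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged default rule set
#'
#' Encodes the staged CDA decision tree: anemia with inadequate
#' reticulocytosis plus thrombocytopenia suggests XLDAT; multinucleated
#' erythroblasts suggest CDA III; macrocytic anemia with dyserythropoietic
#' morphology, EM features or skeletal/limb malformations suggests CDA I;
#' normocytic anemia with binucleated erythroblasts or EM features suggests
#' CDA II; an elevated reticulocyte response, isolated microcytosis, or the
#' absence of any matching pattern yields a reasoned `NOT_CDA`.
#'
#' @return A `cda_rule_set`.
#' @export
default_rule_set <- function() {
  if (is.null(.codysan$rules)) {
    .codysan$rules <- load_rule_set(
      system.file("extdata", "rules_default.yaml", package = "codysan",
                  mustWork = TRUE))
  }
  .codysan$rules
}

rule_matches <- function(rule, flags, record) {
  w <- rule$when %||% list()
  if (!is.null(w$morphology) &&
      !(flags$morphology %in% unlist(w$morphology))) return(FALSE)
  if (!is.null(w$inadequate_reticulocytosis) &&
      !identical(flags$inadequate_reticulocytosis,
                 w$inadequate_reticulocytosis)) return(FALSE)
  if (!is.null(w$thrombocytopenia) &&
      !identical(flags$thrombocytopenia, w$thrombocytopenia)) return(FALSE)
  if (!is.null(w$features_any) &&
      !any(unlist(w$features_any) %in% record$features)) return(FALSE)
  if (!is.null(w$features_all) &&
      !all(unlist(w$features_all) %in% record$features)) return(FALSE)
  if (!is.null(w$sex) && !(record$sex %in% unlist(w$sex))) return(FALSE)
  TRUE
}

new_outcome <- function(category, cda_type = NULL, rule_id = NULL,
                        message, trace, rule_set_version = NA_character_) {
  structure(
    list(category = category, cda_type = cda_type, rule_id = rule_id,
         message = message, trace = trace,
         rule_set_version = rule_set_version,
         disclaimer = cda_disclaimer()),
    class = "cda_outcome"
  )
}

#' Fourth stage: evaluate the rule set over the derived flags
#'
#' Rules are tried in ascending priority; the first whose conjunction of
#' predicates holds fires. A CDA outcome is annotated with the type's
#' inheritance mode and causal genes.
#'
#' @param flags Flags from [derive_flags()].
#' @param record The [patient_record()].
#' @param rules A `cda_rule_set`; defaults to [default_rule_set()].
#' @param trace Trace lines accumulated by earlier stages.
#' @return A `cda_outcome`.
#' @export
apply_rules <- function(flags, record, rules = default_rule_set(),
                        trace = character()) {
  for (rule in rules$rules) {
    if (rule_matches(rule, flags, record)) {
      trace <- c(trace, sprintf("rules: fired '%s' (priority %s) -> %s",
                                rule$id, rule$priority, rule$outcome))
      if (rule$outcome == "NOT_CDA") {
        return(new_outcome("not_cda", rule_id = rule$id,
                           message = rule$message %||%
                             "No clinical suspicion of CDA.",
                           trace = trace,
                           rule_set_version = rules$version))
      }
      info <- cda_type_info(rule$outcome)
      msg <- rule$message %||% sprintf(
        "Clinical suspicion of %s (%s inheritance; genes: %s).",
        info$code, info$inheritance, paste(info$genes, collapse = ", "))
      return(new_outcome("cda_suspicion", cda_type = info,
                         rule_id = rule$id, message = msg, trace = trace,
                         rule_set_version = rules$version))
    }
  }
  # unreachable with a validated rule set (catch-all is mandatory)
  stop("no rule matched; rule set lacks a catch-all", call. = FALSE)
}

#' Classify a patient record through the full staged algorithm
#'
#' Composes the hemoglobin gate, flag derivation, the exclusion gate and
#' the rule engine, short-circuiting with `no_anemia`,
#' `hyperhemoglobinemia` or an insufficient-exclusions rejection where
#' appropriate. The returned trace records every stage.
#'
#' @inheritParams derive_flags
#' @param rules A `cda_rule_set`.
#' @return A `cda_outcome` with `category` one of `no_anemia`,
#'   `hyperhemoglobinemia`, `not_cda`, `cda_suspicion`; `cda_type` is
#'   non-`NULL` exactly when the category is `cda_suspicion`.
#' @export
#' @examples
#' rec <- patient_record(age = 30, sex = "F", hb = 10, mcv = 88,
#'                       reticulocytes = 50, platelets = 300,
#'                       exclusions = "hemolytic_membrane_defect",
#'                       features = "binucleated_erythroblasts")
#' classify(rec)$category
classify <- function(record, rules = default_rule_set(),
                     table = reference_ranges(),
                     reticulocyte_rule = c("not_elevated", "below_only")) {
  stopifnot(inherits(record, "patient_record"))
  reticulocyte_rule <- match.arg(reticulocyte_rule)
  grp <- get_age_group(record$age)
  trace <- sprintf("input: age %.3g y (%s), sex %s, Hb %.3g g/dL",
                   record$age, grp, record$sex, record$hb)
  gate <- hemoglobin_gate(record, table = table)
  trace <- c(trace, sprintf("hemoglobin gate: %s", gate))
  if (gate == "no_anemia") {
    return(new_outcome("no_anemia",
      message = paste("Hemoglobin is within the normal range for this age",
                      "and sex; there is no anemia."),
      trace = trace, rule_set_version = rules$version))
  }
  if (gate == "hyperhemoglobinemia") {
    return(new_outcome("hyperhemoglobinemia",
      message = paste("Hemoglobin is above the normal range for this age",
                      "and sex (hyperhemoglobinemia); this pattern is not",
                      "compatible with CDA."),
      trace = trace, rule_set_version = rules$version))
  }
  flags <- derive_flags(record, table = table,
                        reticulocyte_rule = reticulocyte_rule)
  trace <- c(trace, sprintf(
    "flags: MCV %s (%s), reticulocytes %s (inadequate: %s), platelets %s (thrombocytopenia: %s)",
    flags$mcv_flag, flags$morphology, flags$retic_flag,
    flags$inadequate_reticulocytosis, flags$platelet_flag,
    flags$thrombocytopenia))
  gate3 <- exclusion_gate(record, flags$morphology)
  trace <- c(trace, sprintf("exclusion gate: %s (excluded: %s)", gate3,
                            if (length(record$exclusions))
                              paste(record$exclusions, collapse = ", ")
                            else "none"))
  if (gate3 == "insufficient") {
    offered <- morphology_exclusions(flags$morphology)
    return(new_outcome("not_cda",
      message = sprintf(
        paste("At least one alternative cause of anemia must be excluded",
              "before a CDA suspicion can be raised. For %s anemia,",
              "consider excluding: %s."),
        flags$morphology, paste(offered, collapse = ", ")),
      trace = trace, rule_set_version = rules$version))
  }
  apply_rules(flags, record, rules = rules, trace = trace)
}

#' @export
print.cda_outcome <- function(x, ...) {
  cat("CDA diagnostic outcome\n")
  cat("  category:", x$category, "\n")
  if (!is.null(x$cda_type)) {
    cat(sprintf("  suspicion: %s (%s; genes: %s)\n", x$cda_type$code,
                x$cda_type$inheritance,
                paste(x$cda_type$genes, collapse = ", ")))
  }
  cat("  message: ", x$message, "\n", sep = "")
  cat("  trace:\n")
  for (line in x$trace) cat("    -", line, "\n")
  cat("  rule set:", x$rule_set_version, "\n")
  cat("  ", x$disclaimer, "\n", sep = "")
  invisible(x)
}

#' Serialize an outcome as JSON
#'
#' @param x A `cda_outcome`.
#' @return A JSON string.
#' @export
outcome_to_json <- function(x) {
  stopifnot(inherits(x, "cda_outcome"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, null = "null")
}
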