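# Physiologic truncation bounds for sampled laboratory values
# (canonical units).
.lab_bounds <- list(
  hb = c(3, 25),           # g/dL
  mcv = c(50, 140),        # fL
  reticulocytes = c(1, 600),  # 1e9/L
  platelets = c(5, 1000)      # 1e9/L
)

# Inverse-CDF truncated normal draw.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Default condition profiles for the cohort simulator
#'
#' One profile per condition in the design cohort: the CDA types (CDA II,
#' CDA Ia, CDA Ib, XLDAT) and the non-CDA hereditary-anemia confounders
#' (hereditary spherocytosis, pyruvate kinase deficiency with and without a
#' beta-thalassemia trait, AK1 deficiency, X-linked sideroblastic anemia,
#' dehydrated hereditary stomatocytosis types 1 and 2). Each profile
#' carries truncated-normal sampling parameters per laboratory value (in
#' canonical units), feature emission probabilities, an age range, a male
#' probability, and a workup-compliance probability (the probability that
#' the record arrives with the morphology-appropriate alternative cause
#' already excluded; 1 by default so simulator studies measure the rule
#' logic rather than form compliance).
#'
#' CDA profiles are anemic with a reticulocyte response that is not
#' elevated; hemolytic confounders carry marked reticulocytosis; XLDAT adds
#' thrombocytopenia; the sideroblastic and thalassemia-trait profiles are
#' microcytic. All values are overridable by editing the returned list.
#'
#' @return Named list of condition profiles.
#' @export
condition_profiles <- function() {
  prof <- function(label, hb, mcv, retic, plt, features = c(),
                   p_male = 0.5, age_range = c(2, 70), p_workup = 1) {
    list(label = label, hb = hb, mcv = mcv, reticulocytes = retic,
         platelets = plt, features = features, p_male = p_male,
         age_range = age_range, p_workup = p_workup)
  }
  list(
    CDA_II = prof("CDA",
      hb = c(9.3, 1.2), mcv = c(90, 6), retic = c(55, 22),
      plt = c(250, 70),
      features = c(binucleated_erythroblasts = 0.9, em_features = 0.6,
                   jaundice = 0.6, splenomegaly_or_hepatomegaly = 0.5)),
    CDA_Ia = prof("CDA",
      hb = c(9.0, 1.2), mcv = c(106, 7), retic = c(50, 22),
      plt = c(250, 70),
      features = c(binucleated_erythroblasts = 0.7, em_features = 0.7,
                   skeletal_or_limb_malformations = 0.15, jaundice = 0.5)),
    CDA_Ib = prof("CDA",
      hb = c(8.8, 1.2), mcv = c(106, 7), retic = c(50, 22),
      plt = c(250, 70),
      features = c(binucleated_erythroblasts = 0.7, em_features = 0.7,
                   skeletal_or_limb_malformations = 0.15, jaundice = 0.5)),
    XLDAT = prof("CDA",
      hb = c(8.5, 1.2), mcv = c(95, 7), retic = c(45, 20),
      plt = c(55, 25), p_male = 1,
      features = c(thrombocytopenia_history = 0.9, jaundice = 0.4)),
    HS = prof("NOT_CDA",
      hb = c(10.5, 1.2), mcv = c(85, 6), retic = c(260, 80),
      plt = c(250, 70),
      features = c(jaundice = 0.7, splenomegaly_or_hepatomegaly = 0.7)),
    PK_DEFICIENCY = prof("NOT_CDA",
      hb = c(9.5, 1.4), mcv = c(92, 6), retic = c(280, 90),
      plt = c(250, 70),
      features = c(jaundice = 0.7, splenomegaly_or_hepatomegaly = 0.5)),
    PK_PLUS_BTHAL_TRAIT = prof("NOT_CDA",
      hb = c(9.5, 1.2), mcv = c(68, 5), retic = c(230, 80),
      plt = c(250, 70), features = c(jaundice = 0.6)),
    AK1_DEFICIENCY = prof("NOT_CDA",
      hb = c(9.5, 1.2), mcv = c(90, 6), retic = c(250, 80),
      plt = c(250, 70), features = c(jaundice = 0.6)),
    XLSA = prof("NOT_CDA",
      hb = c(9.0, 1.2), mcv = c(65, 5), retic = c(40, 18),
      plt = c(250, 70), p_male = 1, features = c()),
    DHS1 = prof("NOT_CDA",
      hb = c(10.5, 1.2), mcv = c(96, 6), retic = c(230, 80),
      plt = c(250, 70),
      features = c(jaundice = 0.5, splenomegaly_or_hepatomegaly = 0.4)),
    DHS2 = prof("NOT_CDA",
      hb = c(10.5, 1.2), mcv = c(96, 6), retic = c(230, 80),
      plt = c(250, 70),
      features = c(jaundice = 0.5, splenomegaly_or_hepatomegaly = 0.4))
  )
}

validate_profile <- function(profile, condition = "<profile>") {
  need <- c("label", "hb", "mcv", "reticulocytes", "platelets",
            "features", "p_male", "age_range", "p_workup")
  missing <- setdiff(need, names(profile))
  if (length(missing)) {
    stop(sprintf("profile %s is missing field(s): %s", condition,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!(profile$label %in% c("CDA", "NOT_CDA"))) {
    stop(sprintf("profile %s: label must be CDA or NOT_CDA", condition),
         call. = FALSE)
  }
  for (lab in c("hb", "mcv", "reticulocytes", "platelets")) {
    p <- profile[[lab]]
    if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p)) || p[2] <= 0) {
      stop(sprintf("profile %s: `%s` must be c(mean, sd) with sd > 0",
                   condition, lab), call. = FALSE)
    }
  }
  fp <- profile$features
  if (length(fp)) {
    if (is.null(names(fp)) || !all(names(fp) %in% clinical_features()) ||
        any(fp < 0) || any(fp > 1)) {
      stop(sprintf(
        "profile %s: features must be named probabilities in [0,1] over %s",
        condition, "clinical_features()"), call. = FALSE)
    }
  }
  if (any(profile$p_male < 0 | profile$p_male > 1) ||
      any(profile$p_workup < 0 | profile$p_workup > 1)) {
    stop(sprintf("profile %s: probabilities must be in [0,1]", condition),
         call. = FALSE)
  }
  invisible(profile)
}

#' Composition of the 43-patient design cohort
#'
#' 24 CDA patients (18 CDA II, 4 CDA Ia, 1 CDA Ib, 1 XLDAT) and 19 non-CDA
#' hereditary anemias (8 hereditary spherocytosis, 4 pyruvate kinase
#' deficiency, 1 pyruvate kinase deficiency with beta-thalassemia trait,
#' 1 AK1 deficiency, 1 X-linked sideroblastic anemia, 3 DHS1, 1 DHS2).
#'
#' @return Named integer vector mapping condition to count (total 43).
#' @export
#' @examples
#' sum(design_composition())
design_composition <- function() {
  c(CDA_II = 18L, CDA_Ia = 4L, CDA_Ib = 1L, XLDAT = 1L,
    HS = 8L, PK_DEFICIENCY = 4L, PK_PLUS_BTHAL_TRAIT = 1L,
    AK1_DEFICIENCY = 1L, XLSA = 1L, DHS1 = 3L, DHS2 = 1L)
}

#' Composition of the 23-patient validation cohort
#'
#' @return `c(CDA_II = 23L)`.
#' @export
validation_composition <- function() {
  c(CDA_II = 23L)
}

#' Simulate one labeled patient
#'
#' Draws laboratory values from the profile's truncated normal
#' distributions (truncation at physiologic bounds keeps every value
#' positive), samples sex, age and features, and emits the
#' morphology-appropriate excluded cause with the profile's workup
#' probability. Uses the current RNG stream; seed control belongs to
#' [simulate_cohort()].
#'
#' @param profile A single profile from [condition_profiles()].
#' @param condition Condition name used as record id prefix.
#' @return A list with `record` (a [patient_record()]) and `label`
#'   (`"CDA"` or `"NOT_CDA"`).
#' @export
simulate_patient <- function(profile, condition = "sim") {
  validate_profile(profile, condition)
  draw <- function(lab) {
    b <- .lab_bounds[[lab]]
    rtrunc_norm(1, profile[[lab]][1], profile[[lab]][2], b[1], b[2])
  }
  sex <- if (stats::runif(1) < profile$p_male) "M" else "F"
  age <- stats::runif(1, profile$age_range[1], profile$age_range[2])
  feats <- names(profile$features)[
    stats::runif(length(profile$features)) < profile$features]
  mcv <- draw("mcv")
  excl <- character()
  if (stats::runif(1) < profile$p_workup) {
    rv <- lookup_range("mcv", sex, get_age_group(age))
    morph <- switch(flag_value(mcv, rv), above = "macrocytic",
                    within = "normocytic", below = "microcytic")
    excl <- morphology_exclusions(morph)[1]
  }
  rec <- patient_record(
    age = age, sex = sex, hb = draw("hb"), mcv = mcv,
    reticulocytes = draw("reticulocytes"), platelets = draw("platelets"),
    exclusions = excl, features = feats, id = condition)
  list(record = rec, label = profile$label)
}

#' Simulate a labeled cohort
#'
#' Per-condition counts are exact (not multinomial); the output order is a
#' seed-determined shuffle. Identical (composition, profiles, seed) yield
#' identical cohorts.
#'
#' @param composition Named integer vector, condition -> count, e.g.
#'   [design_composition()].
#' @param profiles Named list of profiles covering every composition
#'   condition; defaults to [condition_profiles()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `cda_cohort`: list with `records` (list of
#'   [patient_record()]), `labels`, and `conditions` (parallel character
#'   vectors).
#' @export
#' @examples
#' cohort <- simulate_cohort(design_composition(), seed = 1)
#' length(cohort$records)
simulate_cohort <- function(composition, profiles = condition_profiles(),
                            seed = NULL) {
  if (is.null(names(composition)) || any(composition < 0) ||
      sum(composition) == 0) {
    stop("`composition` must be a named vector of counts >= 0, total > 0",
         call. = FALSE)
  }
  missing_prof <- setdiff(names(composition)[composition > 0],
                          names(profiles))
  if (length(missing_prof)) {
    stop("no profile for condition(s): ",
         paste(missing_prof, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  conditions <- rep(names(composition), times = composition)
  out <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    sim <- simulate_patient(profiles[[cond]], condition = cond)
    sim$record$id <- sprintf("%s_%03d", cond, i)
    out[[i]] <- sim
  }
  ord <- sample.int(length(out))
  out <- out[ord]
  structure(
    list(records = lapply(out, `[[`, "record"),
         labels = vapply(out, `[[`, character(1), "label"),
         conditions = conditions[ord]),
    class = "cda_cohort"
  )
}

#' Flatten a cohort to a data.frame in the patient-table format
#'
#' Columns match the CSV layout [read_patients()] consumes, with values in
#' canonical units.
#'
#' @param x A `cda_cohort`.
#' @param ... Unused.
#' @return A data.frame, one row per patient.
#' @export
as.data.frame.cda_cohort <- function(x, ...) {
  rows <- lapply(seq_along(x$records), function(i) {
    r <- x$records[[i]]
    data.frame(
      id = r$id, age = r$age, age_unit = "years", sex = r$sex,
      hb = r$hb, hb_unit = "g/dL", mcv = r$mcv, mcv_unit = "fL",
      retics = r$reticulocytes, retics_unit = "1e9/L", rbc = NA_real_,
      platelets = r$platelets, platelets_unit = "1e9/L",
      exclusions = paste(r$exclusions, collapse = ";"),
      features = paste(r$features, collapse = ";"),
      condition = x$conditions[i], label = x$labels[i],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
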