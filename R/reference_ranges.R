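#' @keywords internal
.codysan <- new.env(parent = emptyenv())

#' Hematological parameters evaluated by the algorithm
#'
#' @return Character vector of the four parameter codes, in canonical order.
#' @export
#' @examples
#' cda_parameters()
cda_parameters <- function() {
  c("hemoglobin", "mcv", "reticulocytes", "platelets")
}

#' Canonical reporting unit for a parameter
#'
#' Hemoglobin is expressed in g/dL, MCV in fL, and reticulocyte and platelet
#' counts as absolute concentrations in 1e9/L.
#'
#' @param parameter One of [cda_parameters()].
#' @return Unit label, a length-one character vector.
#' @export
canonical_unit <- function(parameter) {
  parameter <- match.arg(parameter, cda_parameters())
  c(hemoglobin = "g/dL", mcv = "fL",
    reticulocytes = "1e9/L", platelets = "1e9/L")[[parameter]]
}

#' Recognized sex codes
#'
#' @return `c("M", "F")`.
#' @export
cda_sexes <- function() c("M", "F")

#' Age strata used for reference-interval lookup
#'
#' Three groups partition all non-negative ages: 0 to under 6 months,
#' 6 months to under 12 years, and 12 years and older.
#'
#' @return Character vector of the three age-group codes.
#' @export
cda_age_groups <- function() {
  c("infant_0_6m", "child_6m_12y", "over_12y")
}

#' Normalize a sex code
#'
#' Accepts `"M"`/`"F"` in any case as well as the spelled-out words.
#'
#' @param sex Character scalar.
#' @return `"M"` or `"F"`.
#' @export
normalize_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L || is.na(sex)) {
    stop("`sex` must be a single character code", call. = FALSE)
  }
  if (sex == "M" || sex == "F") return(sex)
  code <- switch(tolower(trimws(sex)),
    "m" = , "male" = "M",
    "f" = , "female" = "F",
    NULL
  )
  if (is.null(code)) {
    stop(sprintf("unrecognized sex code '%s' (expected M or F)", sex),
         call. = FALSE)
  }
  code
}

#' Map an age in years to its reference stratum
#'
#' The strata are half-open on the right, so a boundary age belongs to the
#' older group: ages in \[0, 0.5) are infants, \[0.5, 12) are children, and
#' 12 and above are adults/adolescents. Ages given in months should be
#' divided by 12 before calling.
#'
#' @param age Numeric vector of ages in years, each finite and >= 0.
#' @return Character vector of age-group codes, same length as `age`.
#' @export
#' @examples
#' get_age_group(c(0.25, 0.5, 30))
get_age_group <- function(age) {
  if (!is.numeric(age) || length(age) == 0L) {
    stop("`age` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("`age` must be finite and >= 0 (in years)", call. = FALSE)
  }
  ifelse(age < 0.5, "infant_0_6m",
         ifelse(age < 12, "child_6m_12y", "over_12y"))
}

#' Load the reference-interval table
#'
#' The table holds one row per (parameter, sex, age group): 4 x 2 x 3 = 24
#' normal intervals in canonical units, as published for the CoDysAn
#' algorithm. MCV and platelet intervals are sex-identical but are stored
#' per sex so the schema is uniform. A replacement table (for example from
#' an updated reference book) can be supplied via `path`; it is validated
#' against the same completeness and ordering invariants.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `parameter, sex, age_group, low, high, unit`.
#' @return A data.frame with 24 rows and those six columns.
#' @export
#' @examples
#' head(reference_ranges())
reference_ranges <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.codysan$ranges)) return(.codysan$ranges)
    path <- system.file("extdata", "reference_ranges.csv",
                        package = "codysan", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_reference_table(tab)
  if (cache) {
    .codysan$ranges <- tab
    .codysan$range_index <- build_range_index(tab)
  }
  tab
}

# Named-list index over (parameter, sex, age_group) so the hot path in
# classify() avoids repeated data.frame subsetting.
build_range_index <- function(tab) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tab))) {
    key <- paste(tab$parameter[i], tab$sex[i], tab$age_group[i], sep = "|")
    assign(key, list(parameter = tab$parameter[i], sex = tab$sex[i],
                     age_group = tab$age_group[i], low = tab$low[i],
                     high = tab$high[i], unit = tab$unit[i]), envir = idx)
  }
  idx
}

validate_reference_table <- function(tab) {
  required <- c("parameter", "sex", "age_group", "low", "high", "unit")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("reference table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- interaction(tab$parameter, tab$sex, tab$age_group, drop = FALSE)
  full <- expand.grid(parameter = cda_parameters(), sex = cda_sexes(),
                      age_group = cda_age_groups(),
                      stringsAsFactors = FALSE)
  want <- interaction(full$parameter, full$sex, full$age_group)
  if (nrow(tab) != 24L || anyDuplicated(key) || !all(want %in% key)) {
    stop("reference table must contain exactly the 24 (parameter, sex, ",
         "age group) combinations", call. = FALSE)
  }
  if (any(!is.finite(tab$low)) || any(!is.finite(tab$high)) ||
      any(tab$low <= 0) || any(tab$low >= tab$high)) {
    stop("reference table bounds must satisfy 0 < low < high", call. = FALSE)
  }
  expected_unit <- vapply(tab$parameter, canonical_unit, character(1))
  if (any(tab$unit != expected_unit)) {
    stop("reference table units must be canonical for each parameter",
         call. = FALSE)
  }
  invisible(tab)
}

#' Look up one reference interval
#'
#' @param parameter One of [cda_parameters()].
#' @param sex `"M"` or `"F"` (or a spelling [normalize_sex()] accepts).
#' @param age_group One of [cda_age_groups()].
#' @param table Reference table, by default the packaged one.
#' @return A list with fields `parameter`, `sex`, `age_group`, `low`,
#'   `high`, `unit`.
#' @export
#' @examples
#' lookup_range("hemoglobin", "M", "over_12y")
lookup_range <- function(parameter, sex, age_group,
                         table = reference_ranges()) {
  parameter <- match.arg(parameter, cda_parameters())
  sex <- normalize_sex(sex)
  age_group <- match.arg(age_group, cda_age_groups())
  if (identical(table, .codysan$ranges) && !is.null(.codysan$range_index)) {
    hit <- get0(paste(parameter, sex, age_group, sep = "|"),
                envir = .codysan$range_index)
    if (!is.null(hit)) return(hit)
  }
  hit <- table$parameter == parameter & table$sex == sex &
    table$age_group == age_group
  if (sum(hit) != 1L) {
    stop("reference table is corrupt: expected exactly one entry for ",
         paste(parameter, sex, age_group, sep = "/"), call. = FALSE)
  }
  row <- table[hit, , drop = FALSE]
  list(parameter = parameter, sex = sex, age_group = age_group,
       low = row$low, high = row$high, unit = row$unit)
}

#' Flag a value against a reference interval
#'
#' Bounds are inclusive: a value exactly equal to either bound counts as
#' within the normal range (the conservative clinical reading).
#'
#' @param value Numeric vector of values in the interval's canonical unit;
#'   each must be finite and > 0.
#' @param range A reference interval as returned by [lookup_range()], or
#'   any list with numeric `low` and `high`.
#' @return Character vector over `c("below", "within", "above")`.
#' @export
#' @examples
#' rv <- lookup_range("hemoglobin", "M", "over_12y")
#' flag_value(c(12.9, 13, 18), rv)
flag_value <- function(value, range) {
  if (!is.numeric(value) || length(value) == 0L) {
    stop("`value` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("`value` must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(range$low) || !is.numeric(range$high)) {
    stop("`range` must carry numeric low/high bounds", call. = FALSE)
  }
  if (length(value) == 1L) {
    if (value < range$low) return("below")
    if (value > range$high) return("above")
    return("within")
  }
  ifelse(value < range$low, "below",
         ifelse(value > range$high, "above", "within"))
}
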