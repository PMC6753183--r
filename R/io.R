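.patient_columns <- c("id", "age", "age_unit", "sex", "hb", "hb_unit",
                      "mcv", "mcv_unit", "retics", "retics_unit", "rbc",
                      "platelets", "platelets_unit", "exclusions",
                      "features")

#' Read patient records from CSV or JSON
#'
#' The CSV layout has one row per patient with columns `id, age, age_unit,
#' sex, hb, hb_unit, mcv, mcv_unit, retics, retics_unit, rbc, platelets,
#' platelets_unit, exclusions, features`; `exclusions` and `features` are
#' semicolon-separated codes, `age_unit` is `years` or `months`, and `rbc`
#' (red-cell count, 1e12/L) is only needed when reticulocytes are given as
#' a percentage. The JSON form is an array of objects with the same
#' fields. Every value is canonicalized through the unit registry; all
#' row-level problems are collected and reported together with their row
#' numbers.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return List of [patient_record()] objects (empty, with a warning, for
#'   an empty file).
#' @export
read_patients <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  rows <- if (format == "json") {
    lst <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(lst, function(x) x)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    missing_cols <- setdiff(setdiff(.patient_columns, "id"), names(tab))
    if (length(missing_cols)) {
      stop("patient table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
  }
  if (length(rows) == 0L) {
    warning("no patient rows in ", path, call. = FALSE)
    return(list())
  }
  errors <- character()
  records <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    rec <- tryCatch(parse_patient_row(rows[[i]], i),
                    error = function(e) {
                      errors <<- c(errors, sprintf("row %d: %s", i,
                                                   conditionMessage(e)))
                      NULL
                    })
    records[[i]] <- rec
  }
  if (length(errors)) {
    stop("failed to load ", path, ":\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  ids <- vapply(records, function(r) as.character(r$id %||% NA_character_),
                character(1))
  dup <- ids[!is.na(ids) & duplicated(ids)]
  if (length(dup)) {
    stop("duplicate patient id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  records
}

num_or_null <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  x <- trimws(as.character(x))
  if (!nzchar(x) || is.na(x) || toupper(x) == "NA") return(NULL)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("not a number: '", x, "'", call. = FALSE)
  v
}

split_codes <- function(x) {
  if (is.null(x)) return(character())
  if (is.list(x)) return(unlist(x, use.names = FALSE))
  x <- trimws(as.character(x))
  if (length(x) != 1L || !nzchar(x) || is.na(x)) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

parse_patient_row <- function(row, i) {
  age <- num_or_null(row$age)
  if (is.null(age)) stop("missing age", call. = FALSE)
  age_unit <- tolower(trimws(as.character(row$age_unit %||% "years")))
  if (!nzchar(age_unit)) age_unit <- "years"
  age <- switch(age_unit,
                years = , y = age,
                months = , m = age / 12,
                stop("unknown age unit '", age_unit, "'", call. = FALSE))
  rbc <- num_or_null(row$rbc)
  lab <- function(parameter, value_field, unit_field) {
    v <- num_or_null(row[[value_field]])
    if (is.null(v)) return(NULL)
    unit <- trimws(as.character(row[[unit_field]] %||% ""))
    if (!nzchar(unit)) unit <- canonical_unit(parameter)
    canonicalize(parameter, v, unit, rbc = rbc)
  }
  hb <- lab("hemoglobin", "hb", "hb_unit")
  if (is.null(hb)) stop("missing hemoglobin", call. = FALSE)
  patient_record(
    age = age, sex = as.character(row$sex), hb = hb,
    mcv = lab("mcv", "mcv", "mcv_unit"),
    reticulocytes = lab("reticulocytes", "retics", "retics_unit"),
    platelets = lab("platelets", "platelets", "platelets_unit"),
    exclusions = split_codes(row$exclusions),
    features = split_codes(row$features),
    id = if (!is.null(row$id) && nzchar(trimws(as.character(row$id))))
           trimws(as.character(row$id)) else sprintf("row%d", i))
}

#' Write a cohort (or list of records) to the patient CSV format
#'
#' @param x A `cda_cohort` or a list of [patient_record()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_patients <- function(x, path) {
  tab <- if (inherits(x, "cda_cohort")) {
    as.data.frame(x)
  } else {
    as.data.frame(structure(list(records = x,
                                 labels = rep(NA_character_, length(x)),
                                 conditions = rep(NA_character_, length(x))),
                            class = "cda_cohort"))
  }
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Look up laboratories offering genetic testing for a CDA gene
#'
#' Consults a packaged, synthetic snapshot in the shape of a
#' genetic-testing-registry export (gene, lab name, country, URL); a
#' locally maintained TSV with the same columns can be supplied instead.
#' The packaged rows are placeholders, not real laboratories.
#'
#' @param gene Gene symbol (e.g. `"SEC23B"`); `NULL` returns all rows.
#' @param path Optional path to an alternative TSV.
#' @return A data.frame with columns `gene`, `lab_name`, `country`, `url`.
#' @export
gene_labs <- function(gene = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gtr_labs_synthetic.tsv",
                        package = "codysan", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "lab_name", "country", "url")
  if (!all(need %in% names(tab))) {
    stop("lab registry must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(gene)) tab <- tab[tab$gene == gene, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
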