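#' Tabulate a binary confusion matrix for CDA suspicion
#'
#' The positive class is "CDA suspicion of any type": a predicted outcome
#' counts as positive iff its category is `cda_suspicion`, whatever the
#' suspected type; every other category (`no_anemia`,
#' `hyperhemoglobinemia`, `not_cda`) is negative. Truth labels are
#' `"CDA"` / `"NOT_CDA"`.
#'
#' @param truth Character vector of true labels.
#' @param predicted List of `cda_outcome` objects, or a character vector of
#'   outcome categories.
#' @return A `cda_confusion` list with integer fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
#' @examples
#' cm <- confusion_matrix(c("CDA", "NOT_CDA"),
#'                        c("cda_suspicion", "no_anemia"))
#' cm$tp + cm$tn
confusion_matrix <- function(truth, predicted) {
  if (is.list(predicted)) {
    predicted <- vapply(predicted, function(o) {
      stopifnot(inherits(o, "cda_outcome"))
      o$category
    }, character(1))
  }
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length", call. = FALSE)
  }
  bad <- setdiff(unique(truth), c("CDA", "NOT_CDA"))
  if (length(bad)) {
    stop("truth labels must be CDA or NOT_CDA; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pos_pred <- predicted == "cda_suspicion"
  pos_true <- truth == "CDA"
  structure(
    list(tp = sum(pos_true & pos_pred), fp = sum(!pos_true & pos_pred),
         tn = sum(!pos_true & !pos_pred), fn = sum(pos_true & !pos_pred)),
    class = "cda_confusion"
  )
}

check_cm <- function(cm) {
  if (!is.list(cm) || !all(c("tp", "fp", "tn", "fn") %in% names(cm))) {
    stop("`cm` must carry tp, fp, tn, fn counts", call. = FALSE)
  }
  counts <- unlist(cm[c("tp", "fp", "tn", "fn")])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  invisible(cm)
}

#' Sensitivity (true positive rate)
#'
#' @param cm A confusion matrix from [confusion_matrix()] or any list with
#'   `tp`, `fp`, `tn`, `fn`.
#' @return `tp / (tp + fn)`, a fraction in \[0, 1\].
#' @export
#' @examples
#' sensitivity(list(tp = 21, fp = 0, tn = 0, fn = 3))
sensitivity <- function(cm) {
  check_cm(cm)
  if (cm$tp + cm$fn == 0) {
    stop("sensitivity is undefined: no positive (CDA) cases", call. = FALSE)
  }
  cm$tp / (cm$tp + cm$fn)
}

#' Specificity (true negative rate)
#'
#' @inheritParams sensitivity
#' @return `tn / (tn + fp)`, a fraction in \[0, 1\].
#' @export
#' @examples
#' specificity(list(tp = 0, fp = 2, tn = 17, fn = 0))
specificity <- function(cm) {
  check_cm(cm)
  if (cm$tn + cm$fp == 0) {
    stop("specificity is undefined: no negative (non-CDA) cases",
         call. = FALSE)
  }
  cm$tn / (cm$tn + cm$fp)
}

#' Classify a cohort and score it against its true labels
#'
#' Runs [classify()] on every record, tabulates the binary confusion
#' matrix, and reports sensitivity and specificity (each `NA` when
#' undefined for the cohort composition — e.g. specificity on an all-CDA
#' validation cohort — rather than a misleading number) plus a per-condition
#' breakdown of predicted categories and suspected types.
#'
#' @param cohort A `cda_cohort` from [simulate_cohort()], or a list with
#'   `records`, `labels`, `conditions`.
#' @param rules A `cda_rule_set`.
#' @param reticulocyte_rule Passed to [classify()].
#' @return A `cda_evaluation` list: `confusion`, `sensitivity`,
#'   `specificity`, `n`, `outcomes`, `per_condition` (data.frame).
#' @export
#' @examples
#' cohort <- simulate_cohort(design_composition(), seed = 1)
#' ev <- evaluate_cohort(cohort)
#' ev$sensitivity
evaluate_cohort <- function(cohort, rules = default_rule_set(),
                            reticulocyte_rule = "not_elevated") {
  outcomes <- lapply(cohort$records, classify, rules = rules,
                     reticulocyte_rule = reticulocyte_rule)
  cm <- confusion_matrix(cohort$labels, outcomes)
  sens <- if (cm$tp + cm$fn > 0) sensitivity(cm) else NA_real_
  spec <- if (cm$tn + cm$fp > 0) specificity(cm) else NA_real_
  categories <- vapply(outcomes, `[[`, character(1), "category")
  types <- vapply(outcomes, function(o) {
    if (is.null(o$cda_type)) NA_character_ else o$cda_type$code
  }, character(1))
  per_condition <- as.data.frame(
    table(condition = cohort$conditions,
          predicted = ifelse(categories == "cda_suspicion",
                             paste0("suspicion:", types), categories)),
    stringsAsFactors = FALSE)
  per_condition <- per_condition[per_condition$Freq > 0, ]
  rownames(per_condition) <- NULL
  structure(
    list(confusion = cm, sensitivity = sens, specificity = spec,
         n = length(outcomes), outcomes = outcomes,
         per_condition = per_condition,
         rule_set_version = rules$version),
    class = "cda_evaluation"
  )
}

#' @export
print.cda_evaluation <- function(x, ...) {
  cat("Cohort evaluation (positive class: CDA suspicion)\n")
  cat(sprintf("  n = %d; TP %d, FP %d, TN %d, FN %d\n", x$n,
              x$confusion$tp, x$confusion$fp, x$confusion$tn,
              x$confusion$fn))
  cat(sprintf("  sensitivity: %s\n",
              if (is.na(x$sensitivity)) "undefined (no CDA cases)"
              else sprintf("%.1f%%", 100 * x$sensitivity)))
  cat(sprintf("  specificity: %s\n",
              if (is.na(x$specificity)) "undefined (no non-CDA cases)"
              else sprintf("%.1f%%", 100 * x$specificity)))
  cat("  per-condition breakdown:\n")
  print(x$per_condition, row.names = FALSE)
  cat("  rule set:", x$rule_set_version, "\n")
  cat("  ", cda_disclaimer(), "\n", sep = "")
  invisible(x)
}
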