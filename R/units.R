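# Clinical unit registry. Each parameter maps unit label -> multiplicative
# factor to the canonical unit; reticulocyte percent is the one non-linear
# entry (it needs the red-cell count) and is handled explicitly.
.unit_factors <- list(
  hemoglobin = c("g/dL" = 1, "g/L" = 0.1, "mmol/L" = 1.6114),
  mcv = c("fL" = 1),
  reticulocytes = c("1e9/L" = 1, "1e3/uL" = 1),
  platelets = c("1e9/L" = 1, "1e3/uL" = 1)
)

#' Units accepted for a parameter
#'
#' The first element is always the canonical unit. Hemoglobin may be given
#' in g/dL, g/L or mmol/L (monomer convention, 1 mmol/L = 1.6114 g/dL);
#' counts in 1e9/L or the numerically identical 1e3/uL; reticulocytes also
#' as a percentage of red cells, which requires the red-cell count.
#'
#' @param parameter One of [cda_parameters()].
#' @return Character vector of unit labels.
#' @export
#' @examples
#' supported_units("reticulocytes")
supported_units <- function(parameter) {
  parameter <- match.arg(parameter, cda_parameters())
  units <- names(.unit_factors[[parameter]])
  if (parameter == "reticulocytes") units <- c(units, "%")
  units
}

#' Convert a laboratory value to the canonical unit
#'
#' Reticulocytes reported as a percentage are converted to an absolute
#' count: `percent / 100 * rbc * 1000` in 1e9/L, where `rbc` is the
#' red-cell count in 1e12/L. The red-cell count must be supplied
#' explicitly; there is no assumed default.
#'
#' @param parameter One of [cda_parameters()].
#' @param value Positive finite numeric vector.
#' @param unit Unit label, one of [supported_units()] for the parameter.
#' @param rbc Red-cell count in 1e12/L; required only for reticulocyte
#'   percentages.
#' @return Numeric vector in the parameter's canonical unit.
#' @export
#' @examples
#' canonicalize("hemoglobin", 130, "g/L")
#' canonicalize("reticulocytes", 1.0, "%", rbc = 5.0)
canonicalize <- function(parameter, value, unit, rbc = NULL) {
  parameter <- match.arg(parameter, cda_parameters())
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    stop("`value` must be finite and > 0", call. = FALSE)
  }
  if (!is.character(unit) || length(unit) != 1L) {
    stop("`unit` must be a single unit label", call. = FALSE)
  }
  if (!(unit %in% supported_units(parameter))) {
    stop(sprintf("unit '%s' is not supported for %s (accepted: %s)",
                 unit, parameter,
                 paste(supported_units(parameter), collapse = ", ")),
         call. = FALSE)
  }
  if (unit == "%") {
    if (is.null(rbc)) {
      stop("reticulocyte percentage requires the red-cell count ",
           "(`rbc`, in 1e12/L)", call. = FALSE)
    }
    if (!is.numeric(rbc) || any(!is.finite(rbc)) || any(rbc <= 0)) {
      stop("`rbc` must be finite and > 0 (1e12/L)", call. = FALSE)
    }
    return(value / 100 * rbc * 1000)
  }
  value * .unit_factors[[parameter]][[unit]]
}

#' Express a canonical value in an alternate registered unit
#'
#' The exact inverse of [canonicalize()]; used when exporting records in a
#' laboratory's preferred unit and to verify conversion round-trips.
#'
#' @inheritParams canonicalize
#' @param value Numeric vector in the canonical unit.
#' @return Numeric vector in `unit`.
#' @export
from_canonical <- function(parameter, value, unit, rbc = NULL) {
  parameter <- match.arg(parameter, cda_parameters())
  if (!(unit %in% supported_units(parameter))) {
    stop(sprintf("unit '%s' is not supported for %s", unit, parameter),
         call. = FALSE)
  }
  if (unit == "%") {
    if (is.null(rbc)) {
      stop("reticulocyte percentage requires the red-cell count ",
           "(`rbc`, in 1e12/L)", call. = FALSE)
    }
    return(value * 100 / (rbc * 1000))
  }
  value / .unit_factors[[parameter]][[unit]]
}
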