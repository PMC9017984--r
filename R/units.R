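#' Convert physiological quantities to internal SI units
#'
#' The physiology literature reports tissue perfusion as mL/100 mL(tissue)/min
#' and glucose metabolism as umol/100 mL(tissue)/min. All model equations are
#' dimensionally consistent only in strict SI, so internally perfusion is a
#' rate constant in s^-1 and metabolism a volumetric rate in mol m^-3 s^-1.
#' Glucose concentrations in mM are numerically identical to mol m^-3 and pass
#' through unchanged.
#'
#' @param value Numeric vector in conventional units (`to_si`) or SI
#'   (`from_si`). Must be finite.
#' @param kind One of `"flow"` (mL/100 mL/min <-> s^-1), `"metabolism"`
#'   (umol/100 mL/min <-> mol m^-3 s^-1) or `"concentration"` (mM <->
#'   mol m^-3, the identity).
#' @return Numeric vector of the same length, converted.
#' @examples
#' to_si(4, "flow")        # 6.667e-4 s^-1
#' to_si(0.8, "metabolism") # 1.333e-4 mol m^-3 s^-1
#' from_si(to_si(4, "flow"), "flow") # exact round trip
#' @export
to_si <- function(value, kind = c("flow", "metabolism", "concentration")) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || any(!is.finite(value))) {
    abort("`value` must be finite numeric.")
  }
  switch(kind,
    flow = value / (100 * 60),
    metabolism = value * 1e-6 / (1e-4 * 60),
    concentration = value
  )
}

#' @rdname to_si
#' @export
from_si <- function(value, kind = c("flow", "metabolism", "concentration")) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || any(!is.finite(value))) {
    abort("`value` must be finite numeric.")
  }
  switch(kind,
    flow = value * (100 * 60),
    metabolism = value / (1e-6 / (1e-4 * 60)),
    concentration = value
  )
}
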