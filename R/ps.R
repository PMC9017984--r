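# Apparent endothelial permeability-surface area (PS) product from flow and
# concentrations, Renkin-Crone style with a non-zero interstitial
# concentration: PS = -F ln[(Cv - Ci)/(Ca - Ci)]. Because microdialysis
# underestimates Ci, the PS inferred from measured concentrations (PS_m)
# is itself biased.

new_md_ps <- function(ps, variant, F_si, Ca, Cv, Ci) {
  structure(
    list(ps = ps, variant = variant,
         inputs = list(F = F_si, Ca = Ca, Cv = Cv, Ci = Ci)),
    class = "md_ps"
  )
}

#' Apparent endothelial PS product
#'
#' `PS = -F ln[(Cv - Ci)/(Ca - Ci)]`, in s^-1 (equivalently mL/mL/s). The
#' expression is only defined while the extraction is incomplete,
#' `Ci < Cv < Ca`; at `Ci >= Cv` the log argument is non-positive
#' ("elevated extraction") and an error is raised.
#'
#' @param F_blood Blood flow in SI units (s^-1), e.g. `to_si(4, "flow")`.
#' @param Ca,Cv Arterial and venous glucose concentrations (mM), `Ca > Cv`.
#' @param Ci Interstitial glucose concentration (mM).
#' @return An object of class `md_ps` with element `ps` (s^-1).
#' @examples
#' ps_true(to_si(4, "flow"), Ca = 5, Cv = 4.8, Ci = 4.7)$ps # 7.3e-4 s^-1
#' @export
ps_true <- function(F_blood, Ca, Cv, Ci) {
  if (F_blood <= 0) abort("`F_blood` must be positive (s^-1).")
  if (Ca <= Cv) abort("Arterial concentration must exceed venous (Ca > Cv).")
  if (Ci >= Cv) {
    abort("elevated extraction: PS is undefined when Ci >= Cv (log argument <= 0).")
  }
  frac <- (Cv - Ci) / (Ca - Ci)
  new_md_ps(-F_blood * log(frac), "true", F_blood, Ca, Cv, Ci)
}

#' PS product as it would be measured through microdialysis
#'
#' Applies the steady removal-bias map `Ci,0 -> Ci,eff` before the PS
#' formula: `PS_m = -F ln[(Cv - Ci,eff)/(Ca - Ci,eff)]`. Since PS is
#' increasing in the interstitial concentration (on `Ci < Cv`),
#' underestimating the concentration underestimates PS.
#'
#' @param phys A [phys_params()] object (supplies `F`, `Ca` and, through the
#'   mass balance, `Cv`).
#' @param probe A [probe_params()] object.
#' @param Ci0 True interstitial concentration (mM); defaults to the model's
#'   own [igc_quick()] prediction.
#' @return An object of class `md_ps` (variant `"measured"`).
#' @export
ps_measured <- function(phys, probe, Ci0 = igc_quick(phys)) {
  stopifnot(inherits(phys, "phys_params"), inherits(probe, "probe_params"))
  a <- bias_alpha(phys, probe)
  Ci_eff <- (1 - a) * Ci0 + a * probe$Cp
  res <- ps_true(phys$F, phys$Ca, venous_concentration(phys), Ci_eff)
  res$variant <- "measured"
  res
}

#' @export
print.md_ps <- function(x, ...) {
  cat(sprintf("<md_ps (%s)>\n", x$variant))
  cat(sprintf("  PS = %.4g s^-1 = %s\n", x$ps, format_ps(x)))
  cat(sprintf("  inputs: F = %.4g s^-1, Ca = %.3g, Cv = %.3g, Ci = %.4g mM\n",
              x$inputs$F, x$inputs$Ca, x$inputs$Cv, x$inputs$Ci))
  invisible(x)
}

#' Format a PS product in conventional reporting units
#'
#' @param x An `md_ps` object or a numeric PS in s^-1.
#' @return A string in units of 1e-4 mL/mL/s.
#' @export
format_ps <- function(x) {
  ps <- if (inherits(x, "md_ps")) x$ps else x
  sprintf("%.2g x 1e-4 mL/mL/s", ps / 1e-4)
}
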