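# Steady-state three-compartment (plasma / endothelium / interstitium) model
# on a Krogh cone: a single capillary of plasma radius rp and outer wall
# radius rw supplies a conical tissue domain whose radius tapers linearly
# from rt_a (arterial end) to rt_v (venous end). Axial positions are
# normalized, xi = x / L_cap; the capillary length cancels from the axial
# profile under the per-cone mass-balance normalization, so it never needs
# to be specified.

#' Local tissue-cone radius
#'
#' Linear taper from the arterial radius `rt_a` at `xi = 0` to the venous
#' radius `rt_v` at `xi = 1`.
#'
#' @param phys A [phys_params()] object.
#' @param xi Normalized axial position(s) in \[0, 1\].
#' @return Radius (m), vectorized over `xi`.
#' @export
cone_radius <- function(phys, xi) {
  stopifnot(inherits(phys, "phys_params"))
  if (any(xi < 0 | xi > 1)) abort("`xi` must lie in [0, 1].")
  phys$rt_a + xi * (phys$rt_v - phys$rt_a)
}

# Integral over [0, xi] of (rt(s)^2 - rw^2), in m^2 (xi dimensionless).
# Closed form for the linear taper; cone_supply_integral(1) is the cone's
# annular cross-section integral, proportional to its tissue volume.
cone_supply_integral <- function(phys, xi) {
  d <- phys$rt_v - phys$rt_a
  (phys$rt_a^2 - phys$rw^2) * xi + phys$rt_a * d * xi^2 + d^2 * xi^3 / 3
}

#' Mean plasma glucose concentration along the capillary
#'
#' Integrates the axial supply balance over the cone: the glucose carried by
#' the capillary decreases in proportion to the metabolism of the tissue
#' annulus passed so far. Normalizing the per-capillary plasma flow by the
#' cone tissue volume makes the profile independent of capillary length and
#' guarantees the end value equals the venous concentration `Ca - M/F`.
#'
#' @param phys A [phys_params()] object.
#' @param xi Normalized axial position(s) in \[0, 1\].
#' @return Mean plasma concentration (mM), vectorized over `xi`.
#' @examples
#' axial_plasma_profile(phys_params(), c(0, 1)) # c(5, 4.8) at rest
#' @export
axial_plasma_profile <- function(phys, xi) {
  stopifnot(inherits(phys, "phys_params"))
  if (any(xi < 0 | xi > 1)) abort("`xi` must lie in [0, 1].")
  frac <- cone_supply_integral(phys, xi) / cone_supply_integral(phys, 1)
  cbar <- phys$Ca - (phys$M / phys$F) * frac
  if (any(cbar < 0)) {
    abort("Parameters imply negative plasma concentration along the capillary.")
  }
  cbar
}

# Radial drop from the mean plasma concentration to the plasma-wall
# interface; tiny at physiological Dp.
plasma_radial_drop <- function(phys, rt) {
  phys$M * (rt^2 - phys$rw^2) / (8 * phys$Dp)
}

#' Glucose concentration difference across the endothelium
#'
#' The cross-endothelial gradient carries the full metabolic flux of the
#' tissue annulus through the thin wall, so it is proportional to `M` and
#' inversely proportional to the wall diffusion coefficient `Dw`:
#' `M (rt^2 - rw^2) ln(rw/rp) / (2 Dw)`.
#'
#' @param phys A [phys_params()] object.
#' @param rt Tissue radius (m) feeding the wall flux; defaults to the
#'   representative midpoint [rt_mid()].
#' @return Concentration difference (mM). About 0.2 mM at basal rest.
#' @export
endothelial_gradient <- function(phys, rt = rt_mid(phys)) {
  stopifnot(inherits(phys, "phys_params"))
  if (any(rt <= phys$rw)) abort("`rt` must exceed the wall radius rw.")
  phys$M * (rt^2 - phys$rw^2) * log(phys$rw / phys$rp) / (2 * phys$Dw)
}

# Drop within the interstitium from the wall (r = rw) out to radius r,
# for tissue radius rt: M/(4 Vi Di) * [rw^2 - r^2 + 2 rt^2 ln(r/rw)].
interstitial_drop <- function(phys, r, rt) {
  phys$M / (4 * phys$Vi * phys$Di) *
    (phys$rw^2 - r^2 + 2 * rt^2 * log(r / phys$rw))
}

#' Interstitial glucose concentration profile around a capillary
#'
#' Radial concentration within the interstitial annulus `rw <= r <= rt(xi)`,
#' obtained from the wall concentration minus the (very small) diffusive drop
#' required to carry the metabolic flux through the interstitium.
#'
#' @param phys A [phys_params()] object.
#' @param r Radial distance(s) from the capillary axis (m).
#' @param xi Normalized axial position (scalar, default 0.5).
#' @return Concentration (mM), vectorized over `r`.
#' @export
interstitial_profile <- function(phys, r, xi = 0.5) {
  stopifnot(inherits(phys, "phys_params"), length(xi) == 1)
  rt <- cone_radius(phys, xi)
  if (any(r < phys$rw | r > rt)) abort("`r` must lie in [rw, rt(xi)].")
  c_rw <- axial_plasma_profile(phys, xi) -
    plasma_radial_drop(phys, rt) -
    endothelial_gradient(phys, rt)
  c_rw - interstitial_drop(phys, r, rt)
}

#' Analytic radial gradient of the interstitial profile
#'
#' `dC/dr = M / (2 Vi Di) * (r - rt^2 / r)`; vanishes at the no-flux outer
#' boundary `r = rt` and is negative (outward transport) inside.
#'
#' @param phys A [phys_params()] object.
#' @param r Radial distance(s) from the capillary axis (m).
#' @param rt Tissue radius (m); defaults to [rt_mid()].
#' @return Gradient (mM per m), vectorized over `r`.
#' @export
interstitial_gradient <- function(phys, r, rt = rt_mid(phys)) {
  stopifnot(inherits(phys, "phys_params"))
  if (any(r < phys$rw | r > rt)) abort("`r` must lie in [rw, rt].")
  phys$M / (2 * phys$Vi * phys$Di) * (r - rt^2 / r)
}

#' Quick estimate of the unperturbed interstitial glucose concentration
#'
#' Assumes uniform uptake along the capillary (plasma term `(Ca + Cv)/2`) and
#' neglects the interstitial drop, leaving the cross-endothelial gradient at
#' the representative radius: `(Ca + Cv)/2 - M (rt^2 - rw^2) ln(rw/rp)/(2 Dw)`.
#' About 4.7 mM at basal rest.
#'
#' @param phys A [phys_params()] object.
#' @return Estimated interstitial concentration `Ci,0` (mM).
#' @export
igc_quick <- function(phys) {
  stopifnot(inherits(phys, "phys_params"))
  (phys$Ca + venous_concentration(phys)) / 2 -
    endothelial_gradient(phys, rt_mid(phys))
}

#' Unperturbed interstitial glucose concentration from the full chain
#'
#' Chains the axial plasma profile, plasma radial drop, endothelial gradient
#' and the volume-averaged interstitial drop at one axial position. Agrees
#' with [igc_quick()] to within a few hundredths of a mM at the midpoint.
#'
#' @param phys A [phys_params()] object.
#' @param xi Normalized axial evaluation position (default 0.5, matching the
#'   plasma mean `(Ca + Cv)/2` of the quick estimate).
#' @return Interstitial concentration `Ci,0` (mM).
#' @export
igc_full <- function(phys, xi = 0.5) {
  stopifnot(inherits(phys, "phys_params"), length(xi) == 1)
  rt <- cone_radius(phys, xi)
  # volume-averaged interstitial drop over the annulus [rw, rt]
  num <- integrate(function(r) interstitial_drop(phys, r, rt) * r,
                   phys$rw, rt, rel.tol = 1e-10)$value
  den <- (rt^2 - phys$rw^2) / 2
  axial_plasma_profile(phys, xi) -
    plasma_radial_drop(phys, rt) -
    endothelial_gradient(phys, rt) -
    num / den
}

#' Axial and radial concentration profiles as a tidy table
#'
#' Convenience export of the compartment model: the axial mean plasma
#' profile plus, at a chosen axial position, the radial profile through
#' plasma wall, endothelium and interstitium.
#'
#' @param phys A [phys_params()] object.
#' @param n_axial,n_radial Number of sample points (defaults 51 each).
#' @param xi Axial position for the radial profile (default 0.5).
#' @return A tibble with columns `coordinate` (`"xi"` or `"r"`), `value`
#'   (dimensionless xi or r in m), `compartment` and `concentration_mM`.
#' @export
compartment_profiles <- function(phys, n_axial = 51, n_radial = 51, xi = 0.5) {
  stopifnot(inherits(phys, "phys_params"))
  xis <- seq(0, 1, length.out = n_axial)
  axial <- tibble::tibble(
    coordinate = "xi", value = xis, compartment = "plasma",
    concentration_mM = axial_plasma_profile(phys, xis)
  )
  rt <- cone_radius(phys, xi)
  rs <- seq(phys$rw, rt, length.out = n_radial)
  radial <- tibble::tibble(
    coordinate = "r", value = rs, compartment = "interstitium",
    concentration_mM = interstitial_profile(phys, rs, xi)
  )
  wall <- tibble::tibble(
    coordinate = "r",
    value = c(phys$rp, phys$rw),
    compartment = c("plasma", "endothelium"),
    concentration_mM = c(
      axial_plasma_profile(phys, xi) - plasma_radial_drop(phys, rt),
      axial_plasma_profile(phys, xi) - plasma_radial_drop(phys, rt) -
        endothelial_gradient(phys, rt)
    )
  )
  dplyr::bind_rows(axial, wall, radial)
}
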