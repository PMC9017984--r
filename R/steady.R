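# Steady-state radial reaction--diffusion model of the interstitial glucose
# field around a microdialysis probe. Glucose removed at the probe wall is
# resupplied by the capillary bed; linearizing the compartment model around
# the unperturbed state gives a local resupply rate gamma(r) =
# (Ci,0 - Ci(r)) / A, with the timescale A combining the plasma depletion
# term 1/(2F) and the cross-endothelial transport term
# (rt^2 - rw^2) ln(rw/rp) / (2 Dw). The field then satisfies the modified
# Helmholtz equation, whose decaying axisymmetric solution is
# Ci(r) = Ci,0 + B K0(r / lambda), lambda = sqrt(Di Vi A), with B fixed by
# the Robin (probe-uptake) condition at the membrane, r = r1:
# Di Vi dCi/dr = beta (Ci(r1) - Cp).

#' Capillary resupply timescale and screening length
#'
#' The resupply timescale `A` (s) sums a plasma-depletion component
#' `1/(2F)` and an endothelial component
#' `(rt^2 - rw^2) ln(rw/rp) / (2 Dw)`; the screening length
#' `lambda = sqrt(Di Vi A)` (m) sets how far the probe's influence extends
#' into the tissue (about 0.6 mm at basal parameters).
#'
#' @param phys A [phys_params()] object.
#' @param rt Representative tissue radius (m); defaults to [rt_mid()].
#' @return An object of class `md_sink`: list with `A`, `lambda`,
#'   `plasma_component` and `wall_component` (both s).
#' @export
sink_timescale <- function(phys, rt = rt_mid(phys)) {
  stopifnot(inherits(phys, "phys_params"))
  plasma <- 1 / (2 * phys$F)
  wall <- (rt^2 - phys$rw^2) * log(phys$rw / phys$rp) / (2 * phys$Dw)
  A <- plasma + wall
  structure(
    list(A = A, lambda = sqrt(phys$Di * phys$Vi * A),
         plasma_component = plasma, wall_component = wall),
    class = "md_sink"
  )
}

#' @export
print.md_sink <- function(x, ...) {
  cat("<md_sink>\n")
  cat(sprintf("  A = %.4g s (plasma %.4g + wall %.4g), lambda = %.4g m\n",
              x$A, x$plasma_component, x$wall_component, x$lambda))
  invisible(x)
}

# Bias amplitude alpha from the closed form:
# alpha = (beta/DiVi) K0(x1) / [K1(x1)/lambda + (beta/DiVi) K0(x1)],
# x1 = r1/lambda. Exact for the infinite-domain Bessel solution.
alpha_closed_form <- function(phys, probe, rt = rt_mid(phys)) {
  st <- sink_timescale(phys, rt)
  x1 <- probe$r1 / st$lambda
  bfac <- probe$beta / (phys$Di * phys$Vi)
  bfac * besselK(x1, 0) / (besselK(x1, 1) / st$lambda + bfac * besselK(x1, 0))
}

new_md_steady <- function(phys, probe, Ci0, st, alpha, profile, r2, method) {
  Ci_eff <- Ci0 - alpha * (Ci0 - probe$Cp)
  removal <- probe$R0 * probe$f * (Ci_eff - probe$Cp)
  structure(
    list(phys = phys, probe = probe, Ci0 = Ci0, Cp = probe$Cp,
         A = st$A, lambda = st$lambda, alpha = alpha, Ci_eff = Ci_eff,
         removal_rate = removal, flux_r1 = removal / probe$S_probe,
         profile = profile, r2 = r2, method = method),
    class = "md_steady"
  )
}

#' Steady-state interstitial glucose field around a microdialysis probe
#'
#' Solves the radial modified-Helmholtz problem for the interstitial
#' concentration `Ci(r)` between the probe membrane (`r1`, Robin uptake
#' condition) and the unperturbed far field (`Ci,0`). The primary route is
#' the closed-form Bessel `K0` solution, which is exact for the linear
#' operator; [solve_steady_fd()] provides an independent finite-difference
#' solution of the same problem for numerical cross-checks.
#'
#' @param phys A [phys_params()] object.
#' @param probe A [probe_params()] object (perfusate concentration `Cp` is
#'   taken from it).
#' @param Ci0 Unperturbed interstitial concentration far from the probe (mM),
#'   e.g. from [igc_quick()].
#' @param r2 Outer radius of the reported domain (m); default `50 * r1`
#'   (12.5 mm for the standard probe, about 20 screening lengths). An error
#'   is raised if the solution has not decayed to the far-field value there.
#' @param n Number of radial sample points in the stored profile
#'   (log-spaced; default 400).
#' @param rt Representative tissue radius for the sink term (m).
#' @return An object of class `md_steady` with elements `alpha`
#'   (dimensionless bias amplitude), `Ci_eff` (concentration at the membrane,
#'   mM), `removal_rate` (`R0 f (Ci_eff - Cp)`, mol s^-1), `flux_r1`
#'   (mol m^-2 s^-1), `lambda`, `A`, and a tibble `profile` with columns
#'   `r`, `Ci` and the resupply rate `gamma = (Ci0 - Ci)/A`
#'   (mol m^-3 s^-1). See [tidy.md_steady()] / [glance.md_steady()].
#' @examples
#' fit <- solve_steady(phys_params(), probe_params(), Ci0 = 4.7)
#' glance(fit) # alpha ~ 0.54, Ci_eff ~ 3.3 mM
#' @export
solve_steady <- function(phys, probe, Ci0, r2 = 50 * probe$r1, n = 400,
                         rt = rt_mid(phys)) {
  stopifnot(inherits(phys, "phys_params"), inherits(probe, "probe_params"))
  if (Ci0 < 0) abort("`Ci0` must be non-negative.")
  if (r2 <= probe$r1) abort("`r2` must exceed the probe radius r1.")
  st <- sink_timescale(phys, rt)
  x1 <- probe$r1 / st$lambda
  bfac <- probe$beta / (phys$Di * phys$Vi)
  B <- -bfac * (Ci0 - probe$Cp) /
    (besselK(x1, 1) / st$lambda + bfac * besselK(x1, 0))
  if (abs(B) * besselK(r2 / st$lambda, 0) > 1e-4) {
    abort("`r2` is too small: the field has not converged to Ci0 there.")
  }
  alpha <- -B * besselK(x1, 0) / (Ci0 - probe$Cp)
  if (Ci0 == probe$Cp) alpha <- alpha_closed_form(phys, probe, rt)
  r <- exp(seq(log(probe$r1), log(r2), length.out = n))
  Ci <- Ci0 + B * besselK(r / st$lambda, 0)
  if (any(Ci < 0)) {
    warn("Negative interstitial concentrations: the linear removal model is outside its validity range.")
  }
  profile <- tibble::tibble(r = r, Ci = Ci, gamma = (Ci0 - Ci) / st$A)
  new_md_steady(phys, probe, Ci0, st, alpha, profile, r2, method = "bessel")
}

#' @rdname solve_steady
#' @param n_fd Number of finite-difference nodes (log-spaced; default 2001).
#' @export
solve_steady_fd <- function(phys, probe, Ci0, r2 = 50 * probe$r1,
                            n_fd = 2001, rt = rt_mid(phys)) {
  stopifnot(inherits(phys, "phys_params"), inherits(probe, "probe_params"))
  st <- sink_timescale(phys, rt)
  DiVi <- phys$Di * phys$Vi
  r <- exp(seq(log(probe$r1), log(r2), length.out = n_fd))
  n <- n_fd
  rh <- (r[-1] + r[-n]) / 2
  h <- diff(r)
  # conservative finite-volume discretization of
  # DiVi (1/r) d/dr(r dCi/dr) = (Ci - Ci0)/A, Robin at r1, Dirichlet at r2
  i <- 2:(n - 1)
  voli <- r[i] * (rh[i] - rh[i - 1])
  aW <- DiVi * rh[i - 1] / h[i - 1] / voli
  aE <- DiVi * rh[i] / h[i] / voli
  diag_i <- -(aW + aE) - 1 / st$A
  vol1 <- (rh[1]^2 - r[1]^2) / 2
  a1E <- DiVi * rh[1] / h[1] / vol1
  a1P <- -a1E - probe$beta * r[1] / vol1 - 1 / st$A
  rhs <- c(-probe$beta * r[1] * probe$Cp / vol1 - Ci0 / st$A,
           rep(-Ci0 / st$A, n - 2), Ci0)
  M <- Matrix::sparseMatrix(
    i = c(1, 1, i, i, i, n),
    j = c(1, 2, i - 1, i, i + 1, n),
    x = c(a1P, a1E, aW, diag_i, aE, 1),
    dims = c(n, n)
  )
  Ci <- as.numeric(Matrix::solve(M, rhs))
  alpha <- if (Ci0 != probe$Cp) (Ci0 - Ci[1]) / (Ci0 - probe$Cp) else
    alpha_closed_form(phys, probe, rt)
  profile <- tibble::tibble(r = r, Ci = Ci, gamma = (Ci0 - Ci) / st$A)
  new_md_steady(phys, probe, Ci0, st, alpha, profile, r2, method = "fd")
}

#' @export
print.md_steady <- function(x, ...) {
  cat(sprintf("<md_steady (%s)>\n", x$method))
  cat(sprintf("  Ci0 = %.3g mM, Cp = %.3g mM\n", x$Ci0, x$Cp))
  cat(sprintf("  alpha = %.4f, Ci_eff = %.4g mM (underestimation %.1f%%)\n",
              x$alpha, x$Ci_eff,
              if (x$Ci0 > 0) 100 * (x$Ci0 - x$Ci_eff) / x$Ci0 else NA_real_))
  cat(sprintf("  removal rate = %.3g mol/s, lambda = %.3g m\n",
              x$removal_rate, x$lambda))
  invisible(x)
}

#' Bias amplitude of the steady probe--tissue exchange
#'
#' The bias amplitude `alpha` is the proportionality constant between the
#' measurement bias `Ci,0 - Ci,eff` and the driving difference `Ci,0 - Cp`.
#' By linearity it is independent of both concentrations, so one solve with
#' an arbitrary pair determines it.
#'
#' @param phys A [phys_params()] object.
#' @param probe A [probe_params()] object.
#' @param rt Representative tissue radius for the sink term (m).
#' @return `alpha` in \[0, 1\] (about 0.54 for the standard parameters).
#' @export
bias_alpha <- function(phys, probe, rt = rt_mid(phys)) {
  stopifnot(inherits(phys, "phys_params"), inherits(probe, "probe_params"))
  alpha_closed_form(phys, probe, rt)
}

#' Predicted measured concentration as a function of the true concentration
#'
#' Evaluates `Ci,eff = (1 - alpha) Ci,0 + alpha Cp` over a grid of true
#' interstitial concentrations: a straight line through `(Cp, Cp)` with
#' slope `1 - alpha`.
#'
#' @param phys A [phys_params()] object.
#' @param probe A [probe_params()] object.
#' @param Ci0 Grid of true concentrations (mM); default 50 points spanning
#'   `[Cp, 8]` mM.
#' @return A tibble of class `md_bias_curve` with columns `Ci0`, `Ci_eff`,
#'   `underestimation_pct` and `abs_bias` (mM).
#' @export
bias_curve <- function(phys, probe, Ci0 = seq(probe$Cp, 8, length.out = 50)) {
  a <- bias_alpha(phys, probe)
  out <- tibble::tibble(
    Ci0 = Ci0,
    Ci_eff = (1 - a) * Ci0 + a * probe$Cp,
    abs_bias = a * (Ci0 - probe$Cp),
    underestimation_pct = ifelse(Ci0 > 0, 100 * a * (Ci0 - probe$Cp) / Ci0,
                                 NA_real_)
  )
  class(out) <- c("md_bias_curve", class(out))
  attr(out, "alpha") <- a
  attr(out, "Cp") <- probe$Cp
  out
}

#' Two-dimensional concentration map around the probe
#'
#' Expands the axisymmetric steady solution into a cross-sectional map and
#' locates the isocontour radii where the field equals given fractions of
#' `Ci,0`. Contours that would fall below the membrane concentration
#' `Ci_eff/Ci0` do not exist and are flagged `NA` (not an error).
#'
#' @param phys A [phys_params()] object.
#' @param probe A [probe_params()] object.
#' @param Ci0 True interstitial concentration (mM).
#' @param levels Contour levels as fractions of `Ci0`
#'   (default `c(0.99, 0.95, 0.90, 0.80, 0.70)`).
#' @param r2 Outer domain radius (m).
#' @return An object of class `md_field`: the underlying `md_steady` fit
#'   plus a tibble `contours` with columns `level` and `radius` (m), and
#'   `affected_radius`, the 95% contour radius (perturbation >= 5%).
#' @export
field_map <- function(phys, probe, Ci0,
                      levels = c(0.99, 0.95, 0.90, 0.80, 0.70),
                      r2 = 50 * probe$r1) {
  fit <- solve_steady(phys, probe, Ci0, r2 = r2)
  radius_at <- function(level) {
    target <- level * Ci0
    if (target <= fit$Ci_eff || Ci0 <= fit$probe$Cp) return(NA_real_)
    if (target >= Ci0) return(NA_real_)
    # invert Ci(r) = Ci0 + B K0(r/lambda) for r
    prof <- fit$profile
    approx(prof$Ci, prof$r, xout = target, ties = "ordered")$y
  }
  contours <- tibble::tibble(
    level = levels,
    radius = vapply(levels, radius_at, numeric(1))
  )
  structure(
    list(fit = fit, contours = contours,
         affected_radius = radius_at(0.95)),
    class = "md_field"
  )
}

#' @export
print.md_field <- function(x, ...) {
  cat("<md_field>\n")
  cat(sprintf("  Ci0 = %.3g mM, Ci_eff = %.3g mM\n", x$fit$Ci0, x$fit$Ci_eff))
  print(x$contours)
  invisible(x)
}
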