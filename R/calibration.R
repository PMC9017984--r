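# Recovery calibration under glucose removal. The probe's true recovery R0
# relates dialysate to membrane concentration; removal depresses the
# membrane concentration itself, so a calibration performed wait_time after
# onset measures Rm = (1 - alpha_t(wait_time)) R0 rather than R0, and the
# inferred interstitial concentration Ci,m lands between Ci,eff (no
# calibration bias) and Ci,0 (fully settled calibration: the two biases
# cancel exactly).

#' Dialysate concentration leaving the probe
#'
#' `Cd = (1 - R0) Cp + R0 Ci_eff`: the perfusate equilibrates toward the
#' membrane concentration by the true recovery fraction.
#'
#' @param probe A [probe_params()] object (supplies `R0` and `Cp`).
#' @param Ci_eff Effective membrane concentration (mM).
#' @param Cp Optional perfusate concentration override (mM).
#' @return Dialysate concentration (mM).
#' @examples
#' dialysate_concentration(probe_params(), Ci_eff = 3.3) # 2.65 mM
#' @export
dialysate_concentration <- function(probe, Ci_eff, Cp = probe$Cp) {
  stopifnot(inherits(probe, "probe_params"))
  (1 - probe$R0) * Cp + probe$R0 * Ci_eff
}

new_md_calibration <- function(method, probe, R0, Rm, alpha, alpha_tilde,
                               Ci0, Ci_m, Cd_points = NULL, fit = NULL) {
  structure(
    list(method = method, probe = probe, R0 = R0, Rm = Rm, alpha = alpha,
         alpha_tilde = alpha_tilde, Ci0 = Ci0, Ci_m = Ci_m,
         Cd_points = Cd_points, fit = fit),
    class = "md_calibration"
  )
}

#' @export
print.md_calibration <- function(x, ...) {
  cat(sprintf("<md_calibration (%s)>\n", x$method))
  cat(sprintf("  R0 = %.3f -> Rm = %.4f (alpha_tilde = %.4f, alpha = %.4f)\n",
              x$R0, x$Rm, x$alpha_tilde, x$alpha))
  cat(sprintf("  Ci0 = %.3g mM -> measured Ci_m = %.4g mM\n", x$Ci0, x$Ci_m))
  invisible(x)
}

#' Simulated no-net-flux recovery calibration
#'
#' For each perfusate concentration in `Cp_grid` the probe-bias model is run
#' for `wait_time` after onset; the dialysate concentration is regressed on
#' the perfusate concentration and the measured recovery is `1 - slope`.
#' Because the removal model is linear in the driving difference, the
#' `(Cp, Cd)` points remain exactly collinear even under glucose removal,
#' and the slope yields `Rm = (1 - alpha_t(wait_time)) R0`.
#'
#' @param phys A [phys_params()] object.
#' @param probe A [probe_params()] object.
#' @param Ci0 True interstitial concentration (mM).
#' @param Cp_grid Perfusate concentrations sampled during calibration (mM);
#'   default `c(0, 1, 2, 4, 6)`. At least two distinct values.
#' @param wait_time Time waited after removal onset before each dialysate
#'   sample (s); `Inf` (default) means fully settled (`alpha_t = alpha`), 0
#'   means instantaneous (unbiased calibration).
#' @param n Radial nodes for the transient solves at finite `wait_time`.
#' @return An object of class `md_calibration` with the measured recovery
#'   `Rm`, the bias factors, the `(Cp, Cd)` points, and the measured
#'   concentration `Ci_m` the experimenter would report (the subsequent
#'   measurement itself is taken at steady state).
#' @export
no_net_flux <- function(phys, probe, Ci0, Cp_grid = c(0, 1, 2, 4, 6),
                        wait_time = Inf, n = 150) {
  stopifnot(inherits(phys, "phys_params"), inherits(probe, "probe_params"))
  if (length(unique(Cp_grid)) < 2) {
    abort("`Cp_grid` needs at least two distinct perfusate concentrations.")
  }
  if (wait_time < 0) abort("`wait_time` must be non-negative.")
  alpha <- bias_alpha(phys, probe)
  ci_eff_at <- function(cp) {
    pr <- probe_params(R0 = probe$R0, f = probe$f, L = probe$L,
                       r1 = probe$r1, Cp = cp)
    if (is.infinite(wait_time)) {
      solve_steady(phys, pr, Ci0, n = 50)$Ci_eff
    } else if (wait_time == 0) {
      Ci0
    } else {
      sol <- solve_transient(phys, pr, Ci0, t_end = wait_time, n = n,
                             times = c(0, wait_time))
      sol$trace$Ci_eff[nrow(sol$trace)]
    }
  }
  pts <- tibble::tibble(
    Cp = Cp_grid,
    Ci_eff = vapply(Cp_grid, ci_eff_at, numeric(1))
  )
  pts$Cd <- (1 - probe$R0) * pts$Cp + probe$R0 * pts$Ci_eff
  fit <- lm(Cd ~ Cp, data = pts)
  max_resid <- max(abs(resid(fit)))
  if (max_resid > 1e-6) {
    abort("No-net-flux points deviate from collinearity beyond solver tolerance.")
  }
  Rm <- 1 - unname(coef(fit)[2])
  a_t <- 1 - Rm / probe$R0
  Ci_m <- measured_igc_closed_form(Ci0, probe$Cp, alpha, a_t)
  new_md_calibration("no-net-flux", probe, probe$R0, Rm, alpha, a_t,
                     Ci0, Ci_m, Cd_points = pts, fit = fit)
}

#' Simulated internal-reference recovery calibration
#'
#' The measured recovery from the fractional loss of a perfusate glucose
#' tracer is depressed by the tracer that has already accumulated around the
#' probe: `Rm = (1 - Ci*(r1, wait_time)/Cp*) R0`, which mirrors the
#' no-net-flux bias at equal wait time to within about a percent.
#'
#' @param phys A [phys_params()] object.
#' @param probe A [probe_params()] object.
#' @param tracer A [tracer_params()] object.
#' @param Ci0 True interstitial concentration (mM).
#' @param wait_time Calibration wait after tracer onset (s); `Inf` for the
#'   settled limit.
#' @param n Radial nodes for the tracer solver.
#' @return An object of class `md_calibration`.
#' @export
internal_reference <- function(phys, probe, tracer = tracer_params(), Ci0,
                               wait_time = Inf, n = 200) {
  stopifnot(inherits(phys, "phys_params"), inherits(probe, "probe_params"))
  if (wait_time < 0) abort("`wait_time` must be non-negative.")
  alpha <- bias_alpha(phys, probe)
  ratio <- if (wait_time == 0) {
    0
  } else if (is.infinite(wait_time)) {
    tracer_steady_ratio(phys, probe, tracer, Ci0 = Ci0)
  } else {
    acc <- tracer_accumulation(phys, probe, tracer, Ci0 = Ci0,
                               t_end = wait_time, n = n,
                               times = c(0, wait_time))
    acc$trace$ratio[nrow(acc$trace)]
  }
  Rm <- (1 - ratio) * probe$R0
  a_t <- 1 - Rm / probe$R0
  Ci_m <- measured_igc_closed_form(Ci0, probe$Cp, alpha, a_t)
  new_md_calibration("internal-reference", probe, probe$R0, Rm, alpha, a_t,
                     Ci0, Ci_m)
}

#' Measured interstitial concentration from dialysate and recovery
#'
#' The experimenter's inversion `Ci,m = (Cd - (1 - Rm) Cp) / Rm`, and its
#' closed-form equivalent in terms of the bias amplitudes,
#' `Ci,m = ((1 - alpha) Ci,0 + (alpha - alpha_tilde) Cp) / (1 - alpha_tilde)`
#' (the dialysate sample itself taken at steady state, the recovery
#' calibrated at `alpha_tilde`). The two routes agree to machine precision.
#'
#' @param Cd Dialysate concentration (mM).
#' @param Rm Measured (possibly biased) recovery; must be positive.
#' @param Cp Perfusate concentration (mM).
#' @return Measured concentration `Ci,m` (mM).
#' @export
measured_igc <- function(Cd, Rm, Cp) {
  if (any(Rm <= 0)) abort("`Rm` must be positive.")
  (Cd - (1 - Rm) * Cp) / Rm
}

#' @rdname measured_igc
#' @param Ci0 True interstitial concentration (mM).
#' @param alpha Steady bias amplitude.
#' @param alpha_tilde Bias amplitude at calibration time, in \[0, alpha\].
#' @export
measured_igc_closed_form <- function(Ci0, Cp, alpha, alpha_tilde) {
  if (any(alpha_tilde >= 1)) abort("`alpha_tilde` must be < 1.")
  ((1 - alpha) * Ci0 + (alpha - alpha_tilde) * Cp) / (1 - alpha_tilde)
}

#' Correct a measured interstitial concentration for removal bias
#'
#' Exact algebraic inverse of [measured_igc_closed_form()]: recovers the
#' true concentration from the measured one given the bias amplitudes of
#' the measurement (`alpha`) and of the recovery calibration
#' (`alpha_tilde`).
#'
#' @param Ci_m Measured concentration (mM).
#' @param Cp Perfusate concentration (mM).
#' @param alpha Steady bias amplitude; must be < 1.
#' @param alpha_tilde Calibration bias amplitude (default 0, i.e. an
#'   unbiased calibration).
#' @return Estimated true concentration `Ci,0` (mM).
#' @examples
#' correct_igc(3.3, Cp = 2, alpha = 0.52) # ~ 4.7 mM
#' @export
correct_igc <- function(Ci_m, Cp, alpha, alpha_tilde = 0) {
  if (any(alpha >= 1)) abort("`alpha` must be < 1 for the inversion.")
  ((1 - alpha_tilde) * Ci_m - (alpha - alpha_tilde) * Cp) / (1 - alpha)
}
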