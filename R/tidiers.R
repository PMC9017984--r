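# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy the radial profile of a steady probe-bias solution
#'
#' @param x An [solve_steady()] result.
#' @param ... Unused.
#' @return A tibble with columns `r` (m), `Ci` (mM) and `gamma`
#'   (mol m^-3 s^-1).
#' @method tidy md_steady
#' @export
tidy.md_steady <- function(x, ...) x$profile

#' One-row summary of a steady probe-bias solution
#'
#' @param x An [solve_steady()] result.
#' @param ... Unused.
#' @return A one-row tibble: `Ci0`, `Cp`, `alpha`, `Ci_eff`,
#'   `underestimation_pct`, `removal_rate`, `lambda`, `A`, `method`.
#' @method glance md_steady
#' @export
glance.md_steady <- function(x, ...) {
  tibble::tibble(
    Ci0 = x$Ci0, Cp = x$Cp, alpha = x$alpha, Ci_eff = x$Ci_eff,
    underestimation_pct = if (x$Ci0 > 0) 100 * (x$Ci0 - x$Ci_eff) / x$Ci0
                          else NA_real_,
    removal_rate = x$removal_rate, lambda = x$lambda, A = x$A,
    method = x$method
  )
}

#' @rdname tidy.md_steady
#' @method tidy md_transient
#' @export
tidy.md_transient <- function(x, ...) x$trace

#' @rdname glance.md_steady
#' @method glance md_transient
#' @export
glance.md_transient <- function(x, ...) {
  tibble::tibble(
    Ci0 = x$Ci0, Cp = x$Cp, storage = x$storage,
    alpha_steady = x$alpha_steady, Ci_eff_steady = x$Ci_eff_steady,
    tau_char = x$tau_char, t_ss = x$t_ss, converged = x$converged
  )
}

#' @rdname tidy.md_steady
#' @method tidy md_calibration
#' @export
tidy.md_calibration <- function(x, ...) {
  x$Cd_points %||% tibble::tibble(Cp = numeric(), Ci_eff = numeric(),
                                  Cd = numeric())
}

#' @rdname glance.md_steady
#' @method glance md_calibration
#' @export
glance.md_calibration <- function(x, ...) {
  tibble::tibble(
    method = x$method, R0 = x$R0, Rm = x$Rm,
    alpha = x$alpha, alpha_tilde = x$alpha_tilde,
    Ci0 = x$Ci0, Ci_m = x$Ci_m
  )
}

#' @rdname glance.md_steady
#' @method glance md_ps
#' @export
glance.md_ps <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, ps = x$ps,
    F = x$inputs$F, Ca = x$inputs$Ca, Cv = x$inputs$Cv, Ci = x$inputs$Ci
  )
}

#' Plot the radial concentration profile around the probe
#'
#' @param object An [solve_steady()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot md_steady
#' @export
autoplot.md_steady <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$r * 1e3, y = .data$Ci)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = object$Ci0, linetype = "dashed") +
    ggplot2::labs(
      x = "distance from probe axis (mm)",
      y = "interstitial glucose (mM)",
      title = sprintf("Steady probe bias: alpha = %.2f, Ci_eff = %.2f mM",
                      object$alpha, object$Ci_eff)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the membrane concentration transient after removal onset
#'
#' @param object An [solve_transient()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot md_transient
#' @export
autoplot.md_transient <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$t / 60, y = .data$Ci_eff)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#d95f02") +
    ggplot2::geom_hline(yintercept = object$Ci_eff_steady,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "time after removal onset (min)",
      y = "concentration at the probe (mM)",
      title = sprintf("tau = %.0f s, steady Ci_eff = %.2f mM",
                      object$tau_char, object$Ci_eff_steady)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the measured-vs-true concentration line
#'
#' @param object A [bias_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot md_bias_curve
#' @export
autoplot.md_bias_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$Ci0, y = .data$Ci_eff)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::labs(x = "true interstitial glucose Ci,0 (mM)",
                  y = "measured Ci,eff (mM)") +
    ggplot2::theme_minimal()
}

#' Plot the cross-sectional concentration map with isocontours
#'
#' @param object A [field_map()] result.
#' @param n_grid Raster resolution per axis (default 151).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot md_field
#' @export
autoplot.md_field <- function(object, n_grid = 151, ...) {
  fit <- object$fit
  lim <- fit$r2
  xy <- tidyr::expand_grid(
    x = seq(-lim, lim, length.out = n_grid),
    y = seq(-lim, lim, length.out = n_grid)
  )
  xy$rr <- sqrt(xy$x^2 + xy$y^2)
  prof <- fit$profile
  xy$Ci <- ifelse(
    xy$rr < fit$probe$r1, NA_real_,
    approx(prof$r, prof$Ci, xout = pmin(xy$rr, max(prof$r)),
           ties = "ordered")$y
  )
  ggplot2::ggplot(xy, ggplot2::aes(x = .data$x * 1e3, y = .data$y * 1e3,
                                   fill = .data$Ci)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "Ci (mM)") +
    ggplot2::theme_minimal()
}

#' Plot a no-net-flux calibration
#'
#' @param object A [no_net_flux()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot md_calibration
#' @export
autoplot.md_calibration <- function(object, ...) {
  if (is.null(object$Cd_points)) {
    abort("No (Cp, Cd) points to plot for this calibration method.")
  }
  ggplot2::ggplot(object$Cd_points,
                  ggplot2::aes(x = .data$Cp, y = .data$Cd)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#2c7fb8", linewidth = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "perfusate glucose Cp (mM)", y = "dialysate glucose Cd (mM)",
      title = sprintf("slope 1 - Rm: Rm = %.3f (R0 = %.2f)",
                      object$Rm, object$R0)
    ) +
    ggplot2::theme_minimal()
}
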