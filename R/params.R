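#' Tissue-side physiological parameters
#'
#' Bundles the tissue parameters of the capillary--tissue exchange model:
#' perfusion, glucose metabolism, arterial concentration, interstitial volume
#' fraction, compartmental diffusion coefficients and the Krogh-cone geometry.
#' Defaults describe resting human skeletal muscle during euglycemia.
#'
#' Flow and metabolism are accepted in conventional units
#' (mL/100 mL/min and umol/100 mL/min) by default and stored in SI; see
#' [to_si()]. All other arguments are SI already (concentrations in mM, which
#' equal mol m^-3).
#'
#' @param F_blood Tissue blood flow, mL/100 mL/min (default 4, rest).
#' @param M Glucose metabolism, umol/100 mL/min (default 0.8, basal).
#' @param Ca Arterial glucose concentration, mM (default 5, euglycemia).
#' @param Vi Interstitial volume fraction, dimensionless in (0, 1] (default 0.2).
#' @param Di,Dp Glucose diffusion coefficient in interstitial fluid and plasma,
#'   m^2 s^-1 (default 9.2e-10 for both).
#' @param Dw Effective glucose diffusion coefficient of the capillary
#'   endothelium, m^2 s^-1 (default 4.50e-14, calibrated against a ~15 min
#'   plasma-to-interstitium tracer equilibration time; see [calibrate_dw()]).
#' @param rp Capillary plasma radius, m (default 2.5e-6).
#' @param rw Capillary outer-wall radius (plasma + endothelium), m
#'   (default 3.1e-6).
#' @param rt_a,rt_v Tissue cone radius at the arterial and venous end, m
#'   (defaults 28e-6 and 22e-6).
#' @param units `"conventional"` (default) interprets `F_blood` and `M` as
#'   above; `"si"` takes them as s^-1 and mol m^-3 s^-1 directly.
#' @return An object of class `phys_params`: a validated list whose `F` and
#'   `M` elements are in SI.
#' @examples
#' p <- phys_params()
#' venous_concentration(p) # 4.8 mM at rest
#' @export
phys_params <- function(F_blood = 4, M = 0.8, Ca = 5, Vi = 0.2,
                        Di = 9.2e-10, Dp = 9.2e-10, Dw = 4.50e-14,
                        rp = 2.5e-6, rw = 3.1e-6,
                        rt_a = 28e-6, rt_v = 22e-6,
                        units = c("conventional", "si")) {
  units <- match.arg(units)
  if (units == "conventional") {
    F_blood <- to_si(F_blood, "flow")
    M <- to_si(M, "metabolism")
  }
  p <- structure(
    list(F = F_blood, M = M, Ca = Ca, Vi = Vi, Di = Di, Dp = Dp, Dw = Dw,
         rp = rp, rw = rw, rt_a = rt_a, rt_v = rt_v),
    class = "phys_params"
  )
  validate_phys_params(p)
}

validate_phys_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) abort("All physiological parameters must be finite scalars.")
  pos <- unlist(p[c("F", "Ca", "Vi", "Di", "Dp", "Dw",
                    "rp", "rw", "rt_a", "rt_v")])
  if (any(pos <= 0)) abort("Physiological parameters must be strictly positive.")
  if (p$M < 0) abort("Metabolism `M` must be non-negative.")
  if (p$Vi > 1) abort("Interstitial volume fraction `Vi` must be <= 1.")
  if (!(p$rp < p$rw && p$rw < p$rt_v && p$rt_v <= p$rt_a)) {
    abort("Radii must satisfy rp < rw < rt_v <= rt_a.")
  }
  p
}

#' @export
print.phys_params <- function(x, ...) {
  cat("<phys_params>\n")
  cat(sprintf("  F  = %.4g s^-1 (%.3g mL/100mL/min)\n",
              x$F, from_si(x$F, "flow")))
  cat(sprintf("  M  = %.4g mol m^-3 s^-1 (%.3g umol/100mL/min)\n",
              x$M, from_si(x$M, "metabolism")))
  cat(sprintf("  Ca = %.3g mM, Vi = %.2g\n", x$Ca, x$Vi))
  cat(sprintf("  Di = %.3g, Dp = %.3g, Dw = %.3g m^2 s^-1\n", x$Di, x$Dp, x$Dw))
  cat(sprintf("  rp = %.3g, rw = %.3g, rt_a = %.3g, rt_v = %.3g m\n",
              x$rp, x$rw, x$rt_a, x$rt_v))
  invisible(x)
}

#' Representative tissue-cone radius
#'
#' Midpoint of the arterial and venous cone radii, used wherever a single
#' scalar tissue radius enters the equations (endothelial gradient, quick
#' interstitial estimate, probe sink term).
#'
#' @param phys A [phys_params()] object.
#' @return Radius in m.
#' @export
rt_mid <- function(phys) (phys$rt_a + phys$rt_v) / 2

#' Venous glucose concentration from the steady-state mass balance
#'
#' At steady state the capillary bed loses `M` per tissue volume, so
#' `F (Ca - Cv) = M` and `Cv = Ca - M/F`.
#'
#' @param phys A [phys_params()] object.
#' @return Venous concentration in mM.
#' @examples
#' venous_concentration(phys_params()) # 4.8
#' @export
venous_concentration <- function(phys) {
  stopifnot(inherits(phys, "phys_params"))
  cv <- phys$Ca - phys$M / phys$F
  if (cv <= 0) {
    abort("complete extraction exceeded: M/F >= Ca leaves no venous glucose.")
  }
  cv
}

#' Microdialysis probe parameters
#'
#' Geometry, true relative recovery, perfusate flow and perfusate glucose
#' concentration of the microdialysis probe. The exchange surface
#' `S_probe = 2 pi r1 L` and the membrane mass-transfer coefficient
#' `beta = R0 f / S_probe` (m s^-1) are derived on construction; `beta` is
#' the single parameter through which the probe enters the bias model, so
#' recovery and perfusate flow only matter via their product.
#'
#' @param R0 True relative recovery, in (0, 1] (default 0.5).
#' @param f Perfusate flow, m^3 s^-1 (default 3.33e-11).
#' @param L Probe membrane length, m (default 16e-3).
#' @param r1 Probe outer radius, m (default 250e-6).
#' @param Cp Perfusate glucose concentration, mM (default 2).
#' @return An object of class `probe_params` with derived `S_probe` and `beta`.
#' @examples
#' probe_params()$beta # ~6.63e-7 m/s
#' @export
probe_params <- function(R0 = 0.5, f = 3.33e-11, L = 16e-3,
                         r1 = 250e-6, Cp = 2) {
  vals <- c(R0 = R0, f = f, L = L, r1 = r1, Cp = Cp)
  if (!all(vapply(vals, function(x) is.numeric(x) && is.finite(x), logical(1)))) {
    abort("All probe parameters must be finite numerics.")
  }
  if (R0 <= 0 || R0 > 1) abort("Recovery `R0` must lie in (0, 1].")
  if (f <= 0 || L <= 0 || r1 <= 0) abort("f, L and r1 must be positive.")
  if (Cp < 0) abort("Perfusate concentration `Cp` must be non-negative.")
  S <- 2 * pi * r1 * L
  structure(
    list(R0 = R0, f = f, L = L, r1 = r1, Cp = Cp,
         S_probe = S, beta = R0 * f / S),
    class = "probe_params"
  )
}

#' @export
print.probe_params <- function(x, ...) {
  cat("<probe_params>\n")
  cat(sprintf("  R0 = %.3g, f = %.3g m^3/s, L = %.3g m, r1 = %.3g m\n",
              x$R0, x$f, x$L, x$r1))
  cat(sprintf("  Cp = %.3g mM; S_probe = %.4g m^2, beta = %.4g m/s\n",
              x$Cp, x$S_probe, x$beta))
  invisible(x)
}

#' Glucose-tracer parameters for internal-reference calibration
#'
#' @param Cp_star Tracer concentration in the perfusate (arbitrary units;
#'   the model is linear in the tracer so only ratios matter). The
#'   internal-reference bias expression assumes the tracer is present at
#'   trace level relative to native glucose.
#' @param include_metabolism_term Include the metabolic tracer sink
#'   `M Ci*(r) / Ci(r)` alongside capillary clearance (default `TRUE`; its
#'   contribution is numerically small).
#' @return An object of class `tracer_params`.
#' @export
tracer_params <- function(Cp_star = 1, include_metabolism_term = TRUE) {
  if (!is.numeric(Cp_star) || !is.finite(Cp_star) || Cp_star <= 0) {
    abort("`Cp_star` must be a positive number.")
  }
  structure(
    list(Cp_star = Cp_star,
         include_metabolism_term = isTRUE(include_metabolism_term)),
    class = "tracer_params"
  )
}

# Keys accepted in config files, per section.
.phys_keys <- c("F", "M", "Ca", "Vi", "Di", "Dp", "Dw",
                "rp", "rw", "rt_a", "rt_v")
.probe_keys <- c("R", "R0", "f", "L", "r1", "Cp")

#' Read physiology and probe parameters from a config file
#'
#' The file (YAML or JSON, by extension) may contain two top-level sections,
#' `physiology` and `probe`, with keys named after the standard symbols
#' (`F`, `M`, `Ca`, `Vi`, `Di`, `Dp`, `Dw`, `rp`, `rw`, `rt_a`, `rt_v`;
#' `R` or `R0`, `f`, `L`, `r1`, `Cp`). Missing keys fall back to the
#' defaults; unknown keys are an error. `F` and `M` are read in conventional
#' units.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `physiology` ([phys_params()]) and
#'   `probe` ([probe_params()]).
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("Config file must be .yaml, .yml or .json.")
  }
  bad_sec <- setdiff(names(cfg), c("physiology", "probe"))
  if (length(bad_sec)) {
    abort(paste0("Unknown config section(s): ", paste(bad_sec, collapse = ", ")))
  }
  phys_in <- cfg$physiology %||% list()
  probe_in <- cfg$probe %||% list()
  bad <- setdiff(names(phys_in), .phys_keys)
  if (length(bad)) {
    abort(paste0("Unknown physiology key(s): ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(names(probe_in), .probe_keys)
  if (length(bad)) {
    abort(paste0("Unknown probe key(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(phys_in$F)) names(phys_in)[names(phys_in) == "F"] <- "F_blood"
  if (!is.null(probe_in$R)) names(probe_in)[names(probe_in) == "R"] <- "R0"
  list(
    physiology = do.call(phys_params, phys_in),
    probe = do.call(probe_params, probe_in)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
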