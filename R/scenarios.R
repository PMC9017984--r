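# Named scenario presets, a scenario runner, figure-data reproduction and a
# seeded Latin-hypercube fixture generator for property-style testing.

#' Define a model scenario
#'
#' A scenario bundles physiology overrides, probe overrides, a metabolism
#' multiplier relative to basal and an optional prescribed true interstitial
#' concentration. When `Ci0` is `NULL` the scenario uses the compartment
#' model's own prediction ([igc_quick()]).
#'
#' @param name Scenario name.
#' @param phys Named list of [phys_params()] overrides (conventional units
#'   for `F_blood` and `M`).
#' @param probe Named list of [probe_params()] overrides.
#' @param M_multiplier Metabolism multiplier applied after `phys` overrides
#'   (default 1).
#' @param Ci0 Optional prescribed true interstitial concentration (mM).
#' @param description Free-text description.
#' @return An object of class `md_scenario`.
#' @export
scenario <- function(name, phys = list(), probe = list(), M_multiplier = 1,
                     Ci0 = NULL, description = "") {
  if (M_multiplier <= 0) abort("`M_multiplier` must be positive.")
  structure(
    list(name = name, phys = phys, probe = probe,
         M_multiplier = M_multiplier, Ci0 = Ci0,
         description = description),
    class = "md_scenario"
  )
}

#' Built-in scenario presets
#'
#' * `basal`: resting euglycemic defaults; the model predicts `Ci,0 ~ 4.7 mM`.
#' * `figure1-quarter-A` .. `-D`: the four assumed true concentrations of
#'   the isocontour map (4.7, 4.1, 3.5, 2.9 mM), representing progressively
#'   higher insulin-stimulated uptake at fixed flow.
#' * `hyperinsulinemia-15x`: 15-fold basal metabolism.
#' * `gudbjornsdottir-probe`: demonstrator probe with recovery 0.3,
#'   perfusate flow 4.17e-11 m^3/s and 1.5 mM perfusate glucose (tissue-side
#'   flow and metabolism must still be chosen by the user for study-specific
#'   predictions).
#'
#' @return Named list of [scenario()] objects.
#' @export
md_scenarios <- function() {
  qs <- c(A = 4.7, B = 4.1, C = 3.5, D = 2.9)
  quarters <- lapply(names(qs), function(q) {
    scenario(paste0("figure1-quarter-", q), Ci0 = qs[[q]],
             description = sprintf(
               "Isocontour-map quarter %s: assumed true IGC %.1f mM", q, qs[[q]]))
  })
  names(quarters) <- paste0("figure1-quarter-", names(qs))
  c(
    list(
      basal = scenario("basal",
                       description = "Resting euglycemia, Table-1 defaults"),
      `hyperinsulinemia-15x` = scenario(
        "hyperinsulinemia-15x", M_multiplier = 15,
        description = "15-fold basal metabolism at unchanged flow"
      ),
      `gudbjornsdottir-probe` = scenario(
        "gudbjornsdottir-probe",
        probe = list(R0 = 0.3, f = 4.17e-11, Cp = 1.5),
        description = "Literature probe demonstrator (R=0.3, f=4.17e-11, Cp=1.5 mM)"
      )
    ),
    quarters
  )
}

# Materialize a scenario into parameter objects and a Ci0 value.
resolve_scenario <- function(sc) {
  stopifnot(inherits(sc, "md_scenario"))
  phys_args <- sc$phys
  phys <- do.call(phys_params, phys_args)
  if (sc$M_multiplier != 1) {
    phys$M <- phys$M * sc$M_multiplier
    phys <- validate_phys_params(phys)
  }
  probe <- do.call(probe_params, sc$probe)
  Ci0 <- sc$Ci0 %||% igc_quick(phys)
  list(phys = phys, probe = probe, Ci0 = Ci0)
}

scenario_meta <- function(sc, res) {
  c(
    sprintf("scenario: %s", sc$name),
    sprintf("F_mL_100mL_min: %s", format(from_si(res$phys$F, "flow"))),
    sprintf("M_umol_100mL_min: %s", format(from_si(res$phys$M, "metabolism"))),
    sprintf("Ca_mM: %s", format(res$phys$Ca)),
    sprintf("Dw_m2_s: %s", format(res$phys$Dw)),
    sprintf("R0: %s", format(res$probe$R0)),
    sprintf("f_m3_s: %s", format(res$probe$f)),
    sprintf("Cp_mM: %s", format(res$probe$Cp)),
    sprintf("beta_m_s: %s", format(signif(res$probe$beta, 6))),
    sprintf("Ci0_mM: %s", format(signif(res$Ci0, 6)))
  )
}

# CSV with '# key: value' metadata header, 6 significant digits.
write_md_csv <- function(df, path, meta) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run a scenario end to end
#'
#' Resolves the scenario, runs the requested model components and returns
#' their results; optionally writes CSV/JSON files (deterministic for a
#' given scenario, every file carrying the resolved parameter set as a
#' metadata header).
#'
#' @param sc A [scenario()] object or the name of a preset from
#'   [md_scenarios()].
#' @param what Components to run: any of `"steady"`, `"compartment"`,
#'   `"transient"`, `"ps"`.
#' @param dir Optional output directory for CSV/JSON files.
#' @param t_end Transient window (s), when `"transient"` is requested.
#' @return A list with the resolved parameters, a `summary` list (written
#'   as JSON when `dir` is given) and the per-component results.
#' @export
run_scenario <- function(sc, what = c("steady", "compartment", "ps"),
                         dir = NULL, t_end = 3600) {
  if (is.character(sc)) {
    presets <- md_scenarios()
    if (!sc %in% names(presets)) {
      abort(paste0("Unknown scenario preset: ", sc))
    }
    sc <- presets[[sc]]
  }
  what <- match.arg(what, c("steady", "compartment", "transient", "ps"),
                    several.ok = TRUE)
  res <- resolve_scenario(sc)
  meta <- scenario_meta(sc, res)
  out <- list(scenario = sc, params = res)
  summary <- list(
    scenario = sc$name,
    ci0_mM = res$Ci0,
    cv_mM = venous_concentration(res$phys)
  )
  if ("compartment" %in% what) {
    out$compartment <- compartment_profiles(res$phys)
    summary$ci0_full_chain_mM <- igc_full(res$phys)
    summary$endothelial_gradient_mM <- endothelial_gradient(res$phys)
    if (!is.null(dir)) {
      write_md_csv(out$compartment, file.path(dir, "compartment.csv"), meta)
    }
  }
  if ("steady" %in% what) {
    out$steady <- solve_steady(res$phys, res$probe, res$Ci0)
    summary$alpha <- out$steady$alpha
    summary$ci_eff_mM <- out$steady$Ci_eff
    summary$removal_rate_mol_per_s <- out$steady$removal_rate
    summary$underestimation_pct <-
      100 * (res$Ci0 - out$steady$Ci_eff) / res$Ci0
    if (!is.null(dir)) {
      write_md_csv(tidy(out$steady), file.path(dir, "steady_profile.csv"),
                   meta)
    }
  }
  if ("transient" %in% what) {
    out$transient <- solve_transient(res$phys, res$probe, res$Ci0,
                                     t_end = t_end)
    summary$tau_char_s <- out$transient$tau_char
    summary$t_ss_s <- out$transient$t_ss
    if (!is.null(dir)) {
      write_md_csv(out$transient$trace, file.path(dir, "transient.csv"), meta)
    }
  }
  if ("ps" %in% what) {
    Cv <- venous_concentration(res$phys)
    if (res$Ci0 < Cv) {
      out$ps <- ps_true(res$phys$F, res$phys$Ca, Cv, res$Ci0)
      summary$ps_true_per_s <- out$ps$ps
    } else {
      summary$ps_true_per_s <- NA
    }
    psm <- try(ps_measured(res$phys, res$probe, res$Ci0), silent = TRUE)
    summary$ps_measured_per_s <- if (inherits(psm, "try-error")) NA else psm$ps
    out$ps_measured <- if (inherits(psm, "try-error")) NULL else psm
  }
  out$summary <- summary
  if (!is.null(dir)) {
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Reproduce the numeric data behind the reference figures
#'
#' Emits tidy tables of the model outputs underlying the standard result
#' plots: the isocontour map (`"fig1"`), the measured-vs-true concentration
#' line (`"fig2"`), the flow-and-beta sensitivity lines (`"fig3"`), the
#' removal/tracer transients (`"fig6"`), and the worked numeric examples of
#' the steady bias model (`"worked-examples"`, returned as a list).
#'
#' @param id One of `"fig1"`, `"fig2"`, `"fig3"`, `"fig6"`,
#'   `"worked-examples"`.
#' @param dir Optional output directory (CSV for tables, JSON for the worked
#'   examples).
#' @return A tibble, or a list for `"worked-examples"`.
#' @export
reproduce <- function(id = c("fig1", "fig2", "fig3", "fig6",
                             "worked-examples"),
                      dir = NULL) {
  id <- match.arg(id)
  phys <- phys_params()
  probe <- probe_params()
  basal <- scenario("basal")
  meta <- scenario_meta(basal, resolve_scenario(basal))
  out <- switch(id,
    fig1 = {
      qs <- c(A = 4.7, B = 4.1, C = 3.5, D = 2.9)
      purrr::map_dfr(names(qs), function(q) {
        fm <- field_map(phys, probe, qs[[q]])
        dplyr::mutate(fm$contours, quarter = q, Ci0 = qs[[q]],
                      .before = 1)
      })
    },
    fig2 = bias_curve(phys, probe, Ci0 = seq(2, 6, length.out = 81)),
    fig3 = {
      grid <- tidyr::expand_grid(
        F_conv = c(1, 4, 40),
        beta_mult = c(0.25, 0.5, 1, 2, 4)
      )
      purrr::pmap_dfr(grid, function(F_conv, beta_mult) {
        ph <- phys_params(F_blood = F_conv)
        pr <- probe_params(f = probe$f * beta_mult)
        a <- bias_alpha(ph, pr)
        tibble::tibble(
          F_mL_100mL_min = F_conv, beta_mult = beta_mult, alpha = a,
          dC_true = seq(0, 6, length.out = 31),
          dC_measured = (1 - a) * dC_true
        )
      })
    },
    fig6 = {
      purrr::map_dfr(c(0.25, 1, 4), function(bm) {
        pr <- probe_params(f = probe$f * bm)
        sol <- solve_transient(phys, pr, Ci0 = 4.7, t_end = 3600, n = 150,
                               times = seq(0, 3600, length.out = 601))
        tr <- tracer_accumulation(phys, pr, tracer_params(), Ci0 = 4.7,
                                  t_end = 3600, n = 150,
                                  times = seq(0, 3600, length.out = 601))
        dplyr::mutate(sol$trace,
                      beta_mult = bm,
                      alpha_norm = .data$alpha_t / sol$alpha_steady,
                      tracer_ratio = tr$trace$ratio,
                      .before = 1)
      })
    },
    `worked-examples` = {
      fit <- solve_steady(phys, probe, Ci0 = 4.7)
      fit6 <- solve_steady(phys, probe, Ci0 = 6.0)
      pr33 <- probe_params(Cp = 3.3)
      fit33 <- solve_steady(phys, pr33, Ci0 = 4.7)
      list(
        ci0_mM = 4.7, cp_mM = probe$Cp,
        alpha = fit$alpha,
        ci_eff_mM = fit$Ci_eff,
        underestimation_pct = 100 * (4.7 - fit$Ci_eff) / 4.7,
        removal_rate_mol_per_s = fit$removal_rate,
        ci_eff_at_6mM = fit6$Ci_eff,
        underestimation_pct_at_6mM = 100 * (6 - fit6$Ci_eff) / 6,
        abs_bias_at_6mM_mM = 6 - fit6$Ci_eff,
        ci_eff_cp_3p3_mM = fit33$Ci_eff
      )
    }
  )
  if (!is.null(dir)) {
    if (id == "worked-examples") {
      jsonlite::write_json(out, file.path(dir, "worked_examples.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      write_md_csv(out, file.path(dir, paste0(id, ".csv")), meta)
    }
  }
  out
}

#' Seeded Latin-hypercube scenario sweep for property testing
#'
#' Draws a reproducible Latin-hypercube sample over the ranges spanned by
#' the sensitivity analyses: true concentration 2--8 mM, perfusate
#' concentration 0--2 mM, probe coefficient 0.25--4 times the standard
#' `beta`, blood flow 1--40 mL/100 mL/min and metabolism 0.8--12
#' umol/100 mL/min.
#'
#' @param n Number of scenarios (>= 1).
#' @param seed Integer seed.
#' @param dir Optional directory; writes `fixtures.csv`.
#' @return A tibble with one row per generated scenario.
#' @export
generate_fixtures <- function(n, seed = 1, dir = NULL) {
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.")
  set.seed(seed)
  u <- lhs::randomLHS(as.integer(n), 5)
  scale01 <- function(x, lo, hi) lo + x * (hi - lo)
  out <- tibble::tibble(
    id = seq_len(nrow(u)),
    Ci0 = scale01(u[, 1], 2, 8),
    Cp = scale01(u[, 2], 0, 2),
    beta_mult = scale01(u[, 3], 0.25, 4),
    F_conv = scale01(u[, 4], 1, 40),
    M_conv = scale01(u[, 5], 0.8, 12)
  )
  if (!is.null(dir)) {
    write_md_csv(out, file.path(dir, "fixtures.csv"),
                 c(sprintf("seed: %d", seed), sprintf("n: %d", as.integer(n))))
  }
  out
}
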