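test_that("all scenario presets resolve to valid parameter sets", {
  for (sc in md_scenarios()) {
    res <- mdbias:::resolve_scenario(sc)
    expect_s3_class(res$phys, "phys_params")
    expect_s3_class(res$probe, "probe_params")
    expect_true(is.finite(res$Ci0) && res$Ci0 > 0)
  }
  g <- mdbias:::resolve_scenario(md_scenarios()$`gudbjornsdottir-probe`)
  expect_equal(g$probe$R0, 0.3)
  expect_equal(g$probe$f, 4.17e-11)
  expect_equal(g$probe$Cp, 1.5)
  hi <- mdbias:::resolve_scenario(md_scenarios()$`hyperinsulinemia-15x`)
  expect_equal(from_si(hi$phys$M, "metabolism"), 12, tolerance = 1e-9)
  expect_error(scenario("bad", M_multiplier = 0), "positive")
})

test_that("the basal scenario reports the reference steady-state numbers", {
  res <- run_scenario("basal")
  expect_equal(res$summary$ci0_mM, 4.7, tolerance = 0.01)
  expect_equal(res$summary$ci_eff_mM, 3.3, tolerance = 0.02)
  expect_equal(res$summary$cv_mM, 4.8)
  expect_error(run_scenario("no-such-preset"), "Unknown scenario preset")
  # empty overrides reproduce the defaults exactly
  res2 <- run_scenario(scenario("copy"))
  expect_identical(res2$summary$ci0_mM, res$summary$ci0_mM)
  expect_identical(res2$summary$alpha, res$summary$alpha)
})

test_that("scenario outputs are byte-identical across repeated runs", {
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  run_scenario("basal", what = "steady", dir = d1)
  run_scenario("basal", what = "steady", dir = d2)
  for (f in c("steady_profile.csv", "summary.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # metadata header carries the resolved parameters
  head1 <- readLines(file.path(d1, "steady_profile.csv"), n = 12)
  expect_true(any(grepl("^# scenario: basal", head1)))
  expect_true(any(grepl("^# beta_m_s:", head1)))
})

test_that("fixture sweeps are seeded, bounded and valid", {
  fx1 <- generate_fixtures(25, seed = 42)
  fx2 <- generate_fixtures(25, seed = 42)
  expect_identical(fx1, fx2)
  fx3 <- generate_fixtures(25, seed = 43)
  expect_false(identical(fx1, fx3))
  expect_error(generate_fixtures(0), ">= 1")

  expect_true(all(fx1$Ci0 >= 2 & fx1$Ci0 <= 8))
  expect_true(all(fx1$Cp >= 0 & fx1$Cp <= 2))
  expect_true(all(fx1$beta_mult >= 0.25 & fx1$beta_mult <= 4))
  # every generated scenario passes the type invariants end to end
  pr0 <- basal_probe()
  for (i in seq_len(5)) {
    p <- phys_params(F_blood = fx1$F_conv[i], M = fx1$M_conv[i])
    pr <- with_beta_mult(pr0, fx1$beta_mult[i])
    expect_s3_class(p, "phys_params")
    a <- bias_alpha(p, pr)
    expect_true(a > 0 && a < 1)
  }
})

test_that("figure-data reproduction emits the expected structures", {
  f2 <- reproduce("fig2")
  # line through (Cp, Cp) = (2, 2)
  expect_equal(f2$Ci_eff[f2$Ci0 == 2], 2)
  expect_equal(f2$abs_bias, attr(f2, "alpha") * (f2$Ci0 - 2),
               tolerance = 1e-12)

  f3 <- reproduce("fig3")
  expect_setequal(unique(f3$F_mL_100mL_min), c(1, 4, 40))
  expect_setequal(unique(f3$beta_mult), c(0.25, 0.5, 1, 2, 4))
  # straight lines through the origin of the difference axes
  expect_equal(f3$dC_measured, (1 - f3$alpha) * f3$dC_true,
               tolerance = 1e-12)

  f1 <- reproduce("fig1")
  expect_setequal(unique(f1$quarter), c("A", "B", "C", "D"))
  expect_setequal(unique(f1$level), c(0.99, 0.95, 0.90, 0.80, 0.70))

  wk <- reproduce("worked-examples")
  expect_named(wk, c("ci0_mM", "cp_mM", "alpha", "ci_eff_mM",
                     "underestimation_pct", "removal_rate_mol_per_s",
                     "ci_eff_at_6mM", "underestimation_pct_at_6mM",
                     "abs_bias_at_6mM_mM", "ci_eff_cp_3p3_mM"))
  expect_error(reproduce("fig9"))
})

test_that("transient figure data has monotone normalized bias curves", {
  f6 <- reproduce("fig6")
  expect_setequal(unique(f6$beta_mult), c(0.25, 1, 4))
  for (bm in c(0.25, 1, 4)) {
    cur <- dplyr::filter(f6, beta_mult == bm)
    expect_true(all(diff(cur$alpha_norm) > -1e-9))
    expect_true(all(cur$alpha_norm >= 0 & cur$alpha_norm <= 1 + 1e-3))
    # tracer curve tracks the native normalized bias
    expect_equal(cur$tracer_ratio[nrow(cur)],
                 cur$alpha_t[nrow(cur)], tolerance = 0.02)
  }
})
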