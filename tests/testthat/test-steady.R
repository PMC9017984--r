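test_that("the resupply timescale decomposes into plasma and wall parts", {
  p <- basal_phys()
  st <- sink_timescale(p)
  expect_equal(st$A, st$plasma_component + st$wall_component)
  expect_equal(st$plasma_component, 1 / (2 * p$F))
  expect_equal(st$A, 2.2e3, tolerance = 0.02)
  expect_equal(st$lambda, sqrt(p$Di * p$Vi * st$A))
  expect_lt(abs(st$lambda - 0.64e-3) / 0.64e-3, 0.01)
  # transparent-wall and infinite-flow limits
  st_fast_wall <- sink_timescale(phys_params(Dw = 1))
  expect_equal(st_fast_wall$A, st$plasma_component, tolerance = 1e-9)
  st_fast_flow <- sink_timescale(phys_params(F_blood = 1e9))
  expect_equal(st_fast_flow$A, st$wall_component, tolerance = 1e-8)
})

test_that("closed-form Bessel field matches the finite-difference oracle", {
  p0 <- basal_phys()
  pr0 <- basal_probe()
  for (f_conv in c(1, 4, 40)) {
    for (bm in c(0.25, 1, 4)) {
      p <- phys_params(F_blood = f_conv)
      pr <- with_beta_mult(pr0, bm)
      cf <- solve_steady(p, pr, Ci0 = 4.7, n = 201)
      fd <- solve_steady_fd(p, pr, Ci0 = 4.7, n_fd = 2001)
      # compare on the FD grid via the closed form directly
      ci_cf <- 4.7 + (cf$Ci_eff - 4.7) *
        besselK(fd$profile$r / cf$lambda, 0) /
        besselK(pr$r1 / cf$lambda, 0)
      rel <- max(abs(ci_cf - fd$profile$Ci)) / 4.7
      expect_lt(rel, 1e-3)
      expect_equal(fd$alpha, cf$alpha, tolerance = 1e-3)
    }
  }
})

test_that("the bias amplitude is a pure transport property", {
  p <- basal_phys()
  pr <- basal_probe()
  # independent of the (Ci0, Cp) pair to 1e-8
  a1 <- with(solve_steady(p, pr, 4.7), (Ci0 - Ci_eff) / (Ci0 - Cp))
  a2 <- with(solve_steady(p, with_cp(pr, 1), 6.0),
             (Ci0 - Ci_eff) / (Ci0 - Cp))
  a3 <- with(solve_steady(p, with_cp(pr, 3.3), 4.7),
             (Ci0 - Ci_eff) / (Ci0 - Cp))
  expect_equal(a1, a2, tolerance = 1e-8)
  expect_equal(a1, a3, tolerance = 1e-8)
  expect_equal(a1, bias_alpha(p, pr), tolerance = 1e-10)
  expect_gte(a1, 0)
  expect_lte(a1, 1)
})

test_that("alpha rises with the membrane coefficient and falls with flow", {
  p <- basal_phys()
  pr <- basal_probe()
  a_beta <- vapply(c(0.25, 0.5, 1, 2, 4),
                   function(m) bias_alpha(p, with_beta_mult(pr, m)),
                   numeric(1))
  expect_true(all(diff(a_beta) > 0))
  a_flow <- vapply(c(1, 4, 40),
                   function(fc) bias_alpha(phys_params(F_blood = fc), pr),
                   numeric(1))
  expect_true(all(diff(a_flow) < 0))
  # probe parameters dominate over blood flow across the sensitivity sweep
  expect_gt(diff(range(a_beta)), diff(range(a_flow)))
})

test_that("degenerate probes and gradients behave trivially", {
  p <- basal_phys()
  pr <- basal_probe()
  # no driving difference: uniform field, nothing removed
  eq <- solve_steady(p, with_cp(pr, 4.7), Ci0 = 4.7)
  expect_equal(eq$Ci_eff, 4.7)
  expect_equal(eq$removal_rate, 0)
  expect_true(all(abs(eq$profile$Ci - 4.7) < 1e-12))
  # vanishing membrane coefficient: unbiased probe
  weak <- solve_steady(p, with_beta_mult(pr, 1e-6), Ci0 = 4.7)
  expect_lt(weak$alpha, 1e-4)
  expect_equal(weak$Ci_eff, 4.7, tolerance = 1e-4)
  # outer boundary too close to contain the screened field
  expect_error(solve_steady(p, pr, 4.7, r2 = 2 * pr$r1), "r2")
})

test_that("probe removal balances the integrated capillary resupply", {
  p <- basal_phys()
  pr <- basal_probe()
  fd <- solve_steady_fd(p, pr, Ci0 = 4.7, n_fd = 4001)
  prof <- fd$profile
  # per length: integral of gamma(r) * 2 pi r dr; times membrane length L
  integrand <- prof$gamma * 2 * pi * prof$r
  resupply <- sum(diff(prof$r) *
                    (integrand[-1] + integrand[-nrow(prof)]) / 2) * pr$L
  expect_equal(resupply, fd$removal_rate, tolerance = 5e-3)
})

test_that("the bias curve is the straight line through (Cp, Cp)", {
  p <- basal_phys()
  pr <- basal_probe()
  bc <- bias_curve(p, pr, Ci0 = seq(2, 8, length.out = 13))
  a <- attr(bc, "alpha")
  expect_equal(bc$Ci_eff, (1 - a) * bc$Ci0 + a * pr$Cp, tolerance = 1e-12)
  expect_equal(bc$Ci_eff[bc$Ci0 == 2], 2) # fixed point at Ci0 = Cp
  fit <- lm(Ci_eff ~ Ci0, data = bc)
  expect_equal(unname(coef(fit)[2]), 1 - a, tolerance = 1e-10)
})

test_that("isocontours grow with the unperturbed concentration", {
  p <- basal_phys()
  pr <- basal_probe()
  fm_hi <- field_map(p, pr, 4.7)
  fm_lo <- field_map(p, pr, 2.9)
  ok <- !is.na(fm_hi$contours$radius) & !is.na(fm_lo$contours$radius)
  expect_true(any(ok))
  expect_true(all(fm_hi$contours$radius[ok] > fm_lo$contours$radius[ok]))
  # perturbed region (>= 5%) spans a radius of roughly 1-2 mm at rest
  expect_gt(fm_hi$affected_radius, 0.5e-3)
  expect_lt(fm_hi$affected_radius, 2e-3)
  # no contours exist when there is no gradient
  fm_eq <- field_map(p, with_cp(pr, 4.7), 4.7)
  expect_true(all(is.na(fm_eq$contours$radius)))
  # contours below the membrane concentration are flagged, not errors
  deep <- field_map(p, pr, 4.7, levels = c(0.95, 0.5))
  expect_true(is.na(deep$contours$radius[deep$contours$level == 0.5]))
})
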