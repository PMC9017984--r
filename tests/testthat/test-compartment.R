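test_that("the tissue cone tapers linearly from arterial to venous radius", {
  p <- basal_phys()
  expect_equal(cone_radius(p, 0), 28e-6)
  expect_equal(cone_radius(p, 1), 22e-6)
  expect_equal(cone_radius(p, 0.5), 25e-6)
  expect_error(cone_radius(p, 1.2), "\\[0, 1\\]")
  expect_error(cone_radius(p, -0.1), "\\[0, 1\\]")
})

test_that("the axial plasma profile closes the cone mass balance", {
  p <- basal_phys()
  expect_equal(axial_plasma_profile(p, 0), 5)
  expect_equal(axial_plasma_profile(p, 1), venous_concentration(p),
               tolerance = 1e-9)
  # monotonically non-increasing when M > 0
  xs <- seq(0, 1, length.out = 41)
  prof <- axial_plasma_profile(p, xs)
  expect_true(all(diff(prof) < 0))
  # conservation: capillary loss equals cone metabolism per tissue volume
  expect_equal(p$F * (p$Ca - axial_plasma_profile(p, 1)), p$M,
               tolerance = 1e-12)
  # no metabolism, no axial gradient
  expect_equal(axial_plasma_profile(phys_params(M = 0), xs), rep(5, 41))
  # parameters implying plasma depletion below zero are rejected
  expect_error(axial_plasma_profile(phys_params(M = 24, Ca = 4.2), 1))
})

test_that("interstitial gradient matches the analytic derivative of the profile", {
  p <- basal_phys()
  rt <- cone_radius(p, 0.5)
  expect_equal(interstitial_gradient(p, rt), 0)
  expect_lt(interstitial_gradient(p, p$rw), 0) # outward transport
  # central finite-difference oracle on the profile
  rs <- seq(p$rw * 1.2, rt * 0.98, length.out = 7)
  hh <- 1e-9
  for (r in rs) {
    fd <- (interstitial_profile(p, r + hh, 0.5) -
             interstitial_profile(p, r - hh, 0.5)) / (2 * hh)
    expect_equal(interstitial_gradient(p, r), fd, tolerance = 1e-6)
  }
  expect_error(interstitial_profile(p, rt * 1.1, 0.5), "rw, rt")
  expect_error(interstitial_gradient(p, p$rw / 2), "rw, rt")
})

test_that("compartmental drops scale linearly with metabolism", {
  p1 <- basal_phys()
  rt <- rt_mid(p1)
  g1 <- endothelial_gradient(p1, rt)
  d1 <- interstitial_profile(p1, p1$rw, 0) - interstitial_profile(p1, rt, 0)
  for (m in c(2, 15, 100)) {
    pm <- phys_params(M = 0.8 * m)
    expect_equal(endothelial_gradient(pm, rt), m * g1, tolerance = 1e-12)
    dm <- interstitial_profile(pm, pm$rw, 0) - interstitial_profile(pm, rt, 0)
    expect_equal(dm, m * d1, tolerance = 1e-9)
  }
  expect_equal(endothelial_gradient(phys_params(M = 0), rt), 0)
  expect_error(endothelial_gradient(p1, p1$rw / 2), "rt")
})

test_that("interstitial variation stays negligible up to extreme metabolism", {
  # whole-annulus drop stays below 5e-2 mM even at 100x basal metabolism
  for (m in c(1, 10, 100)) {
    pm <- phys_params(M = 0.8 * m)
    drop <- interstitial_profile(pm, pm$rw, 0) -
      interstitial_profile(pm, cone_radius(pm, 0), 0)
    expect_lt(drop, 5e-2)
  }
})

test_that("the quick and full-chain interstitial estimates agree", {
  p <- basal_phys()
  expect_equal(igc_full(p), igc_quick(p), tolerance = 0.05 / 4.7)
  # no metabolism: interstitium equilibrates with arterial plasma
  p0 <- phys_params(M = 0)
  expect_equal(igc_quick(p0), 5)
  expect_equal(igc_full(p0), 5, tolerance = 1e-9)
  # plasma radial drop is far below a thousandth of a mM at rest
  drop_pl <- p$M * (rt_mid(p)^2 - p$rw^2) / (8 * p$Dp)
  expect_lt(drop_pl, 1e-3)
  # elevated metabolism: the two estimates drift apart only through the
  # cone-weighted axial profile (scales with M), staying within 0.2 mM
  p15 <- phys_params(M = 0.8 * 15)
  expect_lt(abs(igc_full(p15) - igc_quick(p15)), 0.2)
})

test_that("compartment profile export is tidy and internally consistent", {
  p <- basal_phys()
  prof <- compartment_profiles(p, n_axial = 11, n_radial = 11)
  expect_s3_class(prof, "tbl_df")
  expect_named(prof, c("coordinate", "value", "compartment",
                       "concentration_mM"))
  ax <- dplyr::filter(prof, coordinate == "xi")
  expect_equal(ax$concentration_mM[1], 5)
  expect_equal(ax$concentration_mM[nrow(ax)], 4.8, tolerance = 1e-9)
  rad <- dplyr::filter(prof, coordinate == "r",
                       compartment == "interstitium")
  expect_true(all(diff(rad$concentration_mM) <= 0))
})
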