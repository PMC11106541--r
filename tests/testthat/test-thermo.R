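test_that("helicity calibration is exact, clamped and order-preserving", {
  expect_equal(helicity_from_theta222(3000)$percent_helix, 0)
  expect_equal(helicity_from_theta222(-36000)$percent_helix, 100)
  expect_equal(helicity_from_theta222(-16500)$percent_helix, 50)
  out <- helicity_from_theta222(c(10000, -50000))
  expect_true(all(out$clamped))
  expect_equal(out$percent_helix, c(0, 100))
  # affine and order preserving: more negative theta never lowers helicity
  theta <- seq(5000, -40000, by = -500)
  h <- helicity_from_theta222(theta)$percent_helix
  expect_true(all(diff(h) >= 0))
  expect_error(helicity_from_theta222(NaN), "finite")
  expect_error(helicity_from_theta222(Inf), "finite")
})

test_that("mean residue ellipticity conversion matches hand arithmetic", {
  # 10 mdeg, 0.1 mg/ml, 0.1 cm path, MRW 115.4: 10*115.4/(10*0.1*0.1)
  expect_equal(mean_residue_ellipticity(10, 0.1), 11540)
  expect_error(mean_residue_ellipticity(10, 0), "positive")
})

test_that("Boltzmann fitting recovers known transitions in both orientations", {
  x <- seq(20, 80, by = 0.5)
  y_up <- 100 + (900 - 100) / (1 + exp((52 - x) / 3))
  f <- boltzmann_fit(x, y_up)
  expect_true(f$converged)
  expect_equal(f$x50, 52, tolerance = 52 * 1e-6)
  expect_equal(f$a, 3, tolerance = 3e-6)
  expect_false(f$extrapolated)
  # CD-style falling-magnitude transition (theta becomes less negative)
  scan <- simulate_cd_thermal(55, 40)
  f2 <- boltzmann_fit(scan$temperature, scan$theta222)
  expect_true(f2$converged)
  expect_equal(f2$x50, 55, tolerance = 0.05)
  expect_gt(f2$y_post, f2$y_pre)
  # failure modes are flagged, not thrown
  expect_error(boltzmann_fit(1:5, 1:5), ">= 6")
  flatfit <- boltzmann_fit(x, rep(1, length(x)))
  expect_s3_class(flatfit, "two_state_fit")
})

test_that("Boltzmann midpoint is precise under measurement noise", {
  errs <- vapply(1:50, function(s) {
    scan <- simulate_cd_thermal(47, 35, noise_sd = 0.02 * 17000, seed = s)
    fit <- boltzmann_fit(scan$temperature, scan$theta222)
    abs(fit$x50 - 47)
  }, numeric(1))
  expect_lt(median(errs), 0.3)
})

test_that("van't Hoff enthalpy follows the closed form and round-trips", {
  # Tm = 320 K, a = 2 K: dH = 1.987e-3 * 320^2 / 2
  f <- structure(list(x50 = 320 - 273.15, a = 2, converged = TRUE),
                 class = "two_state_fit")
  expect_equal(vant_hoff_dh(f), 1.987e-3 * 320^2 / 2, tolerance = 1e-12)
  # broad transitions carry vanishing apparent enthalpy
  f$a <- 1e6
  expect_lt(vant_hoff_dh(f), 1e-3)
  # generative round-trip within 2 percent
  scan <- simulate_cd_thermal(55, 50)
  fit <- boltzmann_fit(scan$temperature, scan$theta222)
  expect_equal(vant_hoff_dh(fit), 50, tolerance = 0.02)
  # unit invariance: rescaling the signal leaves dH untouched
  fit2 <- boltzmann_fit(scan$temperature, scan$theta222 * 1e-3 + 7)
  expect_equal(vant_hoff_dh(fit2), vant_hoff_dh(fit), tolerance = 1e-6)
  bad <- structure(list(converged = FALSE), class = "two_state_fit")
  expect_error(vant_hoff_dh(bad), "unconverged")
})

test_that("chemical denaturation midpoint and LEM recover generative values", {
  s <- simulate_chem_denat(5, 2)
  fit <- chem_denat_midpoint(s)
  expect_equal(fit$x50, 2.5, tolerance = 1e-8)
  expect_error(chem_denat_midpoint(list(conc_M = c(0, 1), lambda_max = c(335, 355))),
               ">= 6")
  lem <- lem_free_energy(s, fit)
  expect_equal(lem$dg0, 5, tolerance = 1e-9)
  expect_equal(lem$m_value, 2, tolerance = 1e-9)
  expect_equal(lem$d_half, 2.5, tolerance = 1e-9)
  expect_gt(lem$r_squared, 1 - 1e-12)
  # dG vanishes at the midpoint by construction
  expect_lt(abs(lem$dg0 - lem$m_value * lem$d_half), 1e-9)
  # too narrow a transition window is rejected with a count
  expect_error(lem_free_energy(s, fit, window = c(0.49, 0.51)), ">= 3")
})

test_that("LEM midpoint and free energy are robust to wavelength noise", {
  res <- vapply(1:50, function(s) {
    ser <- simulate_chem_denat(5, 2, noise_sd = 0.3, seed = s)
    fit <- chem_denat_midpoint(ser)
    if (!fit$converged) return(c(NA, NA))
    lem <- tryCatch(lem_free_energy(ser, fit), error = function(e) NULL)
    if (is.null(lem)) return(c(NA, NA))
    c(abs(fit$x50 - 2.5), abs(lem$dg0 - 5) / 5)
  }, numeric(2))
  expect_lt(median(res[1, ], na.rm = TRUE), 0.1)
  expect_lt(median(res[2, ], na.rm = TRUE), 0.1)
  # consistency identity under noise: dg0 ~ m * d_half within 5 percent
  ser <- simulate_chem_denat(5, 2, noise_sd = 0.3, seed = 7)
  lem <- lem_free_energy(ser, chem_denat_midpoint(ser))
  expect_lt(abs(lem$dg0 - lem$m_value * lem$d_half) / lem$dg0, 0.05)
})
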