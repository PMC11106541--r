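test_that("Savitzky-Golay smoothing validates parameters and preserves low-degree signals", {
  grid <- seq(20, 80, by = 0.5)
  poly <- melt_curve(grid, 2 + 0.5 * grid - 0.01 * grid^2)
  expect_error(smooth_curve(poly, window = 1), "odd")
  expect_error(smooth_curve(poly, window = 4), "odd")
  expect_error(smooth_curve(poly, window = 7, order = 7), "order")
  expect_error(smooth_curve(melt_curve(1:5, 1:5), window = 5), "shorter")
  # exact on polynomials of degree <= order
  sm <- smooth_curve(poly, window = 7, order = 2)
  expect_equal(sm$fluorescence, poly$fluorescence, tolerance = 1e-12)
  expect_equal(sm$temperature, poly$temperature)
  expect_equal(sm$meta$smoothing, list(window = 7, order = 2))
  # near-identity on the noiseless sigmoid fixture, relative to its range
  cur <- simulate_melt_curve(mut_params())
  smc <- smooth_curve(cur)
  rel <- max(abs(smc$fluorescence - cur$fluorescence)) /
    diff(range(cur$fluorescence))
  expect_lt(rel, 1e-5)
})

test_that("negative derivative handles constant, linear and sigmoid signals", {
  grid <- seq(0, 10, by = 0.5)
  expect_equal(neg_derivative(melt_curve(grid, rep(3, length(grid))))$neg_dfdt,
               rep(0, length(grid)))
  expect_equal(neg_derivative(melt_curve(grid, grid))$neg_dfdt,
               rep(-1, length(grid)))
  # transition minimum lands at the generative midpoint within one grid step
  cur <- simulate_melt_curve(mut_params())
  d <- neg_derivative(cur)
  expect_equal(d$temperature[which.min(d$neg_dfdt)], 47, tolerance = 0.5)
  expect_error(neg_derivative(melt_curve(1:4, 1:4)), ">= 5")
})

test_that("Tm calling recovers the fixture midpoints with quality flags", {
  tm_mut <- tm_from_curve(simulate_melt_curve(mut_params()))
  expect_equal(tm_mut$tm_c, 47, tolerance = 0.5)
  expect_length(tm_mut$flags, 0)
  tm_wt <- tm_from_curve(simulate_melt_curve(wt_params()))
  expect_equal(tm_wt$tm_c, 65, tolerance = 0.5)
  expect_equal(tm_wt$tm_c - tm_mut$tm_c, 18, tolerance = 1)

  # constant curve is a flat no-call, not an exception
  grid <- seq(20, 80, by = 0.5)
  flat <- call_tm(neg_derivative(melt_curve(grid, rep(5, length(grid)))))
  expect_true(is.na(flat$tm_c))
  expect_true("flat_curve" %in% flat$flags)

  # a monotone ramp puts the extremum on the window edge
  ramp <- call_tm(neg_derivative(melt_curve(grid, grid^2)))
  expect_true("edge_minimum" %in% ramp$flags)

  # two transitions of comparable depth raise the multiple-minima flag
  # (widths a = R Tm^2 / dH matched so the derivative dips are equal)
  two <- simulate_melt_curve(thermo_params(35, 60), grid)
  two$fluorescence <- two$fluorescence +
    simulate_melt_curve(thermo_params(65, 72), grid)$fluorescence
  tm2 <- tm_from_curve(two)
  expect_true("multiple_minima" %in% tm2$flags)

  expect_error(call_tm(neg_derivative(simulate_melt_curve(mut_params())),
                       search = c(10, 90)), "search window")
})

test_that("Tm calling converges under grid refinement and translates with the midpoint", {
  tm_at <- function(step, tm) {
    cur <- simulate_melt_curve(thermo_params(tm, 35), seq(20, 80, by = step))
    tm_from_curve(cur)$tm_c
  }
  coarse <- tm_at(0.5, 47)
  fine <- tm_at(0.25, 47)
  expect_lt(abs(fine - coarse), 0.5)
  # translation equivariance within one grid step
  delta <- 3.3
  expect_equal(tm_at(0.5, 47 + delta) - tm_at(0.5, 47), delta,
               tolerance = 0.5)
})

test_that("derivative-called Tm matches the Boltzmann-fit midpoint on symmetric curves", {
  for (tm in c(47, 55, 65)) {
    cur <- simulate_melt_curve(thermo_params(tm, 45))
    called <- tm_from_curve(cur)$tm_c
    fitted <- boltzmann_fit(cur$temperature, cur$fluorescence)$x50
    expect_equal(called, fitted, tolerance = 0.5)
  }
})
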