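test_that("library roster lays compounds out with unique coordinates", {
  roster <- make_library_roster(c(Pfizer = 81, FDA = 875))
  expect_equal(nrow(roster), 956)
  expect_equal(sum(roster$library == "Pfizer"), 81)
  expect_false(anyDuplicated(roster$id) > 0)
  expect_false(anyDuplicated(paste(roster$plate, roster$well)) > 0)
  # reference wells are reserved on every plate
  expect_false(any(roster$well %in% c("H11", "H12")))

  single <- make_library_roster(c(X = 1))
  expect_equal(nrow(single), 1)
  expect_equal(single$plate, 1L)
  expect_equal(single$well, "A1")

  expect_error(make_library_roster(c(X = 0)), "positive")
})

test_that("melt-curve generator honors the two-state model identities", {
  grid <- default_temperature_grid()
  cur <- simulate_melt_curve(mut_params(), grid)
  # f(Tm) = 1/2 exactly: fluorescence at the midpoint is the state average
  i <- which(grid == 47)
  expect_equal(cur$fluorescence[i], (1000 + 9000) / 2)
  # monotone sigmoid when the decay term is off and baselines are flat
  expect_true(all(diff(cur$fluorescence) >= 0))
  # decay > 0 gives an interior maximum above the midpoint
  dec <- simulate_melt_curve(mut_params(decay_rate = 0.02), grid)
  i_max <- which.max(dec$fluorescence)
  expect_gt(grid[i_max], 47)
  expect_lt(i_max, length(grid))
  # grid validation
  expect_error(simulate_melt_curve(mut_params(), seq(20, 30, by = 0.5)),
               "inside the grid")
  expect_error(simulate_melt_curve(mut_params(), c(20, 30, 40, 50)), ">= 5")
})

test_that("screen generator plants hits, references and interference wells", {
  sc <- small_scenario()
  screen <- simulate_screen(sc)
  expect_equal(length(screen$curves), 50)
  # planted wells are WT-like, everything else mutant-like
  tm_of <- function(id) screen$curves[[id]]$meta$params$tm_c
  hits <- c("A-003", "A-011", "B-005", "B-017", "B-028")
  expect_true(all(vapply(hits, tm_of, numeric(1)) == 65))
  others <- setdiff(names(screen$curves), hits)
  expect_true(all(vapply(others, tm_of, numeric(1)) == 47))
  # interference compound-alone well has a large dynamic range
  expect_gt(curve_rng <- diff(range(screen$compound_alone[["B-002"]]$fluorescence)), 1000)
  expect_equal(diff(range(screen$compound_alone[["B-003"]]$fluorescence)), 0)
  # no planted hits -> every sample well shares the mutant parameters
  sc0 <- small_scenario()
  sc0$hits <- list()
  screen0 <- simulate_screen(sc0)
  expect_true(all(vapply(names(screen0$curves), function(id) {
    screen0$curves[[id]]$meta$params$tm_c
  }, numeric(1)) == 47))
})

test_that("generators are deterministic under a fixed scenario and seed", {
  sc <- small_scenario(noise_sd = 30)
  s1 <- simulate_screen(sc)
  s2 <- simulate_screen(sc)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  # and a changed seed changes the noise
  sc2 <- small_scenario(noise_sd = 30, seed = 43L)
  s3 <- simulate_screen(sc2)
  expect_false(identical(s1$curves[[1]]$fluorescence,
                         s3$curves[[1]]$fluorescence))
})

test_that("chemical denaturation generator obeys its closed-form limits", {
  s <- simulate_chem_denat(5, 2, lam_f = 335, lam_u = 355,
                           concs = seq(0, 5, by = 0.25))
  # D = dg0/m puts the wavelength exactly at the band midpoint
  i <- which(s$conc_M == 2.5)
  expect_equal(s$lambda_max[i], 345)
  # fully folded limit at zero denaturant
  expect_lt(abs(s$lambda_max[1] - 335), 0.01)
  # monotone nondecreasing in denaturant
  expect_true(all(diff(s$lambda_max) >= 0))
  expect_error(simulate_chem_denat(-1, 2), "dg0")
  expect_error(simulate_chem_denat(5, 2, concs = numeric(0)), "empty")
  expect_error(simulate_chem_denat(5, 2, lam_f = 360, lam_u = 355), "lam_u")
})

test_that("Tm-dose generator hits the hyperbola anchors", {
  d <- simulate_tm_dose(0.2, tm0 = 47, dtm_max = 18,
                        concs = c(0, 0.2, 1000))
  expect_equal(d$tm_c[1], 47)
  expect_equal(d$tm_c[2], 47 + 9)
  expect_equal(d$tm_c[3], 65, tolerance = 1e-3)
  expect_error(simulate_tm_dose(-1), "ec50")
})

test_that("ITC generator follows the dilution schedule and hyperbolic heats", {
  e <- simulate_itc(0.40, q_max = 200, syringe_conc_mM = 5)
  # dilution-schedule arithmetic, checked by hand: 1 ul of 5 mM into 350 ul
  conc <- itc_ligand_conc(1, 350, 5, n_inj = 50)
  expect_equal(conc[1], 5 * (1 / 350) * (349 / 350), tolerance = 1e-12)
  expect_equal(conc[1], 5 / 351, tolerance = 1e-3)
  expect_true(all(diff(conc) > 0))
  # ligand spans the half-saturation point within 50 injections
  expect_gt(max(conc), 0.40)
  # hyperbola is concave: first corrected injection heat is the largest
  corr <- correct_itc(e)
  expect_equal(which.max(corr$dq), 1L)
  # q_max = 0 -> all corrected heats vanish
  e0 <- simulate_itc(0.40, q_max = 0, syringe_conc_mM = 5)
  expect_true(all(abs(correct_itc(e0)$dq) < 1e-12))
  expect_error(simulate_itc(0.4, 200, syringe_conc_mM = -5), "positive")
})

test_that("viability and efflux generators partition signal as configured", {
  de <- tibble::tibble(compound = "bexarotene",
                       conc_mM = c(0.2, 0.5),
                       surviving_frac = c(0.75, 0.25))
  plate <- simulate_viability(de)
  ctrl <- plate$absorbance[plate$is_control]
  expect_equal(unique(ctrl), 1.0)
  summ <- viability_summary(plate)
  expect_equal(summ$percent[summ$conc_mM == 0.5], 25)
  expect_error(
    simulate_viability(tibble::tibble(compound = "x", conc_mM = 1,
                                      surviving_frac = 1.5)),
    "\\[0, 1\\]")

  eff <- tibble::tibble(protein = "WT", compound = NA_character_,
                        conc_mM = NA_real_, camp = TRUE, efflux_frac = 0.3)
  tab <- simulate_efflux(eff, total_cpm = 1000)
  expect_true(all(tab$cpm_medium + tab$cpm_cells == 1000))
  expect_true(all(tab$cpm_medium == 300))
})

test_that("noiseless generator output round-trips through its estimator", {
  # chemical denaturation -> Boltzmann midpoint + LEM
  s <- simulate_chem_denat(5, 2)
  fit <- chem_denat_midpoint(s)
  lem <- lem_free_energy(s, fit)
  expect_equal(fit$x50, 2.5, tolerance = 1e-8)
  expect_equal(lem$dg0, 5, tolerance = 1e-8)
  expect_equal(lem$m_value, 2, tolerance = 1e-8)
  # melt curve -> Boltzmann midpoint (two-state, flat baselines)
  cur <- simulate_melt_curve(mut_params())
  bf <- boltzmann_fit(cur$temperature, cur$fluorescence)
  expect_equal(bf$x50, 47, tolerance = 0.01)
  # Tm dose -> one-site EC50
  f <- fit_tm_dose(simulate_tm_dose(0.32))
  expect_equal(f$ec50, 0.32, tolerance = 1e-6)
  expect_equal(f$amplitude, 18, tolerance = 1e-6)
  # ITC -> one-site EC50
  fi <- fit_itc(correct_itc(simulate_itc(0.40, 200, 5)))
  expect_equal(fi$ec50, 0.40, tolerance = 1e-6)
})
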