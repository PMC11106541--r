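test_that("normalized curve RMSD compares shape, not scale", {
  a <- simulate_melt_curve(mut_params())
  expect_equal(normalized_curve_rmsd(a, a), 0)
  # vertical affine transforms are invisible to the measure
  b <- a
  b$fluorescence <- 3.7 * a$fluorescence + 1234
  expect_equal(normalized_curve_rmsd(a, b), 0, tolerance = 1e-12)
  # WT and mutant fixtures are far apart in shape (frozen regression value)
  wt <- simulate_melt_curve(wt_params())
  expect_equal(normalized_curve_rmsd(a, wt), 0.3837, tolerance = 1e-3)
  expect_gt(normalized_curve_rmsd(a, wt), hit_criteria()$max_curve_rmsd)
  disjoint <- melt_curve(seq(100, 120, by = 1), seq(100, 120, by = 1))
  expect_error(normalized_curve_rmsd(a, disjoint), "overlapping")
})

test_that("hit selection reproduces planted hits and excludes interference", {
  screen <- simulate_screen(small_scenario())
  calls <- call_wells(screen)
  res <- select_hits(calls$wells, calls$wt_ref, calls$mut_ref)
  expect_setequal(res$id[res$hit],
                  c("A-003", "A-011", "B-005", "B-017", "B-028"))
  expect_true(res$interference[res$id == "B-002"])
  expect_equal(res$reason[res$id == "B-002"], "interference")
  # mutant-only plates yield no hits
  sc0 <- small_scenario()
  sc0$hits <- list()
  screen0 <- simulate_screen(sc0)
  calls0 <- call_wells(screen0)
  res0 <- select_hits(calls0$wells, calls0$wt_ref, calls0$mut_ref)
  expect_equal(sum(res0$hit), 0)
  # a WT curve submitted as a sample well is always a hit (self-similarity)
  wt_row <- calls$wells[calls$wells$id == "A-003", ]
  wt_row$curve <- list(calls$wt_ref$curve)
  wt_row$tm_c <- calls$wt_ref$tm$tm_c
  res_wt <- select_hits(wt_row, calls$wt_ref, calls$mut_ref)
  expect_true(res_wt$hit)
  # missing references are rejected
  expect_error(select_hits(calls$wells, list(tm = NULL), calls$mut_ref),
               "reference")
})

test_that("hit selection is monotone in criteria and invariant to well order", {
  screen <- simulate_screen(small_scenario(noise_sd = 40))
  calls <- call_wells(screen)
  base <- select_hits(calls$wells, calls$wt_ref, calls$mut_ref,
                      hit_criteria())
  # relaxing any threshold never removes a hit
  relaxed_list <- list(
    hit_criteria(min_shift = 2), hit_criteria(max_wt_gap = 10),
    hit_criteria(max_curve_rmsd = 0.3), hit_criteria(interference_ratio = 2))
  for (cr in relaxed_list) {
    rel <- select_hits(calls$wells, calls$wt_ref, calls$mut_ref, cr)
    expect_true(all(rel$hit[base$hit]))
  }
  # an unreachable shift threshold kills every hit; maximally relaxed
  # criteria make every called, non-interfering well a hit
  none <- select_hits(calls$wells, calls$wt_ref, calls$mut_ref,
                      hit_criteria(min_shift = 1e6))
  expect_equal(sum(none$hit), 0)
  all_in <- select_hits(calls$wells, calls$wt_ref, calls$mut_ref,
                        hit_criteria(min_shift = 1e-9, max_wt_gap = 1e6,
                                     max_curve_rmsd = 1e6,
                                     interference_ratio = 1e6))
  expect_true(all(all_in$hit == (!is.na(all_in$tm_c) &
                                   all_in$shift >= 1e-9)))
  # permutation safety
  perm <- sample(nrow(calls$wells))
  shuffled <- select_hits(calls$wells[perm, ], calls$wt_ref, calls$mut_ref)
  expect_equal(shuffled$hit[order(shuffled$id)], base$hit[order(base$id)])
})

test_that("ANS peak finding locates the band and flags empty spectra", {
  s <- simulate_ans_spectrum(1.5, peak_nm = 470)
  p <- ans_peak(s)
  expect_equal(p$peak_nm, 470, tolerance = 1)
  expect_false(p$flat)
  z <- simulate_ans_spectrum(0)
  pz <- ans_peak(z)
  expect_true(pz$flat)
  expect_equal(pz$peak_intensity, 0)
  # mutant fixture is brighter than WT (more exposed hydrophobic surface)
  pw <- ans_peak(simulate_ans_spectrum(1.0))
  pm <- ans_peak(simulate_ans_spectrum(1.8))
  expect_gt(pm$peak_intensity, pw$peak_intensity)
  expect_error(ans_peak(list(wavelength = 400:500, intensity = rep(1, 101))),
               "425-600")
})

test_that("ANS ratio statistic has the right identities and invariances", {
  w <- simulate_ans_spectrum(1.0)
  m2 <- simulate_ans_spectrum(2.0)
  res <- ans_ratio_test(list(w, w), list(w, w), control_ratios = c(1, 1))
  expect_equal(res$ratios, c(1, 1))
  res2 <- ans_ratio_test(list(w, w), list(m2, m2), control_ratios = c(1, 1))
  expect_equal(res2$ratios, c(0.5, 0.5))
  # scale invariance: scaling both spectra leaves the ratio unchanged
  k <- 7.3
  wk <- w; wk$intensity <- k * w$intensity
  mk <- m2; mk$intensity <- k * m2$intensity
  resk <- ans_ratio_test(list(wk, wk), list(mk, mk), control_ratios = c(1, 1))
  expect_equal(resk$ratios, res2$ratios, tolerance = 1e-12)
  # single replicate: flagged, no verdict
  res1 <- ans_ratio_test(list(w), list(m2), control_ratios = c(1, 1))
  expect_true(res1$flagged)
  expect_true(is.na(res1$pass))
})

test_that("a corrector separates from control ratios at alpha = 0.01", {
  noise <- 20
  spec <- function(exposure, seed) {
    simulate_ans_spectrum(exposure, noise_sd = noise, seed = seed)
  }
  control <- vapply(1:3, function(r) {
    ans_peak(spec(1.0, 100 + r))$peak_intensity /
      ans_peak(spec(1.8, 200 + r))$peak_intensity
  }, numeric(1))
  wt_reps <- lapply(1:3, function(r) spec(1.0, 300 + r))
  corr_reps <- lapply(1:3, function(r) spec(1.0, 400 + r))
  res <- ans_ratio_test(wt_reps, corr_reps, control, alpha = 0.01)
  expect_true(res$pass)
  # a non-corrector (mutant stays exposed) does not pass
  mut_reps <- lapply(1:3, function(r) spec(1.8, 500 + r))
  res_null <- ans_ratio_test(wt_reps, mut_reps, control, alpha = 0.01)
  expect_false(res_null$pass)
})
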