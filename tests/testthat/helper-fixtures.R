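# Shared fixtures: the default WT / mutant generative parameters and the
# standard smoothing -> derivative -> Tm-call chain.

mut_params <- function(...) thermo_params(47, 35, ...)
wt_params <- function(...) thermo_params(65, 55, ...)

tm_from_curve <- function(curve, ...) {
  call_tm(neg_derivative(smooth_curve(curve)), ...)
}

# A small screening scenario (50 compounds, 2 + 3 planted hits, one
# interference compound) for tests that exercise structure rather than the
# full campaign scale.
small_scenario <- function(noise_sd = 0, seed = 42L) {
  wt <- thermo_params(65, 55, noise_sd = noise_sd)
  mut <- thermo_params(47, 35, noise_sd = noise_sd)
  screen_scenario(
    libraries = c(A = 20L, B = 30L),
    wt = wt, mutant = mut,
    hits = list(A = c(3L, 11L), B = c(5L, 17L, 28L)),
    interference = "B-002",
    candidates = list(`A-003` = list(name = "probe", ans_corrector = TRUE,
                                     tm_dose = list(ec50 = 0.1, dtm_max = 18),
                                     viability = c(1, 1, 1, 1, 1),
                                     efflux_restores = TRUE)),
    seed = seed
  )
}
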