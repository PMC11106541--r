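#' Generative parameters of a two-state thermal unfolding fixture
#'
#' Parameterizes the dye-response model used by [simulate_melt_curve()]:
#' a van't Hoff two-state fraction unfolded mixes a folded-state baseline
#' with an unfolded-state amplitude, optionally attenuated above the
#' midpoint by an exponential decay that reproduces the peaked shape of
#' real dye-based melt curves.
#'
#' @param tm_c Transition midpoint (degrees C).
#' @param dh_vh van't Hoff enthalpy (kcal/mol), > 0.
#' @param f_base,f_amp Folded-state baseline and unfolded-state amplitude
#'   (arbitrary fluorescence units).
#' @param base_slope_f,base_slope_u Linear baseline slopes (AU per degree C).
#' @param decay_rate Post-transition signal decay constant (1/degree C, >= 0).
#' @param noise_sd Additive Gaussian noise SD (AU), >= 0.
#'
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(tm_c, dh_vh, f_base = 1000, f_amp = 9000,
                          base_slope_f = 0, base_slope_u = 0,
                          decay_rate = 0, noise_sd = 0) {
  if (!is.finite(tm_c)) stop_input("tm_c must be finite")
  if (!is.finite(dh_vh) || dh_vh <= 0) stop_input("dh_vh must be > 0")
  if (decay_rate < 0) stop_input("decay_rate must be >= 0")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  structure(
    list(tm_c = tm_c, dh_vh = dh_vh, f_base = f_base, f_amp = f_amp,
         base_slope_f = base_slope_f, base_slope_u = base_slope_u,
         decay_rate = decay_rate, noise_sd = noise_sd),
    class = "thermo_params"
  )
}

compound_id <- function(library, index) sprintf("%s-%03d", library, index)

#' Define a screening scenario
#'
#' A scenario bundles everything the synthetic generators need to emulate a
#' full structure-corrector campaign: the compound libraries, the wild-type
#' and mutant generative thermodynamics, which wells carry planted
#' correctors, which compounds autofluoresce (interference), the per-assay
#' settings, and the master seed. A fixed scenario plus seed reproduces
#' every generated artifact exactly.
#'
#' @param libraries Named integer vector of library sizes, e.g.
#'   `c(Pfizer = 81, FDA = 875)`.
#' @param wt,mutant [thermo_params()] for the two protein forms.
#' @param hits Named list (by library) of 1-based compound indices whose
#'   wells are planted with WT-like melting behavior.
#' @param interference Character vector of compound ids whose
#'   compound-alone wells show a large intrinsic signal.
#' @param candidates Named list (by compound id) describing follow-up
#'   candidates: fields `name`, `ans_corrector`, `tm_dose` (list `ec50`,
#'   `dtm_max`), optional `itc` (list `ec50`, `q_max`, `syringe_conc_mM`),
#'   `viability` (surviving fractions at `assays$viability_concs`), and
#'   optional `efflux_restores`.
#' @param assays Named list of assay settings; see
#'   [paper_default_scenario()] for the full shape.
#' @param seed Integer master seed.
#'
#' @return An object of class `screen_scenario`.
#' @export
screen_scenario <- function(libraries, wt, mutant, hits = list(),
                            interference = character(0),
                            candidates = list(), assays = default_assays(),
                            seed = 1905L) {
  if (is.null(names(libraries)) || any(!nzchar(names(libraries)))) {
    stop_input("libraries must be a named vector of sizes")
  }
  if (any(libraries <= 0)) stop_input("library sizes must be positive")
  stopifnot(inherits(wt, "thermo_params"), inherits(mutant, "thermo_params"))
  for (lib in names(hits)) {
    if (!lib %in% names(libraries)) {
      stop_input("hit library '%s' is not a defined library", lib)
    }
    idx <- hits[[lib]]
    if (length(idx) > libraries[[lib]] ||
        any(idx < 1 | idx > libraries[[lib]])) {
      stop_input("hit indices for '%s' must be within 1..%d",
                 lib, libraries[[lib]])
    }
    if (anyDuplicated(idx)) stop_input("duplicate hit indices for '%s'", lib)
  }
  seed <- as.integer(seed)
  structure(
    list(libraries = libraries, wt = wt, mutant = mutant, hits = hits,
         interference = interference, candidates = candidates,
         assays = assays, seed = seed),
    class = "screen_scenario"
  )
}

#' @rdname screen_scenario
#' @export
default_assays <- function() {
  list(
    grid = default_temperature_grid(),
    screen_conc_mM = 0.1,
    ans = list(grid_nm = seq(425, 600, by = 1), peak_nm = 470, width_nm = 40,
               amp = 1000, wt_exposure = 1.0, mut_exposure = 1.8,
               corrected_exposure = 1.0, noise_frac = 0.02, reps = 3),
    dose_concs_mM = c(0, 0.05, 0.1, 0.2, 0.5),
    viability_concs_mM = c(0.01, 0.05, 0.1, 0.2, 0.5),
    viability = list(control_abs = 1.0, reps = 3, noise_sd = 0),
    efflux = list(total_cpm = 2e5, basal_frac = 0.04, wt_net_frac = 0.08,
                  mutant_net_ratio = 0.65, reps = 3, noise_sd = 0),
    itc = list(cell_vol_ul = 350, cell_conc_uM = 10, inj_vol_ul = 1,
               n_inj = 50, dilution_heat = -2, noise_sd = 0)
  )
}

#' The packaged default scenario
#'
#' Mirrors the published campaign this package models: a 956-compound
#' screen (81-compound licensed library plus 875 FDA-approved drugs) at
#' 0.1 mM against 5 uM protein, with 7 + 11 planted correctors of which
#' four (atorvastatin, bexarotene, adapalene, lovastatin) also correct the
#' ANS-reported hydrophobic exposure and two survive the downstream
#' viability and dose-response gates. WT and mutant midpoints default to
#' 65 and 47 degrees C (the printed mutant Tm and the printed ~18 degree
#' destabilization); melt-curve noise and the dye decay term default to
#' zero so derivative Tm calling is exactly invertible.
#'
#' @param noise_sd Melt-curve Gaussian noise SD (AU); default 0.
#' @param decay_rate Post-transition dye decay constant (1/degree C);
#'   default 0.
#' @param seed Master seed.
#'
#' @return A [screen_scenario()].
#' @export
paper_default_scenario <- function(noise_sd = 0, decay_rate = 0,
                                   seed = 1905L) {
  wt <- thermo_params(65, 55, noise_sd = noise_sd, decay_rate = decay_rate)
  mut <- thermo_params(47, 35, noise_sd = noise_sd, decay_rate = decay_rate)
  hits <- list(Pfizer = c(8L, 12L, 23L, 37L, 45L, 61L, 77L),
               FDA = c(9L, 40L, 99L, 150L, 222L, 310L, 401L,
                       487L, 550L, 701L, 860L))
  candidates <- list(
    `Pfizer-008` = list(
      name = "atorvastatin", ans_corrector = TRUE,
      tm_dose = list(ec50 = 0.32, dtm_max = 18),
      itc = list(ec50 = 0.40, q_max = 200, syringe_conc_mM = 5),
      viability = c(1, 1, 1, 1, 1),
      efflux_restores = TRUE, optimal_conc_mM = 0.2
    ),
    `FDA-009` = list(
      name = "bexarotene", ans_corrector = TRUE,
      tm_dose = list(ec50 = 0.059, dtm_max = 18),
      itc = list(ec50 = 0.098, q_max = 150, syringe_conc_mM = 2),
      viability = c(1, 1, 1, 0.75, 0.25),
      efflux_restores = TRUE, optimal_conc_mM = 0.05
    ),
    `FDA-040` = list(
      name = "adapalene", ans_corrector = TRUE,
      tm_dose = list(ec50 = 0.05, dtm_max = 15),
      viability = c(0.5, 0.4, 0.3, 0.2, 0.1),
      efflux_restores = FALSE, optimal_conc_mM = 0.05
    ),
    `FDA-099` = list(
      name = "lovastatin", ans_corrector = TRUE,
      tm_dose = list(ec50 = 0.1, dtm_max = 0.5),
      viability = c(1, 1, 1, 1, 1),
      efflux_restores = FALSE, optimal_conc_mM = 0.1
    )
  )
  screen_scenario(
    libraries = c(Pfizer = 81L, FDA = 875L),
    wt = wt, mutant = mut, hits = hits,
    interference = c("FDA-130", "FDA-600", "FDA-750"),
    candidates = candidates, assays = default_assays(), seed = seed
  )
}

scenario_hit_ids <- function(scenario) {
  unlist(lapply(names(scenario$hits), function(lib) {
    compound_id(lib, scenario$hits[[lib]])
  }), use.names = FALSE)
}

#' Read or write a scenario as a YAML file
#'
#' The on-disk form mirrors the [screen_scenario()] fields; thermodynamic
#' parameter blocks round-trip through [thermo_params()].
#'
#' @param scenario A [screen_scenario()].
#' @param path File path.
#' @return `read_scenario_yaml()` returns a [screen_scenario()];
#'   `write_scenario_yaml()` returns `path` invisibly.
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "screen_scenario"))
  x <- unclass(scenario)
  x$libraries <- as.list(x$libraries)
  x$wt <- unclass(x$wt)
  x$mutant <- unclass(x$mutant)
  x$assays$grid <- list(min = min(scenario$assays$grid),
                        max = max(scenario$assays$grid),
                        step = diff(scenario$assays$grid)[1])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  libs <- unlist(x$libraries)
  assays <- x$assays
  assays$grid <- seq(assays$grid$min, assays$grid$max, by = assays$grid$step)
  screen_scenario(
    libraries = libs,
    wt = do.call(thermo_params, x$wt),
    mutant = do.call(thermo_params, x$mutant),
    hits = x$hits,
    interference = as.character(unlist(x$interference %||% character(0))),
    candidates = x$candidates,
    assays = assays,
    seed = x$seed
  )
}
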