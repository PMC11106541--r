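# Synthetic assay generators. Each generator draws from the statistical
# model the downstream estimator assumes (two-state unfolding, one-site
# hyperbolic binding, proportional count partitioning) plus additive
# i.i.d. Gaussian noise, and is deterministic given its seed.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12
# H11/H12 are reserved on every plate for the WT and mutant reference wells
REF_WELLS <- c("H11", "H12")

plate_sample_wells <- function() {
  wells <- as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
  setdiff(wells, REF_WELLS)
}

#' Build a compound roster from library definitions
#'
#' Lays the libraries out sequentially onto 96-well plates, reserving two
#' wells per plate (H11, H12) for the WT and mutant reference wells.
#'
#' @param library_defs Named vector of positive library sizes, e.g.
#'   `c(Pfizer = 81, FDA = 875)`.
#' @param conc_mM Screening concentration applied to every compound
#'   (default 0.1 mM).
#' @param names Optional named character vector mapping compound ids to
#'   human-readable names.
#'
#' @return A tibble with one row per compound: `id`, `name`, `library`,
#'   `lib_index`, `plate`, `well`, `conc_mM`.
#' @export
make_library_roster <- function(library_defs, conc_mM = 0.1, names = NULL) {
  if (is.list(library_defs)) library_defs <- unlist(library_defs)
  if (is.null(base::names(library_defs)) ||
      any(!nzchar(base::names(library_defs)))) {
    stop_input("library definitions must be named")
  }
  if (any(library_defs <= 0)) {
    stop_input("library sizes must be positive (got %s)",
               paste(library_defs[library_defs <= 0], collapse = ", "))
  }
  libs <- base::names(library_defs)
  roster <- dplyr::bind_rows(lapply(libs, function(lib) {
    tibble::tibble(library = lib, lib_index = seq_len(library_defs[[lib]]))
  }))
  roster$id <- compound_id(roster$library, roster$lib_index)
  wells <- plate_sample_wells()
  cap <- length(wells)
  pos <- seq_len(nrow(roster)) - 1L
  roster$plate <- pos %/% cap + 1L
  roster$well <- wells[pos %% cap + 1L]
  roster$conc_mM <- conc_mM
  roster$name <- if (is.null(names)) NA_character_ else unname(names[roster$id])
  roster[, c("id", "name", "library", "lib_index", "plate", "well", "conc_mM")]
}

#' Simulate one dye-based melt curve
#'
#' Two-state van't Hoff unfolding drives a dye-response model: the folded
#' and unfolded states each contribute a linear baseline, the unfolded
#' contribution decays exponentially above the midpoint (mimicking dye
#' dissociation from the unfolded state at high temperature), and i.i.d.
#' Gaussian noise is added per point.
#'
#' @param params A [thermo_params()].
#' @param grid Strictly increasing temperature grid (degrees C), >= 5
#'   points, with `params$tm_c` strictly inside it.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param well,protein,compound,conc_mM Metadata passed to [melt_curve()].
#'
#' @return A [melt_curve()] carrying `params` in its metadata.
#' @export
simulate_melt_curve <- function(params, grid = default_temperature_grid(),
                                seed = NULL, well = NA_character_,
                                protein = NA_character_,
                                compound = NA_character_,
                                conc_mM = NA_real_) {
  stopifnot(inherits(params, "thermo_params"))
  if (length(grid) < 5) stop_input("temperature grid needs >= 5 points")
  if (any(diff(grid) <= 0)) stop_input("grid must be strictly increasing")
  if (params$tm_c <= min(grid) || params$tm_c >= max(grid)) {
    stop_input("tm_c (%.1f) must lie strictly inside the grid [%.1f, %.1f]",
               params$tm_c, min(grid), max(grid))
  }
  f <- vant_hoff_fraction_unfolded(grid, params$tm_c, params$dh_vh)
  fl <- (1 - f) * (params$f_base + params$base_slope_f * grid) +
    f * (params$f_amp + params$base_slope_u * grid) *
      exp(-params$decay_rate * pmax(0, grid - params$tm_c))
  if (params$noise_sd > 0) {
    fl <- fl + with_optional_seed(
      seed, stats::rnorm(length(grid), sd = params$noise_sd))
  }
  melt_curve(grid, fl, well = well, protein = protein, compound = compound,
             conc_mM = conc_mM, meta = list(params = params, seed = seed))
}

# Compound-alone well: flat dye background, or a strongly ramping
# intrinsic signal for interference compounds.
simulate_compound_alone <- function(grid, interferes, noise_sd = 0,
                                    seed = NULL, well = NA_character_,
                                    compound = NA_character_) {
  fl <- if (interferes) 500 + 80 * (grid - min(grid)) else rep(100, length(grid))
  if (noise_sd > 0) {
    fl <- fl + with_optional_seed(
      seed, stats::rnorm(length(grid), sd = noise_sd))
  }
  melt_curve(grid, fl, well = well, protein = NA_character_,
             compound = compound, meta = list(compound_alone = TRUE))
}

#' Simulate a full primary screen
#'
#' Generates mutant-protein-plus-compound melt curves for every roster
#' well (planted hits use the WT-like parameters), a compound-alone plate
#' for interference detection, and per-plate WT and mutant reference
#' wells. Per-well seeds are derived from the scenario seed, so identical
#' scenario + seed reproduce the plates exactly.
#'
#' @param scenario A [screen_scenario()].
#'
#' @return An object of class `screen_set`: `roster`, named lists `curves`
#'   and `compound_alone` (keyed by compound id), per-plate `wt_ref` and
#'   `mut_ref` curves, and the `scenario`.
#' @export
simulate_screen <- function(scenario) {
  stopifnot(inherits(scenario, "screen_scenario"))
  cand_names <- vapply(scenario$candidates, function(x) x$name %||% NA_character_, "")
  roster <- make_library_roster(scenario$libraries,
                                conc_mM = scenario$assays$screen_conc_mM,
                                names = cand_names)
  hit_ids <- scenario_hit_ids(scenario)
  grid <- scenario$assays$grid
  curves <- vector("list", nrow(roster))
  alone <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    id <- roster$id[i]
    params <- if (id %in% hit_ids) scenario$wt else scenario$mutant
    curves[[i]] <- simulate_melt_curve(
      params, grid, seed = scenario$seed + i, well = roster$well[i],
      protein = "L178P", compound = id, conc_mM = roster$conc_mM[i])
    alone[[i]] <- simulate_compound_alone(
      grid, interferes = id %in% scenario$interference,
      noise_sd = scenario$mutant$noise_sd, seed = scenario$seed + 500000L + i,
      well = roster$well[i], compound = id)
  }
  names(curves) <- roster$id
  names(alone) <- roster$id
  plates <- sort(unique(roster$plate))
  wt_ref <- lapply(plates, function(p) {
    simulate_melt_curve(scenario$wt, grid, seed = scenario$seed + 100000L + p,
                        well = REF_WELLS[1], protein = "WT")
  })
  mut_ref <- lapply(plates, function(p) {
    simulate_melt_curve(scenario$mutant, grid,
                        seed = scenario$seed + 200000L + p,
                        well = REF_WELLS[2], protein = "L178P")
  })
  names(wt_ref) <- names(mut_ref) <- as.character(plates)
  structure(
    list(roster = roster, curves = curves, compound_alone = alone,
         wt_ref = wt_ref, mut_ref = mut_ref, scenario = scenario),
    class = "screen_set"
  )
}

#' @export
print.screen_set <- function(x, ...) {
  cat(sprintf("<screen_set> %d compounds on %d plates (%d planted hits)\n",
              nrow(x$roster), length(x$wt_ref),
              length(scenario_hit_ids(x$scenario))))
  invisible(x)
}

#' Simulate an ANS emission spectrum
#'
#' A Gaussian emission band over the 425-600 nm window, scaled by the
#' protein's solvent-exposed hydrophobic surface (`exposure`): the
#' destabilized mutant exposes more hydrophobic surface than WT and so
#' binds more of the amphipathic probe, giving a brighter band.
#'
#' @param exposure Nonnegative scale of the emission band (dimensionless;
#'   only ratios between spectra are meaningful).
#' @param peak_nm Band center (nm).
#' @param grid_nm Emission wavelengths within 425-600 nm.
#' @param width_nm Gaussian band SD (nm).
#' @param amp Amplitude at unit exposure (AU).
#' @param noise_sd Additive Gaussian noise SD (AU).
#' @param seed Optional seed.
#'
#' @return An object of class `ans_spectrum` with `wavelength` and
#'   `intensity`.
#' @export
simulate_ans_spectrum <- function(exposure, peak_nm = 470,
                                  grid_nm = seq(425, 600, by = 1),
                                  width_nm = 40, amp = 1000, noise_sd = 0,
                                  seed = NULL) {
  if (exposure < 0) stop_input("exposure must be >= 0")
  if (any(grid_nm < 425 | grid_nm > 600)) {
    stop_input("emission grid must lie within 425-600 nm")
  }
  intensity <- exposure * amp * exp(-(grid_nm - peak_nm)^2 / (2 * width_nm^2))
  if (noise_sd > 0) {
    intensity <- intensity + with_optional_seed(
      seed, stats::rnorm(length(grid_nm), sd = noise_sd))
  }
  structure(list(wavelength = grid_nm, intensity = intensity,
                 meta = list(exposure = exposure, peak_nm = peak_nm)),
            class = "ans_spectrum")
}

#' Simulate a chemical denaturation series
#'
#' Two-state unfolding under the linear extrapolation model
#' `dG(D) = dg0 - m * D`: the fraction unfolded follows
#' `K = exp(-dG/RT)`, `f_u = K/(1+K)`, and the tryptophan emission
#' maximum red-shifts linearly with `f_u` from the folded to the unfolded
#' wavelength.
#'
#' @param dg0 Unfolding free energy at zero denaturant (kcal/mol), > 0.
#' @param m m-value (kcal/mol/M), > 0.
#' @param lam_f,lam_u Folded and unfolded emission maxima (nm),
#'   `lam_u > lam_f`.
#' @param concs Nondecreasing denaturant concentrations (M), nonempty.
#' @param noise_sd Additive Gaussian noise on the wavelength (nm).
#' @param seed Optional seed.
#' @param temp_c Temperature of the experiment (degrees C), default 25.
#'
#' @return An object of class `chem_denat_series` with `conc_M` and
#'   `lambda_max`.
#' @export
simulate_chem_denat <- function(dg0, m, lam_f = 335, lam_u = 355,
                                concs = seq(0, 3.5, by = 0.25),
                                noise_sd = 0, seed = NULL, temp_c = 25) {
  if (dg0 <= 0) stop_input("dg0 must be > 0")
  if (m <= 0) stop_input("m must be > 0")
  if (lam_u <= lam_f) stop_input("lam_u must exceed lam_f")
  if (length(concs) == 0) stop_input("denaturant grid is empty")
  if (any(concs < 0) || any(diff(concs) < 0)) {
    stop_input("denaturant concentrations must be nonnegative and increasing")
  }
  rt <- R_GAS_KCAL * celsius_to_kelvin(temp_c)
  dg <- dg0 - m * concs
  k <- exp(-dg / rt)
  f_u <- k / (1 + k)
  lam <- lam_f + (lam_u - lam_f) * f_u
  if (noise_sd > 0) {
    lam <- lam + with_optional_seed(
      seed, stats::rnorm(length(concs), sd = noise_sd))
  }
  structure(list(conc_M = concs, lambda_max = lam,
                 meta = list(dg0 = dg0, m = m, lam_f = lam_f, lam_u = lam_u,
                             temp_c = temp_c)),
            class = "chem_denat_series")
}

#' Simulate a CD thermal denaturation scan
#'
#' Mean residue ellipticity at 222 nm tracks helix content, so thermal
#' unfolding moves theta222 from the (strongly negative) folded plateau to
#' the unfolded plateau along the two-state van't Hoff fraction.
#'
#' @param tm_c,dh_vh Midpoint (degrees C) and van't Hoff enthalpy
#'   (kcal/mol).
#' @param theta_f,theta_u Folded and unfolded plateaus
#'   (deg cm^2 dmol^-1).
#' @param grid Temperature grid (degrees C).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Optional seed.
#'
#' @return An object of class `cd_thermal_scan` with `temperature` and
#'   `theta222`.
#' @export
simulate_cd_thermal <- function(tm_c, dh_vh, theta_f = -20000,
                                theta_u = -3000,
                                grid = default_temperature_grid(),
                                noise_sd = 0, seed = NULL) {
  if (dh_vh <= 0) stop_input("dh_vh must be > 0")
  f <- vant_hoff_fraction_unfolded(grid, tm_c, dh_vh)
  theta <- theta_f + (theta_u - theta_f) * f
  if (noise_sd > 0) {
    theta <- theta + with_optional_seed(
      seed, stats::rnorm(length(grid), sd = noise_sd))
  }
  structure(list(temperature = grid, theta222 = theta,
                 meta = list(tm_c = tm_c, dh_vh = dh_vh)),
            class = "cd_thermal_scan")
}

#' Simulate an apparent-Tm dose-response series
#'
#' One-site hyperbolic stabilization: `Tm(c) = tm0 + dtm_max * c / (ec50 + c)`.
#'
#' @param ec50 Half-maximal concentration (mM), > 0.
#' @param tm0 Apparent Tm without compound (degrees C).
#' @param dtm_max Saturating Tm shift (degrees C).
#' @param concs Nonnegative compound concentrations (mM).
#' @param noise_sd Additive Gaussian noise per replicate Tm measurement
#'   (degrees C).
#' @param reps Replicate measurements per concentration; each reported
#'   point is the replicate mean, as dose-response points are in practice.
#' @param seed Optional seed.
#'
#' @return A tibble with `conc_mM`, `tm_c` (replicate mean), `sd`
#'   (replicate SD; 0 when noiseless).
#' @export
simulate_tm_dose <- function(ec50, tm0 = 47, dtm_max = 18,
                             concs = c(0, 0.05, 0.1, 0.2, 0.5),
                             noise_sd = 0, reps = 3, seed = NULL) {
  if (ec50 <= 0) stop_input("ec50 must be > 0")
  if (any(concs < 0)) stop_input("concentrations must be >= 0")
  if (reps < 1) stop_input("reps must be >= 1")
  tm_true <- tm0 + dtm_max * concs / (ec50 + concs)
  if (noise_sd > 0) {
    noise <- with_optional_seed(
      seed, matrix(stats::rnorm(length(concs) * reps, sd = noise_sd),
                   nrow = length(concs)))
    obs <- tm_true + noise
    tm <- rowMeans(obs)
    sds <- apply(obs, 1, stats::sd)
    if (reps == 1) sds <- rep(noise_sd, length(concs))
  } else {
    tm <- tm_true
    sds <- rep(0, length(concs))
  }
  tibble::tibble(conc_mM = concs, tm_c = tm, sd = sds)
}

#' Cumulative ligand concentration in an ITC cell
#'
#' Perfusion (constant-volume overflow) bookkeeping: each injection of
#' volume `v` into a cell of volume `V` adds `C*v/V` of ligand and the
#' whole cell content (including the fresh aliquot) is attenuated by
#' `(1 - v/V)` to account for the displaced overflow:
#' `c_i = (c_{i-1} + C*v/V) * (1 - v/V)`.
#'
#' @param inj_vol_ul Per-injection volumes (ul); a scalar is recycled with
#'   `n_inj`.
#' @param cell_vol_ul Cell volume (ul).
#' @param syringe_conc_mM Syringe ligand concentration (mM).
#' @param n_inj Number of injections when `inj_vol_ul` is scalar.
#'
#' @return Numeric vector of post-injection cell ligand concentrations (mM).
#' @export
itc_ligand_conc <- function(inj_vol_ul, cell_vol_ul, syringe_conc_mM,
                            n_inj = length(inj_vol_ul)) {
  if (length(inj_vol_ul) == 1) inj_vol_ul <- rep(inj_vol_ul, n_inj)
  conc <- numeric(length(inj_vol_ul))
  c_prev <- 0
  for (i in seq_along(inj_vol_ul)) {
    frac <- inj_vol_ul[i] / cell_vol_ul
    c_prev <- (c_prev + syringe_conc_mM * frac) * (1 - frac)
    conc[i] <- c_prev
  }
  conc
}

#' Simulate an isothermal titration calorimetry experiment
#'
#' Sequential small-volume injections of ligand into the protein cell;
#' the cumulative heat follows a one-site hyperbola
#' `Q(c) = q_max * c / (ec50 + c)` in the post-injection ligand
#' concentration, so each raw per-injection heat is the increment of `Q`
#' plus a constant heat of dilution plus noise. A paired blank experiment
#' (drug into buffer) with an identical schedule carries the dilution term
#' only.
#'
#' @param ec50 Half-saturation ligand concentration (mM), > 0.
#' @param q_max Saturating cumulative heat (instrument units).
#' @param syringe_conc_mM Syringe ligand concentration (mM), > 0.
#' @param cell_conc_uM Protein concentration in the cell (uM), > 0.
#' @param cell_vol_ul Cell volume (ul), > 0.
#' @param inj_vol_ul Per-injection volume (ul), > 0.
#' @param n_inj Number of injections, > 0.
#' @param dilution_heat Constant per-injection heat of dilution.
#' @param noise_sd Gaussian noise SD on per-injection heats.
#' @param seed Optional seed.
#'
#' @return An object of class `itc_experiment`: injection schedule, raw
#'   per-injection `heats`, matching `blank_heats`, and geometry fields.
#' @export
simulate_itc <- function(ec50, q_max, syringe_conc_mM, cell_conc_uM = 10,
                         cell_vol_ul = 350, inj_vol_ul = 1, n_inj = 50,
                         dilution_heat = -2, noise_sd = 0, seed = NULL) {
  if (ec50 <= 0 || syringe_conc_mM <= 0 || cell_conc_uM <= 0 ||
      cell_vol_ul <= 0 || inj_vol_ul <= 0 || n_inj <= 0) {
    stop_input("all ITC concentrations, volumes and n_inj must be positive")
  }
  conc <- itc_ligand_conc(inj_vol_ul, cell_vol_ul, syringe_conc_mM,
                          n_inj = n_inj)
  q_cum <- q_max * conc / (ec50 + conc)
  dq <- diff(c(0, q_cum))
  noise <- if (noise_sd > 0) {
    with_optional_seed(seed, stats::rnorm(2L * n_inj, sd = noise_sd))
  } else rep(0, 2L * n_inj)
  heats <- dq + dilution_heat + noise[seq_len(n_inj)]
  blank <- dilution_heat + noise[n_inj + seq_len(n_inj)]
  structure(
    list(cell_vol_ul = cell_vol_ul, cell_conc_uM = cell_conc_uM,
         syringe_conc_mM = syringe_conc_mM,
         inj_vol_ul = rep(inj_vol_ul, n_inj), heats = heats,
         blank_heats = blank,
         meta = list(ec50 = ec50, q_max = q_max,
                     dilution_heat = dilution_heat)),
    class = "itc_experiment"
  )
}

#' Simulate a viability plate
#'
#' Formazan absorbance at 550 nm proportional to the surviving cell
#' fraction, normalized later against untreated control wells.
#'
#' @param dose_effect Tibble/data.frame with `compound`, `conc_mM`, and
#'   `surviving_frac` in 0-1.
#' @param control_abs Mean absorbance of untreated control wells.
#' @param reps Replicates per condition (>= 2).
#' @param noise_sd Additive Gaussian noise SD on absorbance.
#' @param seed Optional seed.
#'
#' @return A tibble of wells: `compound`, `conc_mM`, `replicate`,
#'   `absorbance`, `is_control`; control rows carry `compound = "control"`.
#' @export
simulate_viability <- function(dose_effect, control_abs = 1.0, reps = 3,
                               noise_sd = 0, seed = NULL) {
  dose_effect <- tibble::as_tibble(dose_effect)
  stopifnot(all(c("compound", "conc_mM", "surviving_frac") %in%
                  names(dose_effect)))
  if (any(dose_effect$surviving_frac < 0 | dose_effect$surviving_frac > 1)) {
    stop_input("surviving fractions must lie in [0, 1]")
  }
  if (reps < 2) stop_input("need >= 2 replicates")
  rows <- dplyr::bind_rows(
    tibble::tibble(compound = "control", conc_mM = 0,
                   surviving_frac = 1, is_control = TRUE),
    dplyr::mutate(dose_effect, is_control = FALSE)
  )
  out <- rows[rep(seq_len(nrow(rows)), each = reps), ]
  out$replicate <- rep(seq_len(reps), nrow(rows))
  out$absorbance <- control_abs * out$surviving_frac
  if (noise_sd > 0) {
    out$absorbance <- out$absorbance + with_optional_seed(
      seed, stats::rnorm(nrow(out), sd = noise_sd))
  }
  tibble::as_tibble(out[, c("compound", "conc_mM", "replicate",
                            "absorbance", "is_control")])
}

#' Simulate a cholesterol efflux table
#'
#' Partitions a fixed total radiolabel (cpm) into medium and cells per
#' condition according to the condition's efflux fraction; noise perturbs
#' the fraction, never the conserved total.
#'
#' @param effects Tibble/data.frame with `protein`, `compound`, `conc_mM`,
#'   `camp` (logical), and `efflux_frac` in 0-1.
#' @param total_cpm Total counts per replicate, > 0.
#' @param reps Replicates per condition.
#' @param noise_sd Gaussian SD on the efflux fraction (absolute).
#' @param seed Optional seed.
#'
#' @return A tibble with one row per replicate: condition columns plus
#'   `replicate`, `cpm_medium`, `cpm_cells`.
#' @export
simulate_efflux <- function(effects, total_cpm = 2e5, reps = 3,
                            noise_sd = 0, seed = NULL) {
  effects <- tibble::as_tibble(effects)
  stopifnot(all(c("protein", "compound", "conc_mM", "camp", "efflux_frac")
                %in% names(effects)))
  if (total_cpm <= 0) stop_input("total_cpm must be positive")
  if (any(effects$efflux_frac < 0 | effects$efflux_frac > 1)) {
    stop_input("efflux fractions must lie in [0, 1]")
  }
  out <- effects[rep(seq_len(nrow(effects)), each = reps), ]
  out$replicate <- rep(seq_len(reps), nrow(effects))
  frac <- out$efflux_frac
  if (noise_sd > 0) {
    frac <- frac + with_optional_seed(
      seed, stats::rnorm(nrow(out), sd = noise_sd))
    frac <- pmin(pmax(frac, 0), 1)
  }
  out$cpm_medium <- total_cpm * frac
  out$cpm_cells <- total_cpm - out$cpm_medium
  tibble::as_tibble(out[, c("protein", "compound", "conc_mM", "camp",
                            "replicate", "cpm_medium", "cpm_cells")])
}
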