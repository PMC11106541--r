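#' Pipeline run configuration
#'
#' Bundles the scenario, thresholds, stage toggles and seed that fully
#' determine a pipeline run (and therefore every output byte).
#'
#' @param scenario A [screen_scenario()]; the packaged default reproduces
#'   the full campaign.
#' @param criteria [hit_criteria()] for the primary screen.
#' @param alpha Significance level of the ANS ratio test.
#' @param stages Character subset of
#'   `c("screen", "ans", "validate", "cells")`, executed in this order;
#'   each stage needs its predecessor's output.
#' @param seed Optional integer overriding the scenario seed.
#' @param smooth_window,smooth_order Savitzky-Golay settings for Tm calling.
#' @param viability_min Minimum percent viability (at a candidate's
#'   optimal corrective concentration) for validation.
#' @param outdir Optional output directory for [write_report()].
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = paper_default_scenario(),
                       criteria = hit_criteria(), alpha = 0.01,
                       stages = c("screen", "ans", "validate", "cells"),
                       seed = NULL, smooth_window = 7, smooth_order = 2,
                       viability_min = 70, outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "screen_scenario"))
    if (!is.null(seed)) scenario$seed <- as.integer(seed)
  }
  structure(
    list(scenario = scenario, criteria = criteria, alpha = alpha,
         stages = stages, smooth_window = smooth_window,
         smooth_order = smooth_order, viability_min = viability_min,
         outdir = outdir),
    class = "run_config")
}

ans_noise_sd <- function(ans) ans$noise_frac * ans$amp

# ANS orthogonal screen over the TSA hits: replicate WT/mutant spectra
# with and without each compound; corrector compounds pull the mutant's
# hydrophobic exposure back to WT.
run_ans_stage <- function(hit_ids, scenario, alpha) {
  ans <- scenario$assays$ans
  sd <- ans_noise_sd(ans)
  base_seed <- scenario$seed + 300000L
  spec <- function(exposure, seed) {
    simulate_ans_spectrum(exposure, peak_nm = ans$peak_nm,
                          grid_nm = ans$grid_nm, width_nm = ans$width_nm,
                          amp = ans$amp, noise_sd = sd, seed = seed)
  }
  control_ratios <- vapply(seq_len(ans$reps), function(r) {
    w <- ans_peak(spec(ans$wt_exposure, base_seed + r))
    m <- ans_peak(spec(ans$mut_exposure, base_seed + 100L + r))
    w$peak_intensity / m$peak_intensity
  }, numeric(1))
  rows <- lapply(seq_along(hit_ids), function(i) {
    id <- hit_ids[i]
    cand <- scenario$candidates[[id]]
    corr <- isTRUE(cand$ans_corrector)
    mut_exp <- if (corr) ans$corrected_exposure else ans$mut_exposure
    off <- base_seed + 1000L * i
    wt_reps <- lapply(seq_len(ans$reps), function(r) {
      spec(ans$wt_exposure, off + r)
    })
    mut_reps <- lapply(seq_len(ans$reps), function(r) {
      spec(mut_exp, off + 500L + r)
    })
    res <- ans_ratio_test(wt_reps, mut_reps, control_ratios, alpha = alpha)
    tibble::tibble(id = id, name = cand$name %||% NA_character_,
                   ratio = res$ratio, p_value = res$p_value,
                   pass = isTRUE(res$pass))
  })
  dplyr::bind_rows(rows)
}

# Dose-response + viability validation of the ANS-confirmed candidates:
# a candidate survives if its fitted saturating Tm stabilization reaches
# the hit threshold and macrophages stay viable at the lowest
# concentration that achieves that threshold.
run_validate_stage <- function(candidate_ids, scenario, criteria,
                               viability_min) {
  assays <- scenario$assays
  base_seed <- scenario$seed + 400000L
  rows <- lapply(seq_along(candidate_ids), function(i) {
    id <- candidate_ids[i]
    cand <- scenario$candidates[[id]]
    if (is.null(cand)) {
      return(tibble::tibble(
        id = id, name = NA_character_, ec50_mM = NA_real_,
        dtm_max = NA_real_, optimal_conc_mM = NA_real_,
        viability_pct = NA_real_, stabilizes = FALSE, viable = FALSE,
        validated = FALSE))
    }
    dose <- simulate_tm_dose(
      ec50 = cand$tm_dose$ec50, tm0 = scenario$mutant$tm_c,
      dtm_max = cand$tm_dose$dtm_max, concs = assays$dose_concs_mM,
      noise_sd = 0, seed = base_seed + i)
    fit <- fit_tm_dose(dose)
    stabilizes <- fit$converged && is.finite(fit$amplitude) &&
      fit$amplitude >= criteria$min_shift
    opt <- NA_real_
    if (stabilizes) {
      shift <- fit$amplitude * assays$dose_concs_mM /
        (fit$ec50 + assays$dose_concs_mM)
      ok <- assays$dose_concs_mM[shift >= criteria$min_shift &
                                   assays$dose_concs_mM > 0]
      if (length(ok) > 0) opt <- min(ok)
    }
    viab_pct <- NA_real_
    viable <- FALSE
    if (!is.na(opt)) {
      de <- tibble::tibble(compound = id,
                           conc_mM = assays$viability_concs_mM,
                           surviving_frac = unlist(cand$viability))
      plate <- simulate_viability(
        de, control_abs = assays$viability$control_abs,
        reps = assays$viability$reps, noise_sd = assays$viability$noise_sd,
        seed = base_seed + 100L + i)
      summ <- viability_summary(plate)
      j <- which.min(abs(summ$conc_mM - opt))
      viab_pct <- summ$percent[j]
      viable <- viab_pct >= viability_min
    }
    tibble::tibble(
      id = id, name = cand$name %||% NA_character_,
      ec50_mM = if (fit$converged) fit$ec50 else NA_real_,
      dtm_max = if (fit$converged) fit$amplitude else NA_real_,
      optimal_conc_mM = opt, viability_pct = viab_pct,
      stabilizes = stabilizes, viable = viable,
      validated = stabilizes && viable)
  })
  dplyr::bind_rows(rows)
}

# Cholesterol-efflux functional assay: WT, mutant, and mutant plus each
# validated corrector at its optimal concentration, +/- cAMP.
run_cells_stage <- function(validated, scenario) {
  ef <- scenario$assays$efflux
  mut_net <- ef$basal_frac + ef$mutant_net_ratio * ef$wt_net_frac
  wt_net <- ef$basal_frac + ef$wt_net_frac
  conds <- tibble::tibble(
    protein = c("WT", "L178P"), compound = NA_character_,
    conc_mM = NA_real_, plus_frac = c(wt_net, mut_net))
  if (nrow(validated) > 0) {
    v <- validated[validated$validated, ]
    if (nrow(v) > 0) {
      restored <- vapply(v$id, function(id) {
        isTRUE(scenario$candidates[[id]]$efflux_restores)
      }, logical(1))
      conds <- dplyr::bind_rows(conds, tibble::tibble(
        protein = "L178P", compound = v$id, conc_mM = v$optimal_conc_mM,
        plus_frac = ifelse(restored, wt_net, mut_net)))
    }
  }
  effects <- dplyr::bind_rows(
    dplyr::mutate(conds, camp = TRUE, efflux_frac = .data$plus_frac),
    dplyr::mutate(conds, camp = FALSE, efflux_frac = ef$basal_frac))
  effects$plus_frac <- NULL
  tab <- simulate_efflux(effects, total_cpm = ef$total_cpm, reps = ef$reps,
                         noise_sd = ef$noise_sd,
                         seed = scenario$seed + 450000L)
  key <- function(x) paste(x$protein, x$compound, x$conc_mM)
  net_rep <- function(rows) {
    plus <- rows[rows$camp, ]
    minus <- rows[!rows$camp, ]
    efflux_percent(plus$cpm_medium, plus$cpm_cells) -
      efflux_percent(minus$cpm_medium, minus$cpm_cells)
  }
  conds$k <- key(conds)
  tab$k <- key(tab)
  wt_nets <- net_rep(tab[tab$k == conds$k[1], ])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sub <- tab[tab$k == conds$k[i], ]
    net <- net_abca1_efflux(sub[sub$camp, setdiff(names(sub), "k")],
                            sub[!sub$camp, setdiff(names(sub), "k")])
    cmp <- compare_groups(net_rep(sub), wt_nets, labels = c(conds$k[i], "WT"))
    tibble::tibble(protein = conds$protein[i], compound = conds$compound[i],
                   conc_mM = conds$conc_mM[i], net_percent = net$net_percent,
                   sd = net$sd, p_vs_wt = cmp$p_value, tier = cmp$tier)
  })
  dplyr::bind_rows(rows)
}

#' Run the full structure-corrector pipeline
#'
#' Executes the enabled stages in campaign order -- primary thermal-shift
#' screen, ANS-ratio orthogonal screen of the hits, dose-response plus
#' viability validation of the ANS-confirmed candidates, and the
#' cholesterol-efflux functional assay of the validated correctors -- and
#' assembles the per-stage tables, the selection funnel, and a manifest
#' sufficient to reproduce every table.
#'
#' @param config A [run_config()].
#'
#' @return An object of class `report_bundle`: `tables` (named list of
#'   tibbles), `funnel` (tibble of stage counts), `manifest`, `failures`
#'   (named list of stage error messages, empty on success), `summary`
#'   (character lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scenario <- config$scenario
  tables <- list()
  failures <- list()
  funnel <- tibble::tibble(stage = character(0), count = integer(0))
  add_funnel <- function(stage, count) {
    funnel <<- dplyr::bind_rows(funnel,
                                tibble::tibble(stage = stage,
                                               count = as.integer(count)))
  }
  hit_ids <- NULL
  if ("screen" %in% config$stages) {
    res <- tryCatch({
      if (is.null(scenario)) stop("no scenario or screen input supplied")
      screen <- simulate_screen(scenario)
      calls <- call_wells(screen, window = config$smooth_window,
                          order = config$smooth_order,
                          criteria = config$criteria)
      select_hits(calls$wells, calls$wt_ref, calls$mut_ref, config$criteria)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures$screen <- conditionMessage(res)
    } else {
      tables$screen <- res
      hit_ids <- res$id[res$hit]
      add_funnel("screened", nrow(res))
      add_funnel("tsa_hits", length(hit_ids))
    }
  }
  ans_pass <- NULL
  if ("ans" %in% config$stages) {
    if (is.null(hit_ids)) {
      failures$ans <- "screen stage output unavailable"
    } else {
      res <- tryCatch(run_ans_stage(hit_ids, scenario, config$alpha),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures$ans <- conditionMessage(res)
      } else {
        tables$ans <- res
        ans_pass <- res$id[res$pass]
        add_funnel("ans_confirmed", length(ans_pass))
      }
    }
  }
  validated <- NULL
  if ("validate" %in% config$stages) {
    if (is.null(ans_pass)) {
      failures$validate <- "ans stage output unavailable"
    } else {
      res <- tryCatch(
        run_validate_stage(ans_pass, scenario, config$criteria,
                           config$viability_min),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures$validate <- conditionMessage(res)
      } else {
        tables$validation <- res
        validated <- res
        add_funnel("validated", sum(res$validated))
      }
    }
  }
  if ("cells" %in% config$stages) {
    if (is.null(validated)) {
      failures$cells <- "validation stage output unavailable"
    } else {
      res <- tryCatch(run_cells_stage(validated, scenario),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures$cells <- conditionMessage(res)
      } else {
        tables$efflux <- res
      }
    }
  }
  manifest <- list(
    package = "apoastab",
    version = as.character(utils::packageVersion("apoastab")),
    seed = if (is.null(scenario)) NA_integer_ else scenario$seed,
    stages = config$stages,
    config_hash = rlang::hash(config),
    failures = names(failures))
  summary_lines <- c(
    "Structure-corrector screening funnel:",
    sprintf("  %-14s %d", funnel$stage, funnel$count),
    if (length(failures) > 0) {
      sprintf("FAILED stage '%s': %s", names(failures),
              unlist(failures, use.names = FALSE))
    })
  structure(list(tables = tables, funnel = funnel, manifest = manifest,
                 failures = failures, summary = summary_lines),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(paste(x$summary, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One TSV per stage table, the funnel table, a JSON manifest, and a
#' plain-text summary; stable column order, UTF-8, LF line endings, so
#' rewriting the same bundle is byte-identical.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0) {
    stop_input("output directory '%s' is not writable", outdir)
  }
  for (nm in names(bundle$tables)) {
    readr::write_tsv(bundle$tables[[nm]],
                     file.path(outdir, paste0(nm, ".tsv")), eol = "\n")
  }
  if (nrow(bundle$funnel) > 0) {
    readr::write_tsv(bundle$funnel, file.path(outdir, "funnel.tsv"),
                     eol = "\n")
  }
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(bundle$summary, file.path(outdir, "summary.txt"))
  invisible(outdir)
}
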