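#' Hit-selection thresholds for the primary screen
#'
#' A well is a hit when the compound makes the mutant melt like the WT
#' reference: a large enough Tm shift over the mutant-alone reference, a
#' small enough gap to the WT Tm, a similar normalized curve shape, and no
#' compound-alone interference.
#'
#' @param min_shift Minimum Tm(mutant+compound) - Tm(mutant) (degrees C).
#' @param max_wt_gap Maximum |Tm(mutant+compound) - Tm(WT)| (degrees C).
#' @param max_curve_rmsd Maximum RMSD between min-max-normalized sample and
#'   WT curves (fraction of normalized range).
#' @param interference_ratio Wells whose compound-alone dynamic range
#'   exceeds this fraction of the sample-well dynamic range are excluded.
#' @param flat_frac Sample wells with fluorescence dynamic range below this
#'   fraction of the plate-set median are no-calls (flat curves).
#'
#' @return An object of class `hit_criteria`.
#' @export
hit_criteria <- function(min_shift = 5, max_wt_gap = 5,
                         max_curve_rmsd = 0.10, interference_ratio = 0.5,
                         flat_frac = 0.05) {
  vals <- c(min_shift, max_wt_gap, max_curve_rmsd, interference_ratio,
            flat_frac)
  if (any(vals <= 0)) stop_input("all hit-criteria thresholds must be > 0")
  structure(list(min_shift = min_shift, max_wt_gap = max_wt_gap,
                 max_curve_rmsd = max_curve_rmsd,
                 interference_ratio = interference_ratio,
                 flat_frac = flat_frac),
            class = "hit_criteria")
}

#' RMSD between min-max normalized melt curves
#'
#' Both curves are restricted to their common temperature range (the
#' second interpolated onto the first's grid), min-max normalized to
#' \[0, 1\], and compared by root-mean-square difference. The measure is
#' invariant to vertical affine transforms of either curve, so it compares
#' shape, not signal magnitude.
#'
#' @param curve_a,curve_b [melt_curve()] objects with overlapping
#'   temperature ranges.
#'
#' @return A nonnegative fraction (0 for identical shapes).
#' @export
normalized_curve_rmsd <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "melt_curve"), inherits(curve_b, "melt_curve"))
  lo <- max(min(curve_a$temperature), min(curve_b$temperature))
  hi <- min(max(curve_a$temperature), max(curve_b$temperature))
  if (lo >= hi) stop_input("curves have no overlapping temperature range")
  keep <- curve_a$temperature >= lo & curve_a$temperature <= hi
  ta <- curve_a$temperature[keep]
  fa <- curve_a$fluorescence[keep]
  fb <- stats::approx(curve_b$temperature, curve_b$fluorescence,
                      xout = ta)$y
  norm01 <- function(x) {
    r <- diff(range(x))
    if (r == 0) rep(0.5, length(x)) else (x - min(x)) / r
  }
  sqrt(mean((norm01(fa) - norm01(fb))^2))
}

#' Call Tm on every well of a simulated or ingested screen
#'
#' Smooths and differentiates each sample well, calls the apparent Tm, and
#' attaches the dynamic-range bookkeeping the hit criteria need: each
#' well's fluorescence range, its compound-alone range, and a plate-set
#' flatness threshold (wells below `flat_frac` of the median sample range
#' are no-calls, so compound-only or dye-only wells never yield a Tm).
#'
#' @param screen A `screen_set` from [simulate_screen()], or a list with
#'   `roster`, `curves`, `compound_alone`, `wt_ref`, `mut_ref`.
#' @param window,order Savitzky-Golay settings (see [smooth_curve()]).
#' @param criteria A [hit_criteria()] (supplies `flat_frac`).
#'
#' @return A list: `wells` (tibble of per-well calls with list-column
#'   `curve`), `wt_ref` and `mut_ref` (each a list with `tm` and `curve`).
#' @export
call_wells <- function(screen, window = 7, order = 2,
                       criteria = hit_criteria()) {
  roster <- screen$roster
  ranges <- vapply(screen$curves, curve_dynamic_range, numeric(1))
  flat_abs <- criteria$flat_frac * stats::median(ranges)
  calls <- lapply(seq_len(nrow(roster)), function(i) {
    cur <- screen$curves[[i]]
    if (curve_dynamic_range(cur) < flat_abs) {
      return(list(tm_c = NA_real_, depth = NA_real_, flags = "flat_curve",
                  curve = cur))
    }
    tm <- call_tm(neg_derivative(smooth_curve(cur, window, order)))
    list(tm_c = tm$tm_c, depth = tm$depth, flags = tm$flags, curve = cur)
  })
  wells <- tibble::tibble(
    id = roster$id, name = roster$name, library = roster$library,
    plate = roster$plate, well = roster$well, conc_mM = roster$conc_mM,
    tm_c = vapply(calls, function(x) x$tm_c, numeric(1)),
    depth = vapply(calls, function(x) x$depth, numeric(1)),
    flags = vapply(calls, function(x) paste(x$flags, collapse = ","), ""),
    dyn_range = unname(ranges),
    alone_range = unname(vapply(screen$compound_alone, curve_dynamic_range,
                                numeric(1))[roster$id]),
    curve = lapply(calls, function(x) x$curve)
  )
  ref_call <- function(curve) {
    list(tm = call_tm(neg_derivative(smooth_curve(curve, window, order))),
         curve = curve)
  }
  list(wells = wells,
       wt_ref = ref_call(screen$wt_ref[[1]]),
       mut_ref = ref_call(screen$mut_ref[[1]]))
}

#' Select primary-screen hits
#'
#' Applies the full [hit_criteria()] rule to per-well Tm calls: Tm shift
#' over the mutant reference, gap to the WT reference, normalized
#' curve-shape RMSD against the WT curve, and compound-alone interference.
#' No-call wells are never hits; the `reason` column records why each
#' non-hit failed. Deterministic and independent of well order.
#'
#' @param wells Per-well tibble from [call_wells()] (columns `tm_c`,
#'   `dyn_range`, `alone_range`, list-column `curve`).
#' @param wt_ref,mut_ref Reference calls, each a list with `tm` (a
#'   `tm_call`) and `curve` (a [melt_curve()]).
#' @param criteria A [hit_criteria()].
#'
#' @return The `wells` tibble with added `shift`, `wt_gap`, `rmsd`,
#'   `interference`, `hit`, `reason` columns (curve list-column dropped).
#' @export
select_hits <- function(wells, wt_ref, mut_ref, criteria = hit_criteria()) {
  if (is.null(wt_ref$tm) || is.na(wt_ref$tm$tm_c) ||
      is.null(mut_ref$tm) || is.na(mut_ref$tm$tm_c)) {
    stop_input("valid WT and mutant reference Tm calls are required")
  }
  stopifnot(inherits(criteria, "hit_criteria"))
  wt_tm <- wt_ref$tm$tm_c
  mut_tm <- mut_ref$tm$tm_c
  shift <- wells$tm_c - mut_tm
  wt_gap <- abs(wells$tm_c - wt_tm)
  rmsd <- vapply(wells$curve, normalized_curve_rmsd, numeric(1),
                 curve_b = wt_ref$curve)
  interference <- wells$alone_range >
    criteria$interference_ratio * wells$dyn_range
  called <- !is.na(wells$tm_c)
  hit <- called & !interference &
    shift >= criteria$min_shift &
    wt_gap <= criteria$max_wt_gap &
    rmsd <= criteria$max_curve_rmsd
  reason <- rep(NA_character_, nrow(wells))
  reason[!called] <- "no_call"
  reason[called & interference] <- "interference"
  reason[called & !interference & shift < criteria$min_shift] <- "small_shift"
  reason[called & !interference & shift >= criteria$min_shift &
           wt_gap > criteria$max_wt_gap] <- "wt_gap"
  reason[called & !interference & shift >= criteria$min_shift &
           wt_gap <= criteria$max_wt_gap &
           rmsd > criteria$max_curve_rmsd] <- "curve_shape"
  out <- wells[, setdiff(names(wells), "curve")]
  out$shift <- shift
  out$wt_gap <- wt_gap
  out$rmsd <- rmsd
  out$interference <- interference
  out$hit <- hit
  out$reason <- reason
  out
}

#' Peak of an ANS emission spectrum
#'
#' Smooths the spectrum (Savitzky-Golay) and returns the wavelength and
#' intensity of its maximum. Spectra with no usable signal are flagged.
#'
#' @param spectrum An `ans_spectrum` from [simulate_ans_spectrum()] or an
#'   equivalent list with `wavelength` (within 425-600 nm) and `intensity`.
#' @param window,order Smoothing settings; smoothing is skipped for
#'   spectra shorter than the window.
#'
#' @return A list: `peak_nm`, `peak_intensity`, `flat` (logical flag).
#' @export
ans_peak <- function(spectrum, window = 7, order = 2) {
  wl <- spectrum$wavelength
  y <- spectrum$intensity
  if (any(wl < 425 | wl > 600)) {
    stop_input("spectrum must lie within 425-600 nm")
  }
  if (length(y) > window) {
    y <- as.numeric(signal::sgolayfilt(y, p = order, n = window))
  }
  if (diff(range(y)) <= .Machine$double.eps^0.5 && max(abs(y)) < 1e-12) {
    return(list(peak_nm = NA_real_, peak_intensity = 0, flat = TRUE))
  }
  i <- which.max(y)
  list(peak_nm = wl[i], peak_intensity = y[i], flat = FALSE)
}

#' ANS fluorescence-ratio significance test
#'
#' The orthogonal screen statistic is the ratio of the WT peak ANS
#' intensity to the mutant peak intensity, each taken at its own peak so
#' the measure tolerates small band shifts. Without a corrector the
#' destabilized mutant binds more probe and the ratio sits below 1; a
#' corrector raises the mutant-bound signal toward WT and the ratio toward
#' 1. Compound ratios are compared to no-compound control ratios by a
#' Welch two-sample t-test; the compound passes if the mean ratio
#' increased and the (two-sided) p-value is below `alpha`.
#'
#' @param wt_reps,mut_reps Lists of replicate spectra (>= 2 each, paired
#'   in order).
#' @param control_ratios Numeric vector of replicate ratios measured
#'   without compound (>= 2).
#' @param alpha Significance level (default 0.01).
#'
#' @return An object of class `ans_ratio_result`: `ratio` (mean), `ratios`,
#'   `p_value`, `pass`, `flagged` (TRUE when replicates were insufficient;
#'   `pass` is then `NA`).
#' @export
ans_ratio_test <- function(wt_reps, mut_reps, control_ratios, alpha = 0.01) {
  if (length(wt_reps) != length(mut_reps)) {
    stop_input("WT and mutant replicate counts differ")
  }
  ratios <- vapply(seq_along(wt_reps), function(i) {
    pw <- ans_peak(wt_reps[[i]])
    pm <- ans_peak(mut_reps[[i]])
    if (pm$peak_intensity <= 0) return(NA_real_)
    pw$peak_intensity / pm$peak_intensity
  }, numeric(1))
  if (length(ratios) < 2 || length(control_ratios) < 2 || anyNA(ratios)) {
    return(structure(list(ratio = mean(ratios), ratios = ratios,
                          p_value = NA_real_, pass = NA, flagged = TRUE),
                     class = "ans_ratio_result"))
  }
  tt <- tryCatch(stats::t.test(ratios, control_ratios, var.equal = FALSE),
                 error = function(e) NULL)
  # zero-variance degenerate case: decide on the means alone
  p <- if (is.null(tt)) {
    if (isTRUE(all.equal(mean(ratios), mean(control_ratios)))) 1 else 0
  } else {
    tt$p.value
  }
  pass <- mean(ratios) > mean(control_ratios) && p < alpha
  structure(list(ratio = mean(ratios), ratios = ratios,
                 p_value = p, pass = pass, flagged = FALSE),
            class = "ans_ratio_result")
}
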