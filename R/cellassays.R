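#' Viability as percent of untreated control
#'
#' `100 * absorbance / mean(control absorbances)` per replicate, summarized
#' as mean +/- SD.
#'
#' @param absorbance Replicate absorbances at 550 nm (>= 2, >= 0).
#' @param control_absorbance Untreated control-well absorbances (mean > 0).
#'
#' @return A list: `percent` (mean), `sd`, `replicates` (per-replicate
#'   percentages).
#' @export
viability_percent <- function(absorbance, control_absorbance) {
  if (length(absorbance) < 2) stop_input("need >= 2 replicates")
  if (any(absorbance < 0) || any(control_absorbance < 0)) {
    stop_input("absorbances must be >= 0")
  }
  ctrl <- mean(control_absorbance)
  if (ctrl <= 0) stop_input("control mean absorbance must be > 0")
  reps <- 100 * absorbance / ctrl
  list(percent = mean(reps), sd = stats::sd(reps), replicates = reps)
}

#' Summarize a viability plate
#'
#' Applies [viability_percent()] to every (compound, concentration)
#' condition of a long plate table against its control wells.
#'
#' @param plate Tibble from [simulate_viability()] or an ingested plate
#'   with columns `compound`, `conc_mM`, `absorbance`, `is_control`.
#'
#' @return A tibble: `compound`, `conc_mM`, `percent`, `sd`, `n`.
#' @export
viability_summary <- function(plate) {
  plate <- tibble::as_tibble(plate)
  ctrl <- plate$absorbance[plate$is_control]
  if (length(ctrl) == 0) stop_input("plate has no control wells")
  treated <- plate[!plate$is_control, ]
  treated |>
    dplyr::group_by(.data$compound, .data$conc_mM) |>
    dplyr::summarise(
      percent = viability_percent(.data$absorbance, ctrl)$percent,
      sd = viability_percent(.data$absorbance, ctrl)$sd,
      n = dplyr::n(), .groups = "drop")
}

#' Percent cholesterol efflux
#'
#' `100 * cpm_medium / (cpm_medium + cpm_cells)`: the fraction of the
#' radiolabel released to the medium. Vectorized; invariant to rescaling
#' both counts.
#'
#' @param cpm_medium,cpm_cells Nonnegative counts with positive totals.
#'
#' @return Percent efflux in 0-100.
#' @export
efflux_percent <- function(cpm_medium, cpm_cells) {
  if (any(cpm_medium < 0) || any(cpm_cells < 0)) {
    stop_input("counts must be >= 0")
  }
  total <- cpm_medium + cpm_cells
  if (any(total <= 0)) stop_input("total counts must be > 0")
  100 * cpm_medium / total
}

check_efflux_table <- function(x, arg) {
  x <- tibble::as_tibble(x)
  need <- c("protein", "compound", "conc_mM", "camp", "cpm_medium",
            "cpm_cells")
  if (!all(need %in% names(x))) {
    stop_input("%s must have columns %s", arg, paste(need, collapse = ", "))
  }
  x
}

#' Net ABCA1-mediated cholesterol efflux
#'
#' The transporter-specific signal is the efflux of cAMP-stimulated cells
#' (ABCA1 upregulated) minus the efflux of unstimulated cells, for one
#' matched condition (same protein, compound, concentration). Replicate
#' SDs combine in quadrature.
#'
#' @param plus_camp,minus_camp Efflux tables (one condition each, as rows
#'   of a [simulate_efflux()] table) with `camp` TRUE and FALSE
#'   respectively and matching metadata.
#'
#' @return A list: `net_percent`, `sd`, plus the condition metadata.
#' @export
net_abca1_efflux <- function(plus_camp, minus_camp) {
  plus_camp <- check_efflux_table(plus_camp, "plus_camp")
  minus_camp <- check_efflux_table(minus_camp, "minus_camp")
  meta_of <- function(x) unique(x[, c("protein", "compound", "conc_mM")])
  mp <- meta_of(plus_camp)
  mm <- meta_of(minus_camp)
  if (nrow(mp) != 1 || nrow(mm) != 1 || !identical(mp, mm)) {
    stop_input("plus/minus cAMP records must describe one matching condition")
  }
  if (!all(plus_camp$camp) || any(minus_camp$camp)) {
    stop_input("camp flags must be TRUE in plus_camp and FALSE in minus_camp")
  }
  ep <- efflux_percent(plus_camp$cpm_medium, plus_camp$cpm_cells)
  em <- efflux_percent(minus_camp$cpm_medium, minus_camp$cpm_cells)
  list(protein = mp$protein, compound = mp$compound, conc_mM = mp$conc_mM,
       net_percent = mean(ep) - mean(em),
       sd = sqrt(stats::sd(ep)^2 + stats::sd(em)^2),
       plus_percent = mean(ep), minus_percent = mean(em))
}

#' Welch comparison of two replicate groups
#'
#' Welch two-sample t-test with significance tiers at the reporting
#' thresholds 0.05 / 0.005 / 0.0001 (one to three stars). Degenerate
#' zero-variance groups are handled without an exception: equal means give
#' p = 1, separated means p = 0.
#'
#' @param a,b Numeric replicate vectors (>= 2 each).
#' @param labels Optional length-2 group labels.
#'
#' @return An object of class `group_comparison`: group means/SDs, `t`,
#'   `p_value`, `tier` (`""`, `"*"`, `"**"`, `"***"`).
#' @export
compare_groups <- function(a, b, labels = c("a", "b")) {
  if (length(a) < 2 || length(b) < 2) stop_input("need >= 2 replicates per group")
  tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    stat <- NA_real_
  } else {
    p <- tt$p.value
    stat <- unname(tt$statistic)
  }
  tier <- if (p < 1e-4) "***" else if (p < 0.005) "**" else if (p < 0.05) "*" else ""
  structure(
    list(labels = labels, mean_a = mean(a), sd_a = stats::sd(a),
         mean_b = mean(b), sd_b = stats::sd(b), t = stat, p_value = p,
         tier = tier),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %.3g +/- %.3g vs %s: %.3g +/- %.3g, p = %.3g %s\n",
              x$labels[1], x$mean_a, x$sd_a, x$labels[2], x$mean_b, x$sd_b,
              x$p_value, x$tier))
  invisible(x)
}
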