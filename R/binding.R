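one_site <- function(c, baseline, amplitude, ec50) {
  baseline + amplitude * c / (ec50 + c)
}

new_binding_fit <- function(ec50 = NA_real_, amplitude = NA_real_,
                            baseline = NA_real_, vcov = NULL,
                            rmse = NA_real_, converged = FALSE,
                            extrapolated = FALSE) {
  structure(list(ec50 = ec50, amplitude = amplitude, baseline = baseline,
                 vcov = vcov, rmse = rmse, converged = converged,
                 extrapolated = extrapolated),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<binding_fit> did not converge\n")
  } else {
    cat(sprintf("<binding_fit> EC50 = %.4g mM, amplitude = %.4g, baseline = %.4g%s\n",
                x$ec50, x$amplitude, x$baseline,
                if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  }
  invisible(x)
}

fit_one_site <- function(conc, y, weights = NULL, fix_baseline = NA) {
  if (diff(range(y)) == 0) return(new_binding_fit())
  amp0 <- y[which.max(conc)] - min(y)
  if (amp0 == 0) amp0 <- diff(range(y))
  half <- min(y) + amp0 / 2
  pos <- conc[conc > 0]
  ec0 <- conc[which.min(abs(y - half))]
  if (!is.finite(ec0) || ec0 <= 0) ec0 <- stats::median(pos)
  dat <- data.frame(conc = conc, y = y)
  w <- weights %||% rep(1, length(y))
  fit <- tryCatch({
    if (is.finite(fix_baseline)) {
      minpack.lm::nlsLM(
        y ~ one_site(conc, fix_baseline, amplitude, ec50), data = dat,
        start = list(amplitude = amp0, ec50 = ec0),
        lower = c(amplitude = -Inf, ec50 = 1e-12), weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(
        y ~ one_site(conc, baseline, amplitude, ec50), data = dat,
        start = list(baseline = min(y), amplitude = amp0, ec50 = ec0),
        lower = c(baseline = -Inf, amplitude = -Inf, ec50 = 1e-12),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(new_binding_fit())
  cf <- as.list(coef(fit))
  ec50 <- cf$ec50
  if (!is.finite(ec50) || ec50 <= 0) return(new_binding_fit())
  new_binding_fit(
    ec50 = ec50, amplitude = cf$amplitude,
    baseline = if (is.finite(fix_baseline)) fix_baseline else cf$baseline,
    vcov = tryCatch(vcov(fit), error = function(e) NULL),
    rmse = sqrt(mean(stats::residuals(fit)^2)), converged = TRUE,
    extrapolated = ec50 > max(conc))
}

#' Fit a one-site binding model to apparent Tm versus concentration
#'
#' `Tm(c) = baseline + amplitude * c / (ec50 + c)` by (optionally
#' weighted) nonlinear least squares. When replicate SDs are present and
#' positive they are used as `1/SD^2` weights.
#'
#' @param series Tibble/data.frame with `conc_mM`, `tm_c`, optional `sd`
#'   (as produced by [simulate_tm_dose()]); >= 4 distinct concentrations.
#' @param fix_baseline Fix the baseline at the `c = 0` response instead of
#'   fitting it (requires a zero-concentration point).
#'
#' @return A `binding_fit` with `ec50` in mM. All-equal responses or a
#'   nonpositive fitted EC50 yield `converged = FALSE`.
#' @export
fit_tm_dose <- function(series, fix_baseline = FALSE) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("conc_mM", "tm_c") %in% names(series)))
  if (length(unique(series$conc_mM)) < 4) {
    stop_input("need >= 4 distinct concentrations")
  }
  if (any(series$conc_mM < 0)) stop_input("concentrations must be >= 0")
  w <- NULL
  if ("sd" %in% names(series) && all(is.finite(series$sd)) &&
      all(series$sd > 0)) {
    w <- 1 / series$sd^2
  }
  fb <- NA_real_
  if (isTRUE(fix_baseline)) {
    i0 <- which(series$conc_mM == 0)
    if (length(i0) == 0) stop_input("fix_baseline requires a c = 0 point")
    fb <- mean(series$tm_c[i0])
  }
  fit_one_site(series$conc_mM, series$tm_c, weights = w, fix_baseline = fb)
}

#' Blank-correct an ITC experiment and rebuild the ligand schedule
#'
#' Subtracts the paired blank (drug-into-buffer) heats injection-for-
#' injection, removing the heat of dilution, and recomputes the
#' post-injection cell ligand concentration with the perfusion
#' displacement-dilution bookkeeping of [itc_ligand_conc()].
#'
#' @param exp An `itc_experiment` from [simulate_itc()] or an equivalent
#'   list (fields `inj_vol_ul`, `heats`, `blank_heats`, `cell_vol_ul`,
#'   `syringe_conc_mM`).
#'
#' @return A tibble: `injection`, `conc_mM`, `dq` (corrected per-injection
#'   heat), `q_cum` (cumulative corrected heat).
#' @export
correct_itc <- function(exp) {
  if (is.null(exp$blank_heats)) stop_input("a paired blank experiment is required")
  if (length(exp$blank_heats) != length(exp$heats)) {
    stop_input("blank schedule (%d injections) does not match sample (%d)",
               length(exp$blank_heats), length(exp$heats))
  }
  conc <- itc_ligand_conc(exp$inj_vol_ul, exp$cell_vol_ul,
                          exp$syringe_conc_mM)
  dq <- exp$heats - exp$blank_heats
  tibble::tibble(injection = seq_along(dq), conc_mM = conc, dq = dq,
                 q_cum = cumsum(dq))
}

#' Fit a one-site binding model to corrected ITC heats
#'
#' The default fits the cumulative corrected heat against the cell ligand
#' concentration, `Q(c) = q_max * c / (ec50 + c)`; the per-injection form
#' fits the heat increments `Q(c_i) - Q(c_{i-1})` instead and serves as an
#' internal cross-check (both recover the same EC50 on noiseless data).
#'
#' @param corrected Tibble from [correct_itc()].
#' @param form `"cumulative"` (default) or `"per_injection"`.
#'
#' @return A `binding_fit`: `ec50` (mM), `amplitude` (= q_max), `baseline`
#'   fixed at 0; `extrapolated` is set when the fitted EC50 exceeds the
#'   maximum ligand concentration reached.
#' @export
fit_itc <- function(corrected, form = c("cumulative", "per_injection")) {
  form <- match.arg(form)
  corrected <- tibble::as_tibble(corrected)
  if (nrow(corrected) < 6) stop_input("need >= 6 injections")
  conc <- corrected$conc_mM
  if (diff(range(corrected$q_cum)) == 0) {
    return(new_binding_fit(amplitude = 0))
  }
  if (form == "cumulative") {
    return(fit_one_site(conc, corrected$q_cum, fix_baseline = 0))
  }
  dat <- data.frame(c1 = conc, c0 = c(0, head(conc, -1)),
                    dq = corrected$dq)
  q0 <- max(abs(corrected$q_cum)) * sign(sum(corrected$dq))
  ec0 <- conc[which.min(abs(abs(corrected$q_cum) - abs(q0) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dq ~ q_max * (c1 / (ec50 + c1) - c0 / (ec50 + c0)), data = dat,
      start = list(q_max = q0, ec50 = max(ec0, 1e-6)),
      lower = c(q_max = -Inf, ec50 = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(new_binding_fit())
  cf <- as.list(coef(fit))
  new_binding_fit(ec50 = cf$ec50, amplitude = cf$q_max, baseline = 0,
                  vcov = tryCatch(vcov(fit), error = function(e) NULL),
                  rmse = sqrt(mean(stats::residuals(fit)^2)),
                  converged = TRUE, extrapolated = cf$ec50 > max(conc))
}
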