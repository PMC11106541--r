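#' Percent alpha-helix from mean residue ellipticity at 222 nm
#'
#' Applies the standard linear calibration
#' `%helix = (-theta222 + 3000) / (36000 + 3000) * 100` and clamps the
#' result into 0-100, flagging values that fell outside.
#'
#' @param theta222 Mean residue ellipticity at 222 nm
#'   (deg cm^2 dmol^-1); finite, vectorized.
#'
#' @return A tibble with `theta222`, `percent_helix`, `clamped`.
#' @export
helicity_from_theta222 <- function(theta222) {
  if (any(!is.finite(theta222))) stop_input("theta222 must be finite")
  raw <- (-theta222 + 3000) / (36000 + 3000) * 100
  clamped <- raw < 0 | raw > 100
  tibble::tibble(theta222 = theta222,
                 percent_helix = pmin(pmax(raw, 0), 100),
                 clamped = clamped)
}

#' Convert observed ellipticity to mean residue ellipticity
#'
#' `[theta] = theta_obs * MRW / (10 * path_cm * conc_mg_ml)`, with the
#' mean residue weight defaulting to 115.4 (243-residue apoA-I).
#'
#' @param theta_obs Observed ellipticity (mdeg).
#' @param conc_mg_ml Protein concentration (mg/ml).
#' @param path_cm Cuvette path length (cm).
#' @param mrw Mean residue weight (g/mol).
#' @return Mean residue ellipticity (deg cm^2 dmol^-1).
#' @export
mean_residue_ellipticity <- function(theta_obs, conc_mg_ml, path_cm = 0.1,
                                     mrw = 115.4) {
  if (conc_mg_ml <= 0 || path_cm <= 0) {
    stop_input("concentration and path length must be positive")
  }
  theta_obs * mrw / (10 * path_cm * conc_mg_ml)
}

boltzmann_model <- function(x, x50, a, y_pre, y_post, m_pre = 0, m_post = 0) {
  f <- 1 / (1 + exp((x50 - x) / a))
  (y_pre + m_pre * x) * (1 - f) + (y_post + m_post * x) * f
}

#' Fit a Boltzmann sigmoid to a two-state transition
#'
#' `y = y_pre + (y_post - y_pre) / (1 + exp((x50 - x)/a))`, optionally
#' with linear pre/post baselines, fit by Levenberg-Marquardt nonlinear
#' least squares. Initialization is taken from the data (midpoint at half
#' dynamic range, width a tenth of the x-range) and is orientation
#' agnostic, so both rising (fluorescence) and falling-magnitude (CD)
#' transitions fit directly.
#'
#' @param x Increasing abscissa (temperature in degrees C, or denaturant
#'   in M), >= 6 points.
#' @param y Observed signal.
#' @param sloped_baselines Fit linear baseline slopes (default FALSE).
#'
#' @return An object of class `two_state_fit`: `x50`, `a` (width, > 0),
#'   `y_pre`, `y_post`, slopes, `vcov`, `rmse`, `converged`,
#'   `extrapolated` (midpoint outside the data range). Non-convergence
#'   yields `converged = FALSE`, never an exception.
#' @export
boltzmann_fit <- function(x, y, sloped_baselines = FALSE) {
  if (length(x) < 6) stop_input("need >= 6 points for a Boltzmann fit")
  if (length(y) != length(x)) stop_input("x and y lengths differ")
  if (any(diff(x) <= 0)) stop_input("x must be strictly increasing")
  k <- max(3L, min(5L, length(x) %/% 4L))
  y_pre0 <- mean(head(y, k))
  y_post0 <- mean(tail(y, k))
  mid <- (y_pre0 + y_post0) / 2
  x50_0 <- x[which.min(abs(y - mid))]
  a0 <- diff(range(x)) / 10
  dat <- data.frame(x = x, y = y)
  fail <- function() {
    structure(list(x50 = NA_real_, a = NA_real_, y_pre = NA_real_,
                   y_post = NA_real_, m_pre = 0, m_post = 0, vcov = NULL,
                   rmse = NA_real_, converged = FALSE, extrapolated = NA,
                   x_range = range(x), sloped_baselines = sloped_baselines),
              class = "two_state_fit")
  }
  fit <- tryCatch({
    if (sloped_baselines) {
      minpack.lm::nlsLM(
        y ~ boltzmann_model(x, x50, a, y_pre, y_post, m_pre, m_post),
        data = dat,
        start = list(x50 = x50_0, a = a0, y_pre = y_pre0, y_post = y_post0,
                     m_pre = 0, m_post = 0),
        lower = c(x50 = -Inf, a = 1e-9, y_pre = -Inf, y_post = -Inf,
                  m_pre = -Inf, m_post = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(
        y ~ boltzmann_model(x, x50, a, y_pre, y_post),
        data = dat,
        start = list(x50 = x50_0, a = a0, y_pre = y_pre0, y_post = y_post0),
        lower = c(x50 = -Inf, a = 1e-9, y_pre = -Inf, y_post = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- as.list(coef(fit))
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  structure(
    list(x50 = cf$x50, a = cf$a, y_pre = cf$y_pre, y_post = cf$y_post,
         m_pre = cf$m_pre %||% 0, m_post = cf$m_post %||% 0, vcov = vc,
         rmse = sqrt(mean(stats::residuals(fit)^2)), converged = TRUE,
         extrapolated = cf$x50 < min(x) || cf$x50 > max(x),
         x_range = range(x), sloped_baselines = sloped_baselines),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<two_state_fit> did not converge\n")
  } else {
    cat(sprintf("<two_state_fit> x50 = %.3f, width = %.3f (rmse %.3g)%s\n",
                x$x50, x$a, x$rmse,
                if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  }
  invisible(x)
}

#' Apparent van't Hoff enthalpy from a thermal Boltzmann fit
#'
#' At the midpoint of a two-state thermal transition
#' `d lnK/dT = 1/a`, so `dH = R * Tm_K^2 / a_K`. This is the apparent
#' (relative) transition enthalpy; it depends only on the midpoint and
#' width in temperature units, not on the signal scale.
#'
#' @param fit A converged [boltzmann_fit()] of a thermal transition with
#'   `x` in degrees C.
#'
#' @return Apparent dH (kcal/mol).
#' @export
vant_hoff_dh <- function(fit) {
  stopifnot(inherits(fit, "two_state_fit"))
  if (!fit$converged) stop_input("cannot derive dH from an unconverged fit")
  if (fit$a <= 0) stop_input("transition width must be positive")
  tm_k <- celsius_to_kelvin(fit$x50)
  R_GAS_KCAL * tm_k^2 / fit$a
}

#' Midpoint of a chemical denaturation series
#'
#' Boltzmann sigmoid fit of the tryptophan emission maximum versus
#' denaturant concentration; the fitted midpoint is D_1/2. Baselines are
#' flat by default (the emission maximum is bounded within the
#' instrument's wavelength window).
#'
#' @param series A `chem_denat_series` from [simulate_chem_denat()] or an
#'   equivalent list with `conc_M` and `lambda_max`.
#' @param sloped_baselines Passed to [boltzmann_fit()].
#'
#' @return A `two_state_fit` whose `x50` is D_1/2 (M).
#' @export
chem_denat_midpoint <- function(series, sloped_baselines = FALSE) {
  boltzmann_fit(series$conc_M, series$lambda_max,
                sloped_baselines = sloped_baselines)
}

#' Unfolding free energy by the linear extrapolation method
#'
#' Per-point fractions unfolded are computed from the fitted transition
#' baselines, converted to equilibrium constants `K = f_u/(1 - f_u)` and
#' free energies `dG(D) = -RT ln K` for points inside the transition
#' window, and a least-squares line `dG = dg0 - m * D` is extrapolated to
#' zero denaturant. The temperature is fixed at 25 degrees C.
#'
#' @param series A `chem_denat_series`.
#' @param fit A converged [boltzmann_fit()] of the same series (e.g. from
#'   [chem_denat_midpoint()]).
#' @param window Fraction-unfolded bounds delimiting the transition region
#'   used for the line fit (default 0.1-0.9).
#' @param temp_c Temperature for `RT` (degrees C).
#'
#' @return An object of class `lem_result`: `dg0` (kcal/mol), `m_value`
#'   (kcal/mol/M), `d_half` (M, the sigmoid midpoint of `fit`, so
#'   `dg0 ~ m_value * d_half` is a genuine consistency check rather than
#'   an identity), `n_points`, `r_squared`.
#' @export
lem_free_energy <- function(series, fit, window = c(0.1, 0.9),
                            temp_c = 25) {
  stopifnot(inherits(fit, "two_state_fit"))
  if (!fit$converged) stop_input("LEM requires a converged transition fit")
  d <- series$conc_M
  pre <- fit$y_pre + fit$m_pre * d
  post <- fit$y_post + fit$m_post * d
  f_u <- (series$lambda_max - pre) / (post - pre)
  keep <- is.finite(f_u) & f_u > window[1] & f_u < window[2]
  if (sum(keep) < 3) {
    stop_input("only %d points inside the f_u window [%.2f, %.2f]; >= 3 required",
               sum(keep), window[1], window[2])
  }
  rt <- R_GAS_KCAL * celsius_to_kelvin(temp_c)
  dg <- -rt * log(f_u[keep] / (1 - f_u[keep]))
  line <- stats::lm(dg ~ d[keep])
  dg0 <- unname(coef(line)[1])
  m_value <- -unname(coef(line)[2])
  if (m_value <= 0) stop_input("fitted m-value is not positive")
  structure(
    list(dg0 = dg0, m_value = m_value, d_half = fit$x50,
         n_points = sum(keep),
         r_squared = summary(line)$r.squared, temp_c = temp_c),
    class = "lem_result")
}

#' @export
print.lem_result <- function(x, ...) {
  cat(sprintf(
    "<lem_result> dG0 = %.3f kcal/mol, m = %.3f kcal/mol/M, D1/2 = %.3f M (%d pts, R2 %.4f)\n",
    x$dg0, x$m_value, x$d_half, x$n_points, x$r_squared))
  invisible(x)
}
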