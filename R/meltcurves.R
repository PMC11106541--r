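#' Construct a melt curve
#'
#' A melt curve is the fluorescence-versus-temperature trace of one well of
#' a differential scanning fluorimetry (thermal shift) experiment: a
#' hydrophobicity-sensitive dye reports protein unfolding as the sample is
#' ramped, so fluorescence rises through the unfolding transition.
#'
#' @param temperature Strictly increasing temperatures (degrees C), >= 5
#'   points.
#' @param fluorescence Fluorescence values (arbitrary units), same length,
#'   no missing values.
#' @param well Well identifier (e.g. "A1").
#' @param protein Protein identifier (e.g. "WT", "L178P"); may be `NA` for
#'   compound-alone wells.
#' @param compound Compound identifier or `NA`.
#' @param conc_mM Compound concentration in mM, or `NA`.
#' @param meta Named list of free-form metadata (generative parameters,
#'   smoothing settings, ...).
#'
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, fluorescence, well = NA_character_,
                       protein = NA_character_, compound = NA_character_,
                       conc_mM = NA_real_, meta = list()) {
  temperature <- as.numeric(temperature)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperature) < 5) {
    stop_input("melt curve needs >= 5 points, got %d", length(temperature))
  }
  if (length(fluorescence) != length(temperature)) {
    stop_input("temperature and fluorescence lengths differ (%d vs %d)",
               length(temperature), length(fluorescence))
  }
  if (anyNA(temperature) || anyNA(fluorescence)) {
    stop_input("melt curve contains missing values")
  }
  if (any(diff(temperature) <= 0)) {
    stop_input("temperatures must be strictly increasing")
  }
  structure(
    list(temperature = temperature, fluorescence = fluorescence,
         well = well, protein = protein, compound = compound,
         conc_mM = conc_mM, meta = meta),
    class = "melt_curve"
  )
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf(
    "<melt_curve> well %s, protein %s, compound %s: %d points, %.1f-%.1f C\n",
    x$well, x$protein, x$compound, length(x$temperature),
    min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' @export
as_tibble.melt_curve <- function(x, ...) {
  tibble::tibble(
    well = x$well, protein = x$protein, compound = x$compound,
    conc_mM = x$conc_mM, temperature_C = x$temperature,
    fluorescence = x$fluorescence
  )
}

curve_dynamic_range <- function(curve) diff(range(curve$fluorescence))

#' Savitzky-Golay smoothing of a melt curve
#'
#' Local-polynomial smoothing of the fluorescence channel prior to
#' differentiation. Polynomial signals of degree `<= order` pass through
#' unchanged, so noiseless two-state fixtures are essentially untouched.
#'
#' @param curve A [melt_curve()].
#' @param window Odd window length >= 3 and < number of points.
#' @param order Polynomial order, `< window`.
#'
#' @return A smoothed `melt_curve`; temperatures unchanged, smoothing
#'   parameters recorded in `meta`.
#' @export
smooth_curve <- function(curve, window = 7, order = 2) {
  stopifnot(inherits(curve, "melt_curve"))
  if (window < 3 || window %% 2 != 1) {
    stop_input("smoothing window must be odd and >= 3, got %s", window)
  }
  if (order >= window) {
    stop_input("polynomial order (%s) must be < window (%s)", order, window)
  }
  if (window >= length(curve$temperature)) {
    stop_input("window (%s) must be shorter than the curve (%d points)",
               window, length(curve$temperature))
  }
  sm <- signal::sgolayfilt(curve$fluorescence, p = order, n = window)
  out <- curve
  out$fluorescence <- as.numeric(sm)
  out$meta$smoothing <- list(window = window, order = order)
  out
}

#' Negative first derivative of a melt curve
#'
#' Central divided differences on interior points and one-sided differences
#' at the endpoints, negated, so the unfolding transition appears as a
#' minimum of -dF/dT at the apparent melting temperature.
#'
#' @param curve A [melt_curve()] with >= 5 points.
#'
#' @return An object of class `deriv_curve` with fields `temperature` and
#'   `neg_dfdt`, same length as the input.
#' @export
neg_derivative <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  t <- curve$temperature
  f <- curve$fluorescence
  n <- length(t)
  if (n < 5) stop_input("need >= 5 points for differentiation")
  if (any(diff(t) == 0)) stop_input("duplicate temperatures are not allowed")
  d <- numeric(n)
  d[1] <- (f[2] - f[1]) / (t[2] - t[1])
  d[n] <- (f[n] - f[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (f[i + 1] - f[i - 1]) / (t[i + 1] - t[i - 1])
  structure(list(temperature = t, neg_dfdt = -d, well = curve$well),
            class = "deriv_curve")
}

# 3-point parabolic refinement of a grid minimum; returns the sub-grid
# abscissa of the vertex (falls back to the grid point when degenerate).
parabolic_vertex <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(x[i])
  x0 <- x[i - 1]; x1 <- x[i]; x2 <- x[i + 1]
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- (x0 - x1) * (x0 - x2) * (x1 - x2)
  a <- (x2 * (y1 - y0) + x1 * (y0 - y2) + x0 * (y2 - y1)) / denom
  b <- (x2^2 * (y0 - y1) + x1^2 * (y2 - y0) + x0^2 * (y1 - y2)) / denom
  if (!is.finite(a) || a <= 0) return(x1)
  v <- -b / (2 * a)
  # keep the vertex inside the bracketing interval
  min(max(v, x0), x2)
}

local_minima_idx <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
}

#' Call the apparent melting temperature from a derivative curve
#'
#' The apparent Tm is the temperature of the global minimum of -dF/dT
#' within a search window, refined below the grid step by a three-point
#' parabola. Quality flags report minima touching the window edge, flat
#' (no-transition) curves, and competing local minima.
#'
#' @param deriv A `deriv_curve` from [neg_derivative()].
#' @param search Length-2 numeric window (degrees C) to search; default
#'   trims 2 degrees C from each end of the data range, where one-sided
#'   differences can fabricate edge minima.
#' @param flat_threshold Minimum dynamic range of -dF/dT (AU per degree C)
#'   required to call a transition; below it the well is a no-call with the
#'   `flat_curve` flag. Plate-level screening sets this from the plate's
#'   median well range.
#' @param multi_frac A second local minimum whose depth is within this
#'   fraction of the global depth raises the `multiple_minima` flag.
#'
#' @return An object of class `tm_call`: `tm_c` (NA for no-call), `depth`
#'   (value of -dF/dT at the minimum), `search`, and character vector
#'   `flags` (subset of `edge_minimum`, `flat_curve`, `multiple_minima`).
#' @export
call_tm <- function(deriv, search = NULL, flat_threshold = 1e-8,
                    multi_frac = 0.1) {
  stopifnot(inherits(deriv, "deriv_curve"))
  t <- deriv$temperature
  y <- deriv$neg_dfdt
  rng <- range(t)
  if (is.null(search)) {
    search <- c(rng[1] + 2, rng[2] - 2)
    if (diff(search) <= 0) search <- rng
  }
  if (search[1] < rng[1] || search[2] > rng[2] || search[1] >= search[2]) {
    stop_input("search window [%.2f, %.2f] must lie inside the data range",
               search[1], search[2])
  }
  keep <- which(t >= search[1] & t <= search[2])
  flags <- character(0)
  if (diff(range(y[keep])) <= flat_threshold) {
    return(structure(list(tm_c = NA_real_, depth = NA_real_, search = search,
                          flags = "flat_curve"), class = "tm_call"))
  }
  i_win <- keep[which.min(y[keep])]
  if (i_win == keep[1] || i_win == keep[length(keep)]) {
    flags <- c(flags, "edge_minimum")
  }
  depth_global <- max(y[keep]) - y[i_win]
  lm_idx <- intersect(local_minima_idx(y), keep)
  lm_idx <- setdiff(lm_idx, i_win)
  if (length(lm_idx) > 0) {
    depths <- max(y[keep]) - y[lm_idx]
    if (any(depths >= (1 - multi_frac) * depth_global)) {
      flags <- c(flags, "multiple_minima")
    }
  }
  tm <- parabolic_vertex(t, y, i_win)
  structure(list(tm_c = tm, depth = y[i_win], search = search, flags = flags),
            class = "tm_call")
}

#' @export
print.tm_call <- function(x, ...) {
  if (is.na(x$tm_c)) {
    cat(sprintf("<tm_call> no call [%s]\n", paste(x$flags, collapse = ",")))
  } else {
    cat(sprintf("<tm_call> Tm = %.1f C (depth %.3g)%s\n", x$tm_c, x$depth,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  }
  invisible(x)
}
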