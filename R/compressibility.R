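#' Compressibility modulus of a monolayer isotherm
#'
#' In-plane elastic stiffness of a Langmuir monolayer,
#' \deqn{C_s^{-1}(\pi) = -A_\pi \left(\frac{d\pi}{dA}\right)_T}
#' where \eqn{A_\pi} is the molecular area at surface pressure \eqn{\pi}.
#' High values correspond to rigid, densely packed films; the value
#' classifies the monolayer phase state (see [classify_phase()]).
#'
#' The derivative \eqn{d\pi/dA} is estimated by a local polynomial
#' (Savitzky--Golay-style) least-squares fit at each sample point, which
#' tolerates measurement noise and non-uniform area spacing; window and
#' order are recorded in the result for reproducibility.
#'
#' @param iso an [isotherm()].
#' @param grid pressure grid (mN/m) on which to report \eqn{C_s^{-1}};
#'   defaults to 200 uniform points over the isotherm's pressure range.
#' @param window odd number of points in the local fit window (default 11).
#' @param order polynomial order of the local fit (default 3).
#' @return A `compressibility_curve`: data frame with columns `pressure`,
#'   `area`, `dpi_dA`, and `Cs_inv` (mN/m), plus a `smoothing` attribute.
#' @examples
#' A <- seq(70, 20, length.out = 101)
#' iso <- isotherm(A, 70 - A)            # linear fixture: Cs^-1(pi) = A
#' cc <- compressibility_modulus(iso)
#' @export
compressibility_modulus <- function(iso, grid = NULL, window = 11L, order = 3L) {
  stopifnot(inherits(iso, "isotherm"))
  # canonical order is decreasing area; differentiate on increasing area
  A <- rev(iso$area)
  p <- rev(iso$pressure)
  dpdA <- local_poly_deriv(A, p, window = window, order = order)
  Cs <- -A * dpdA
  if (is.null(grid)) {
    grid <- seq(min(p), max(p), length.out = 200L)
  }
  grid <- as.numeric(grid)
  pr <- range(p)
  if (min(grid) < pr[1] - 1e-9 || max(grid) > pr[2] + 1e-9) {
    stop("pressure grid outside the isotherm's sampled range")
  }
  area_g <- stats::approx(p, A, xout = grid, ties = mean)$y
  Cs_g <- stats::approx(p, Cs, xout = grid, ties = mean)$y
  d_g <- stats::approx(p, dpdA, xout = grid, ties = mean)$y
  out <- data.frame(pressure = grid, area = area_g, dpi_dA = d_g, Cs_inv = Cs_g)
  structure(out, class = c("compressibility_curve", "data.frame"),
            smoothing = sprintf("local polynomial derivative, window %d, order %d",
                                as.integer(window), as.integer(order)))
}

#' @export
print.compressibility_curve <- function(x, ...) {
  cat(sprintf("<compressibility_curve> %d grid points, Cs^-1 in [%.1f, %.1f] mN/m (%s)\n",
              nrow(x), min(x$Cs_inv, na.rm = TRUE), max(x$Cs_inv, na.rm = TRUE),
              attr(x, "smoothing")))
  invisible(x)
}

#' Default monolayer phase-state thresholds
#'
#' Boundaries (mN/m) of the classical compressibility-modulus convention for
#' monolayer physical states: 0--12.5 gaseous, 12.5--50 liquid-expanded,
#' 50--100 transitional, 100--250 liquid-condensed, above 250 solid.
#' All boundaries are configurable in [classify_phase()].
#'
#' @return Named numeric vector of upper boundaries.
#' @export
phase_thresholds <- function() {
  c(gaseous = 12.5, `liquid-expanded` = 50,
    transitional = 100, `liquid-condensed` = 250)
}

#' Classify monolayer phase state from the compressibility modulus
#'
#' Maps each \eqn{C_s^{-1}} value to a monolayer physical state
#' (gaseous, liquid-expanded, transitional, liquid-condensed, solid) by the
#' configured thresholds. Non-finite values are flagged `unclassified`
#' rather than raising an error.
#'
#' @param curve a `compressibility_curve` from [compressibility_modulus()],
#'   or a bare numeric vector of \eqn{C_s^{-1}} values in mN/m.
#' @param thresholds named upper boundaries as from [phase_thresholds()].
#' @return Data frame with columns `pressure` (if available), `Cs_inv`, and
#'   `phase` (factor); thresholds echoed in attribute `thresholds`.
#' @export
classify_phase <- function(curve, thresholds = phase_thresholds()) {
  if (inherits(curve, "compressibility_curve")) {
    cs <- curve$Cs_inv
    pres <- curve$pressure
  } else {
    cs <- as.numeric(curve)
    pres <- rep(NA_real_, length(cs))
  }
  if (length(thresholds) != 4L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be 4 strictly increasing upper boundaries")
  }
  levs <- c(names(thresholds), "solid", "unclassified")
  lab <- rep("unclassified", length(cs))
  ok <- is.finite(cs)
  lab[ok] <- levs[findInterval(cs[ok], thresholds, left.open = TRUE) + 1L]
  out <- data.frame(pressure = pres, Cs_inv = cs,
                    phase = factor(lab, levels = levs))
  structure(out, thresholds = thresholds)
}

#' Quantitative similarity of two isotherms
#'
#' Compares the molecular areas of two isotherms on a common pressure grid,
#' reporting the root-mean-square and maximum absolute area differences.
#' Symmetric in its arguments; used to quantify claims that one isotherm
#' (e.g. after enzymatic SM-to-CER conversion) matches another mixture's.
#'
#' @param a,b isotherms.
#' @param grid pressure grid (mN/m); defaults to 200 uniform points over the
#'   shared range.
#' @return List with elements `rms` and `max` (Angstrom^2), `n_grid`, and
#'   the per-grid `differences` (area of `a` minus area of `b`).
#' @export
compare_isotherms <- function(a, b, grid = NULL) {
  stopifnot(inherits(a, "isotherm"), inherits(b, "isotherm"))
  if (is.null(grid)) grid <- pressure_grid(a, b)
  da <- as.numeric(area_at_pressure(a, grid)) - as.numeric(area_at_pressure(b, grid))
  list(rms = sqrt(mean(da^2)), max = max(abs(da)),
       n_grid = length(grid), differences = da, pressure = grid)
}
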