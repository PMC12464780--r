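#' Construct a surface pressure--area isotherm
#'
#' An `isotherm` holds an ordered Langmuir \eqn{\pi}--A compression curve:
#' surface pressure \eqn{\pi} in mN/m against molecular area A in
#' Angstrom^2 per molecule, with temperature and mixture-composition
#' metadata. Points are canonicalised to strictly decreasing area:
#' sorted by decreasing area, with exact duplicate areas averaged.
#' Compression/expansion hysteresis branches must be split by the caller
#' before construction.
#'
#' @param area molecular areas in Angstrom^2 per molecule (strictly positive).
#' @param pressure surface pressures in mN/m, same length as `area`.
#' @param temperature temperature in K (metadata).
#' @param composition optional [mixture_spec()] describing the CER/SM mixture.
#' @param label free-text label for reports.
#' @return An object of class `isotherm`: a data frame with columns `area`
#'   and `pressure` plus metadata attributes.
#' @examples
#' iso <- isotherm(area = seq(70, 20, by = -1), pressure = 70 - seq(70, 20, by = -1))
#' area_at_pressure(iso, 20)   # 50 on this linear fixture
#' @export
isotherm <- function(area, pressure, temperature = 298.15,
                     composition = NULL, label = "") {
  area <- as.numeric(area)
  pressure <- as.numeric(pressure)
  if (length(area) != length(pressure)) {
    stop("area and pressure must have the same length")
  }
  if (length(area) < 8L) stop("an isotherm needs at least 8 points")
  if (any(!is.finite(area)) || any(!is.finite(pressure))) {
    stop("non-finite values in isotherm data")
  }
  if (any(area <= 0)) stop("molecular areas must be strictly positive")
  if (!is.null(composition) && !inherits(composition, "mixture_spec")) {
    stop("composition must be a mixture_spec")
  }
  df <- stats::aggregate(pressure ~ area, data = data.frame(area, pressure), FUN = mean)
  df <- df[order(df$area, decreasing = TRUE), , drop = FALSE]
  if (nrow(df) < 8L) stop("fewer than 8 distinct areas after deduplication")
  out <- data.frame(area = df$area, pressure = df$pressure)
  structure(out,
            class = c("isotherm", "data.frame"),
            temperature = as.numeric(temperature),
            composition = composition,
            label = as.character(label))
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("<isotherm> %s: %d points, A in [%.2f, %.2f] A^2, pi in [%.2f, %.2f] mN/m, T = %.2f K\n",
              if (nzchar(attr(x, "label"))) attr(x, "label") else "(unlabelled)",
              nrow(x), min(x$area), max(x$area),
              min(x$pressure), max(x$pressure), attr(x, "temperature")))
  invisible(x)
}

#' Binary CER/SM mixture composition
#'
#' Mole fractions of ceramide (CER) and sphingomyelin (SM) in a binary
#' monolayer. The two fractions must sum to 1.
#'
#' @param fraction_CER mole fraction of CER in \[0, 1\].
#' @param fraction_SM mole fraction of SM; defaults to `1 - fraction_CER`.
#' @return An object of class `mixture_spec`.
#' @examples
#' mixture_spec(0.5)
#' @export
mixture_spec <- function(fraction_CER, fraction_SM = 1 - fraction_CER) {
  fraction_CER <- as.numeric(fraction_CER)
  fraction_SM <- as.numeric(fraction_SM)
  if (length(fraction_CER) != 1L || length(fraction_SM) != 1L ||
      !is.finite(fraction_CER) || !is.finite(fraction_SM)) {
    stop("mole fractions must be finite scalars")
  }
  if (fraction_CER < 0 || fraction_CER > 1 || fraction_SM < 0 || fraction_SM > 1) {
    stop("mole fractions must lie in [0, 1]")
  }
  if (abs(fraction_CER + fraction_SM - 1) > 1e-12) {
    stop("mole fractions must sum to 1 (got ", fraction_CER + fraction_SM, ")")
  }
  structure(list(fraction_CER = fraction_CER, fraction_SM = fraction_SM),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> X_CER = %.4g, X_SM = %.4g\n",
              x$fraction_CER, x$fraction_SM))
  invisible(x)
}

#' Interpolate the molecular area at a target surface pressure
#'
#' Returns the molecular area at `pi_target` by monotone linear
#' interpolation of A against \eqn{\pi}. Requests outside the sampled
#' pressure range raise an error; there is no silent extrapolation.
#'
#' @param iso an [isotherm()].
#' @param pi_target target surface pressure(s) in mN/m.
#' @return Interpolated molecular area(s) in Angstrom^2, with the
#'   interpolation method recorded in attribute `method`.
#' @export
area_at_pressure <- function(iso, pi_target) {
  stopifnot(inherits(iso, "isotherm"))
  pr <- range(iso$pressure)
  bad <- pi_target < pr[1] - 1e-12 | pi_target > pr[2] + 1e-12
  if (any(bad)) {
    stop(sprintf(
      "extrapolation refused: pressure %g mN/m outside sampled range [%g, %g]",
      pi_target[which(bad)[1]], pr[1], pr[2]))
  }
  a <- stats::approx(x = iso$pressure, y = iso$area, xout = pi_target,
                     ties = mean, rule = 1)$y
  structure(a, method = "linear interpolation of A vs pi, ties averaged")
}

# Shared pressure range of several isotherms; errors if empty.
shared_pressure_range <- function(...) {
  isos <- list(...)
  lo <- max(vapply(isos, function(i) min(i$pressure), numeric(1)))
  hi <- min(vapply(isos, function(i) max(i$pressure), numeric(1)))
  if (lo >= hi) stop("isotherm pressure ranges do not overlap")
  c(lo, hi)
}

#' Default common-pressure grid over the shared range of isotherms
#'
#' Multi-isotherm operations compare areas at equal pressure; raw curves
#' never share pressures exactly, so they are interpolated onto an explicit
#' uniform grid over the overlap of their sampled ranges.
#'
#' @param ... isotherms.
#' @param n number of grid points (default 200).
#' @return Strictly increasing pressure grid in mN/m.
#' @export
pressure_grid <- function(..., n = 200L) {
  r <- shared_pressure_range(...)
  seq(r[1], r[2], length.out = n)
}
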