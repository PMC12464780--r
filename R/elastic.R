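#' Elastic constants container
#'
#' Holds the spontaneous bending moment \eqn{K_C c_0} (first z-moment of
#' the lateral pressure profile) and the Gaussian modulus \eqn{\bar K_G}
#' (negative second z-moment), with fixed unit conversions:
#' 1 bar nm^2 = 0.1 pN and 1 bar nm^3 = 1e-22 J (divided by
#' \eqn{k_B T} for thermal units).
#'
#' @param bending_moment_bar_nm2 first moment in bar nm^2 (or NA).
#' @param gaussian_modulus_bar_nm3 negative second moment in bar nm^3 (or NA).
#' @param temperature temperature in K for the \eqn{k_B T} conversion.
#' @param bounds optional [detect_bounds()] result used for the integrals.
#' @return An object of class `elastic_constants`.
#' @export
elastic_constants <- function(bending_moment_bar_nm2 = NA_real_,
                              gaussian_modulus_bar_nm3 = NA_real_,
                              temperature = 303.15, bounds = NULL) {
  stopifnot(temperature > 0)
  structure(list(
    bending_moment_bar_nm2 = bending_moment_bar_nm2,
    bending_moment_pN = bar_nm2_to_pN(bending_moment_bar_nm2),
    gaussian_modulus_bar_nm3 = gaussian_modulus_bar_nm3,
    gaussian_modulus_kBT = bar_nm3_to_kBT(gaussian_modulus_bar_nm3, temperature),
    temperature = temperature,
    bounds = bounds
  ), class = "elastic_constants")
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat("<elastic_constants>\n")
  cat(sprintf("  bending moment K_C*c0 : %.4g bar nm^2 = %.4g pN\n",
              x$bending_moment_bar_nm2, x$bending_moment_pN))
  cat(sprintf("  Gaussian modulus K_G  : %.4g bar nm^3 = %.4g kB*T at %.2f K\n",
              x$gaussian_modulus_bar_nm3, x$gaussian_modulus_kBT, x$temperature))
  invisible(x)
}

# z-moment of LPP over [d_minus, d_plus] by composite trapezoid on the
# native grid, with partial trapezoids at the exact bounds.
lpp_moment <- function(profile, bounds, power) {
  stopifnot(inherits(profile, "lpp_profile"), inherits(bounds, "membrane_bounds"))
  z <- profile$z
  v <- profile$lpp
  a <- bounds$d_minus
  b <- bounds$d_plus
  f <- function(zz) stats::approx(z, v, xout = zz, rule = 2)$y * zz^power
  inner <- z[z > a & z < b]
  nodes <- unique(c(a, inner, b))
  pracma::trapz(nodes, f(nodes))
}

#' Spontaneous bending moment from a lateral pressure profile
#'
#' First z-moment of the centred lateral pressure profile,
#' \deqn{K_C c_0 = \int_{d_-}^{d_+} z\, LPP(z)\, dz,}
#' the membrane's intrinsic drive to curve, computed by composite
#' trapezoid quadrature on the native grid and reported both in bar nm^2
#' and pN.
#'
#' @param profile a centred `lpp_profile` (see [center_midplane()]).
#' @param bounds a [detect_bounds()] result (or explicit bounds from it).
#' @param temperature temperature in K propagated to the result container.
#' @return An [elastic_constants()] with the bending-moment fields set.
#' @export
bending_moment <- function(profile, bounds = detect_bounds(profile),
                           temperature = 303.15) {
  m1 <- lpp_moment(profile, bounds, 1)
  elastic_constants(bending_moment_bar_nm2 = m1, temperature = temperature,
                    bounds = bounds)
}

#' Gaussian (saddle-splay) modulus from a lateral pressure profile
#'
#' Negative second z-moment of the centred lateral pressure profile,
#' \deqn{\bar K_G = -\int_{d_-}^{d_+} z^2\, LPP(z)\, dz,}
#' the energetic cost (or gain) of saddle-like, topology-changing
#' deformations, reported in bar nm^3 and in \eqn{k_B T} at the stated
#' temperature.
#'
#' @inheritParams bending_moment
#' @return An [elastic_constants()] with the Gaussian-modulus fields set.
#' @export
gaussian_modulus <- function(profile, bounds = detect_bounds(profile),
                             temperature = 303.15) {
  m2 <- lpp_moment(profile, bounds, 2)
  elastic_constants(gaussian_modulus_bar_nm3 = -m2, temperature = temperature,
                    bounds = bounds)
}

#' Both elastic constants in one pass
#'
#' @inheritParams bending_moment
#' @return An [elastic_constants()] with both moments set.
#' @export
elastic_constants_from_lpp <- function(profile, bounds = detect_bounds(profile),
                                       temperature = 303.15) {
  elastic_constants(
    bending_moment_bar_nm2 = lpp_moment(profile, bounds, 1),
    gaussian_modulus_bar_nm3 = -lpp_moment(profile, bounds, 2),
    temperature = temperature, bounds = bounds)
}

#' Radius of spontaneous curvature
#'
#' Converts a spontaneous curvature \eqn{C_0} (1/nm) to the radius of the
#' preferred curvature, \eqn{R = 1/|C_0|}, in nm. A flat membrane
#' (\eqn{C_0 = 0}) returns `Inf` as a distinguished value rather than an
#' error.
#'
#' @param c0 spontaneous curvature in 1/nm.
#' @return Radius in nm (`Inf` for a flat membrane).
#' @examples
#' curvature_radius(-0.015)   # 66.67 nm
#' @export
curvature_radius <- function(c0) {
  c0 <- as.numeric(c0)
  r <- 1 / abs(c0)
  r[c0 == 0] <- Inf
  r
}
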