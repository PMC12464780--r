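# Physical constants and fixed unit conversions. Isotherm quantities stay in
# (mN/m, Angstrom^2) end to end; SI enters only in the Gibbs integral and the
# elastic-constant reports.

# N_A * 1e-20 m^2 * 1e-3 N/m  =  J/mol per (A^2 * mN/m) per molecule
.A2_mNm_to_J_mol <- 6.02214076

# 1 bar * nm^2 = 1e5 Pa * 1e-18 m^2 = 1e-13 N = 0.1 pN
.bar_nm2_to_pN <- 0.1

# 1 bar * nm^3 = 1e5 Pa * 1e-27 m^3 = 1e-22 J
.bar_nm3_to_J <- 1e-22

.k_B <- 1.380649e-23   # J/K

# Default simulation temperature (K) used when converting the Gaussian
# modulus to thermal units.
.default_temperature <- 303.15

#' Unit conversions for membrane elastic constants
#'
#' Fixed conversions used throughout the elastic-constant layer:
#' 1 bar nm^2 = 0.1 pN for the bending moment, and
#' 1 bar nm^3 = 1e-22 J for the Gaussian modulus, expressed in units of
#' \eqn{k_B T} at the stated temperature.
#'
#' @param x numeric vector of values to convert.
#' @param temperature temperature in K for thermal-unit conversions.
#' @return numeric vector of converted values.
#' @examples
#' bar_nm2_to_pN(50.13)          # ~5.013 pN
#' bar_nm3_to_kBT(-52.14, 303.15)
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
bar_nm2_to_pN <- function(x) x * .bar_nm2_to_pN

#' @rdname unit-conversions
#' @export
pN_to_bar_nm2 <- function(x) x / .bar_nm2_to_pN

#' @rdname unit-conversions
#' @export
bar_nm3_to_kBT <- function(x, temperature = 303.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  x * .bar_nm3_to_J / (.k_B * temperature)
}

#' @rdname unit-conversions
#' @export
kBT_to_bar_nm3 <- function(x, temperature = 303.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  x * (.k_B * temperature) / .bar_nm3_to_J
}
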