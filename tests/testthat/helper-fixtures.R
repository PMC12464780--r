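# Shared fixture builders. All fixtures are built in code at test time.

# Linear isotherm pi = intercept + slope * A sampled on n uniform areas.
linear_iso <- function(intercept = 70, slope = -1, a_range = c(20, 70),
                       n = 101L, ...) {
  A <- seq(a_range[1], a_range[2], length.out = n)
  isotherm(A, intercept + slope * A, ...)
}

# Hyperbolic isotherm pi * A = const.
hyperbolic_iso <- function(const = 1000, a_range = c(20, 60), n = 201L, ...) {
  A <- seq(a_range[1], a_range[2], length.out = n)
  isotherm(A, const / A, ...)
}

# Single-Gaussian-bump stress model (closed-form moment oracle).
single_bump_model <- function(amplitude = 100, center = 1, width = 0.2,
                              z_range = c(-3, 3), n_points = 512L, ...) {
  stress_field_model(data.frame(amplitude = amplitude, center = center,
                                width = width),
                     z_range = z_range, n_points = n_points, ...)
}

# Gaussian first/second moments about z = 0 (independent closed forms).
gauss_moment1 <- function(a, mu, s) a * s * sqrt(2 * pi) * mu
gauss_moment2 <- function(a, mu, s) a * s * sqrt(2 * pi) * (mu^2 + s^2)

# Dense-trapezoid reference moment of a sampled profile (independent of
# the package's bounded quadrature path).
ref_moment <- function(z, v, power) pracma::trapz(z, z^power * v)
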