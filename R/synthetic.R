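# Synthetic-data generators. Every generator carries an analytically known
# ground truth so downstream analyses can be verified without trough data
# or MD trajectories.

#' Parametric isotherm model
#'
#' Declares a noiseless pi(A) functional form plus an additive Gaussian
#' noise level for sampling synthetic Langmuir isotherms.
#'
#' Forms:
#' * `linear`: pi = c1 + c2 * A (c2 <= 0), `coefficients = c(c1, c2)`.
#' * `hyperbolic`: pi = c / A, `coefficients = c` (c > 0).
#' * `plateau`: piecewise-linear compression curve with a low-slope
#'   phase-transition segment. `coefficients = c(pi_at_Amax, s1, s2, s3,
#'   A_b1, A_b2)` where s1, s2, s3 <= 0 are dpi/dA on the segments
#'   (A > A_b1, A_b2..A_b1, A < A_b2) and A_b1 > A_b2 are the breakpoints;
#'   pi is integrated from A_max downward so it is continuous and
#'   non-increasing in A.
#'
#' @param form `"linear"`, `"hyperbolic"` or `"plateau"`.
#' @param coefficients numeric coefficients for the form (above).
#' @param area_range c(A_min, A_max) in Angstrom^2, A_min < A_max.
#' @param noise_sd surface-pressure noise SD in mN/m (default 0).
#' @param seed integer RNG seed; identical seeds give identical samples.
#' @param n number of sampled points (default 200).
#' @return An object of class `isotherm_model`.
#' @export
isotherm_model <- function(form = c("linear", "hyperbolic", "plateau"),
                           coefficients, area_range, noise_sd = 0,
                           seed = NULL, n = 200L) {
  form <- match.arg(form)
  coefficients <- as.numeric(coefficients)
  area_range <- as.numeric(area_range)
  if (length(area_range) != 2L || area_range[1] >= area_range[2] ||
      area_range[1] <= 0) {
    stop("area_range must be positive and nondegenerate (A_min < A_max)")
  }
  nc <- c(linear = 2L, hyperbolic = 1L, plateau = 6L)[[form]]
  if (length(coefficients) != nc) {
    stop(sprintf("form '%s' needs %d coefficient(s), got %d",
                 form, nc, length(coefficients)))
  }
  if (form == "linear" && coefficients[2] > 0) {
    stop("linear form needs a non-positive slope dpi/dA")
  }
  if (form == "hyperbolic" && coefficients[1] <= 0) {
    stop("hyperbolic form needs a positive constant pi*A")
  }
  if (form == "plateau") {
    if (any(coefficients[2:4] > 0)) stop("plateau slopes must be non-positive")
    if (!(coefficients[5] > coefficients[6])) stop("breakpoints need A_b1 > A_b2")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(form = form, coefficients = coefficients,
                 area_range = area_range, noise_sd = noise_sd,
                 seed = seed, n = as.integer(n)),
            class = "isotherm_model")
}

# Noiseless model pressure at given areas.
eval_isotherm_model <- function(model, A) {
  co <- model$coefficients
  switch(model$form,
    linear = co[1] + co[2] * A,
    hyperbolic = co[1] / A,
    plateau = {
      # integrate the piecewise slope from A_max down to each area:
      # pi(a) = pi0 - sum_k s_k * (overlap of [a, A_max] with segment k)
      A_max <- model$area_range[2]
      b1 <- co[5]; b2 <- co[6]
      L1 <- pmax(0, A_max - pmax(A, b1))
      L2 <- pmax(0, pmin(A_max, b1) - pmax(A, b2))
      L3 <- pmax(0, pmin(A_max, b2) - A)
      co[1] - (co[2] * L1 + co[3] * L2 + co[4] * L3)
    })
}

#' Sample an isotherm from a parametric model
#'
#' Samples the model on a uniform area grid, adds Gaussian pressure noise
#' if configured, and returns an [isotherm()] carrying the model as
#' provenance. The noiseless curve is non-increasing in area and
#' non-negative over the sampled range (validated at generation time).
#'
#' @param model an [isotherm_model()].
#' @param label isotherm label.
#' @param composition optional [mixture_spec()] metadata.
#' @param temperature temperature metadata in K.
#' @return An [isotherm()] with attribute `model`.
#' @examples
#' m <- isotherm_model("linear", c(70, -1), c(20, 70))
#' iso <- gen_isotherm(m)
#' area_at_pressure(iso, 20)   # 50
#' @export
gen_isotherm <- function(model, label = "", composition = NULL,
                         temperature = 298.15) {
  stopifnot(inherits(model, "isotherm_model"))
  A <- seq(model$area_range[1], model$area_range[2], length.out = model$n)
  p0 <- eval_isotherm_model(model, A)
  if (any(diff(p0) > 1e-9)) {
    stop("configuration error: model pressure is not non-increasing in area")
  }
  if (any(p0 < -1e-9)) {
    stop("configuration error: model pressure is negative on the sampled range")
  }
  p <- if (model$noise_sd > 0) {
    with_seed_or_not(model$seed, p0 + stats::rnorm(length(p0), 0, model$noise_sd))
  } else p0
  iso <- isotherm(A, p, temperature = temperature,
                  composition = composition, label = label)
  attr(iso, "model") <- model
  iso
}

#' Binary mixture scenario with a declared excess-area function
#'
#' Declares the non-ideality of a binary CER/SM mixture as an explicit
#' excess-area function of pressure, so that downstream excess-area
#' recovery has an exact ground truth:
#' A_mix(pi) = X_CER A_CER(pi) + X_SM A_SM(pi) + A_exc(pi).
#'
#' @param component_names length-2 labels, first = CER-like component.
#' @param mole_fraction_first mole fraction of the first component in \[0,1\].
#' @param excess_coefficients polynomial coefficients of A_exc(pi) in
#'   increasing degree (Angstrom^2; constant = length 1, linear = 2, ...).
#' @return An object of class `mixture_scenario` with an `excess_fn`
#'   closure.
#' @export
mixture_scenario <- function(component_names = c("CER", "SM"),
                             mole_fraction_first = 0.5,
                             excess_coefficients = 0) {
  if (length(component_names) != 2L) stop("need exactly two component names")
  x <- as.numeric(mole_fraction_first)
  if (x < 0 || x > 1) stop("mole fraction must lie in [0, 1]")
  co <- as.numeric(excess_coefficients)
  if (!all(is.finite(co))) stop("excess coefficients must be finite")
  structure(list(component_names = as.character(component_names),
                 mole_fraction_first = x,
                 excess_coefficients = co,
                 excess_fn = function(p) polyval_inc(co, p)),
            class = "mixture_scenario")
}

#' Generate a pure-pair-plus-mixture isotherm family
#'
#' Returns the two pure-component isotherms and a mixture isotherm
#' constructed so that, at every common pressure, the mixture area equals
#' the mole-fraction-weighted pure areas plus the scenario's declared
#' excess-area function. The mixture is sampled on a uniform pressure grid
#' over the shared pure range, so recovering the declared excess with
#' [excess_area()] is exact up to interpolation.
#'
#' @param pure_first,pure_second [isotherm_model()]s for the pure
#'   components (first = CER-like); their pressure ranges must overlap.
#' @param scenario a [mixture_scenario()].
#' @param n_pressure number of mixture sample pressures (default 200).
#' @return List with isotherms `pure_first`, `pure_second`, `mixture` and
#'   the `scenario`.
#' @export
gen_mixture_family <- function(pure_first, pure_second, scenario,
                               n_pressure = 200L) {
  stopifnot(inherits(pure_first, "isotherm_model"),
            inherits(pure_second, "isotherm_model"),
            inherits(scenario, "mixture_scenario"))
  iso1 <- gen_isotherm(pure_first, label = scenario$component_names[1])
  iso2 <- gen_isotherm(pure_second, label = scenario$component_names[2])
  r <- tryCatch(shared_pressure_range(iso1, iso2),
                error = function(e) stop("configuration error: pure-component pressure ranges do not overlap"))
  grid <- seq(r[1], r[2], length.out = n_pressure)
  x <- scenario$mole_fraction_first
  A1 <- as.numeric(area_at_pressure(iso1, grid))
  A2 <- as.numeric(area_at_pressure(iso2, grid))
  A_mix <- x * A1 + (1 - x) * A2 + scenario$excess_fn(grid)
  spec <- mixture_spec(fraction_CER = x)
  mix <- isotherm(A_mix, grid, composition = spec,
                  label = sprintf("%s/%s %.0f:%.0f", scenario$component_names[1],
                                  scenario$component_names[2], 100 * x, 100 * (1 - x)))
  list(pure_first = iso1, pure_second = iso2, mixture = mix,
       scenario = scenario)
}

#' Gaussian-bump model of a lateral pressure field
#'
#' Declares the lateral-minus-normal stress as a sum of Gaussian bumps
#' amplitude * exp(-(z - center)^2 / (2 width^2)), whose z-moments have
#' closed forms — the exact oracle for the elastic-constant integrals.
#' A realistic leaflet profile is three bumps: positive at the headgroups,
#' negative in the interfacial-tension trough, positive in the chain
#' region.
#'
#' @param bumps data frame or matrix with columns `amplitude` (bar),
#'   `center` (nm), `width` (nm > 0); one row per bump.
#' @param z_range c(z_lo, z_hi) in nm; must span every bump center by at
#'   least 5 widths so truncated moments match the infinite-range closed
#'   forms.
#' @param n_points grid size, at least 16 (default 512).
#' @param noise_sd Gaussian noise SD (bar) added to each stress component.
#' @param seed integer RNG seed.
#' @return An object of class `stress_field_model`.
#' @export
stress_field_model <- function(bumps, z_range, n_points = 512L,
                               noise_sd = 0, seed = NULL) {
  bumps <- as.data.frame(bumps)
  if (!all(c("amplitude", "center", "width") %in% names(bumps))) {
    stop("bumps needs columns amplitude, center, width")
  }
  if (any(bumps$width <= 0)) stop("bump widths must be positive")
  z_range <- as.numeric(z_range)
  if (length(z_range) != 2L || z_range[1] >= z_range[2]) {
    stop("z_range must be nondegenerate")
  }
  n_points <- as.integer(n_points)
  if (n_points < 16L) stop("n_points must be at least 16")
  margin_lo <- bumps$center - 5 * bumps$width
  margin_hi <- bumps$center + 5 * bumps$width
  if (any(margin_lo < z_range[1]) || any(margin_hi > z_range[2])) {
    stop("margin error: z_range must span every bump center by at least 5 widths")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(bumps = bumps, z_range = z_range, n_points = n_points,
                 noise_sd = noise_sd, seed = seed),
            class = "stress_field_model")
}

# Bump-sum evaluation and closed-form moments about z = 0.
eval_bumps <- function(bumps, z) {
  v <- numeric(length(z))
  for (k in seq_len(nrow(bumps))) {
    v <- v + bumps$amplitude[k] *
      exp(-(z - bumps$center[k])^2 / (2 * bumps$width[k]^2))
  }
  v
}

bump_moments <- function(bumps) {
  s2pi <- sqrt(2 * pi)
  mass <- bumps$amplitude * bumps$width * s2pi
  m1 <- sum(mass * bumps$center)
  m2 <- sum(mass * (bumps$center^2 + bumps$width^2))
  c(first = m1, second = m2)
}

#' Generate a stress profile with closed-form elastic-constant ground truth
#'
#' Builds a gridded [stress_profile()] whose lateral-minus-normal
#' combination equals the declared bump sum exactly (noise off): the
#' lateral components carry the bump (Pxx = Pyy = bump, Pzz = 0), so
#' (Pxx + Pyy)/2 - Pzz reproduces the sum. Ground truth is the
#' closed-form first moment (bending moment, bar nm^2) and negative
#' second moment (Gaussian modulus, bar nm^3) of the infinite-range bump
#' sum.
#'
#' @param model a [stress_field_model()].
#' @param temperature temperature in K for the ground-truth container.
#' @return List with `stress` ([stress_profile()]), `truth`
#'   ([elastic_constants()]), and `lpp_true` (the noiseless bump-sum
#'   values on the grid).
#' @examples
#' m <- stress_field_model(data.frame(amplitude = 100, center = 1, width = 0.2),
#'                         z_range = c(-3, 3))
#' gs <- gen_stress_profile(m)
#' gs$truth$bending_moment_pN   # 100*0.2*sqrt(2*pi)*1 * 0.1 ~ 5.013
#' @export
gen_stress_profile <- function(model, temperature = 303.15) {
  stopifnot(inherits(model, "stress_field_model"))
  z <- seq(model$z_range[1], model$z_range[2], length.out = model$n_points)
  bump <- eval_bumps(model$bumps, z)
  Pxx <- bump
  Pyy <- bump
  Pzz <- numeric(length(z))
  if (model$noise_sd > 0) {
    noise <- with_seed_or_not(model$seed,
      matrix(stats::rnorm(3 * length(z), 0, model$noise_sd), ncol = 3))
    Pxx <- Pxx + noise[, 1]; Pyy <- Pyy + noise[, 2]; Pzz <- Pzz + noise[, 3]
  }
  mom <- bump_moments(model$bumps)
  list(stress = stress_profile(z, Pxx, Pyy, Pzz, frame_count = 1L),
       truth = elastic_constants(bending_moment_bar_nm2 = mom[["first"]],
                                 gaussian_modulus_bar_nm3 = -mom[["second"]],
                                 temperature = temperature),
       lpp_true = bump)
}

#' Parametric leaflet-surface model
#'
#' Declares an analytic leaflet surface for point-cloud sampling:
#' * `plane`: h = offset.
#' * `tilted_normal_field`: planar cloud whose *prescribed* normal field
#'   is uniformly tilted by `tilt` radians from z (exercises the order
#'   parameter directly; the point cloud itself is planar).
#' * `sinusoid`: h = offset + h0 * sin(2 pi x / wavelength); the
#'   wavelength must divide the box length Lx.
#' * `spherical_bud`: plane with a spherical cap (radius, cap_angle)
#'   rising from the box centre; the cap footprint must fit inside half
#'   the box.
#'
#' @param form surface form (above).
#' @param parameters named list: `offset` (nm, all forms); `tilt` (rad,
#'   tilted_normal_field); `h0`, `wavelength` (nm, sinusoid); `radius`,
#'   `cap_angle` (nm, rad; spherical_bud).
#' @param box periodic box c(Lx, Ly) in nm.
#' @param n_lipids_per_leaflet points sampled per leaflet (default 512).
#' @param jitter_sd positional Gaussian noise SD in nm (x, y, z).
#' @param seed integer RNG seed.
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(form = c("plane", "tilted_normal_field", "sinusoid",
                                   "spherical_bud"),
                          parameters = list(), box = c(10, 10),
                          n_lipids_per_leaflet = 512L, jitter_sd = 0,
                          seed = NULL) {
  form <- match.arg(form)
  box <- as.numeric(box)
  if (length(box) != 2L || any(box <= 0)) stop("box must be positive (Lx, Ly)")
  p <- modifyList(list(offset = 0), parameters)
  if (form == "tilted_normal_field" && is.null(p$tilt)) {
    stop("tilted_normal_field needs parameter 'tilt' (radians)")
  }
  if (form == "sinusoid") {
    if (is.null(p$h0) || is.null(p$wavelength)) {
      stop("sinusoid needs parameters 'h0' and 'wavelength'")
    }
    k <- box[1] / p$wavelength
    if (abs(k - round(k)) > 1e-9) {
      stop("configuration error: wavelength must divide the box length Lx")
    }
  }
  if (form == "spherical_bud") {
    if (is.null(p$radius) || is.null(p$cap_angle)) {
      stop("spherical_bud needs parameters 'radius' and 'cap_angle'")
    }
    if (p$cap_angle <= 0 || p$cap_angle > pi / 2) {
      stop("cap_angle must lie in (0, pi/2]")
    }
    if (p$radius * sin(p$cap_angle) > min(box) / 2) {
      stop("configuration error: bud footprint exceeds the box half-width")
    }
  }
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  structure(list(form = form, parameters = p, box = box,
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 jitter_sd = jitter_sd, seed = seed),
            class = "surface_model")
}

# Analytic surface height and its oracle order parameter.
surface_height_fn <- function(model) {
  p <- model$parameters
  switch(model$form,
    plane = ,
    tilted_normal_field = function(x, y) rep(p$offset, length(x)),
    sinusoid = function(x, y) p$offset + p$h0 * sin(2 * pi * x / p$wavelength),
    spherical_bud = function(x, y) {
      cx <- model$box[1] / 2; cy <- model$box[2] / 2
      r <- sqrt((x - cx)^2 + (y - cy)^2)
      rim <- p$radius * sin(p$cap_angle)
      h <- rep(p$offset, length(x))
      inside <- r < rim
      h[inside] <- p$offset + sqrt(p$radius^2 - r[inside]^2) -
        p$radius * cos(p$cap_angle)
      h
    })
}

# Oracle curvature order parameter: area-weighted surface integral of
# P2(cos theta) for the analytic normal field, by dense 1-D quadrature.
surface_sc_oracle <- function(model) {
  p <- model$parameters
  switch(model$form,
    plane = 1,
    tilted_normal_field = p2(cos(p$tilt)),
    sinusoid = sc_sinusoid_oracle(p$h0, p$wavelength),
    spherical_bud = sc_bud_oracle(p$radius, p$cap_angle, model$box))
}

#' Quadrature oracle for the order parameter of a sinusoidal surface
#'
#' For h(x) = h0 sin(2 pi x / L) the normal tilt satisfies
#' cos(theta) = (1 + h'(x)^2)^(-1/2); the area-weighted order parameter is
#' the ratio of the surface integrals of P2(cos theta) and 1 over one
#' period, with area element sqrt(1 + h'^2) dx, evaluated by adaptive
#' quadrature.
#'
#' @param h0 amplitude in nm.
#' @param L wavelength in nm.
#' @return The oracle S_C value.
#' @export
sc_sinusoid_oracle <- function(h0, L) {
  hp <- function(x) (2 * pi * h0 / L) * cos(2 * pi * x / L)
  w <- function(x) sqrt(1 + hp(x)^2)
  num <- stats::integrate(function(x) p2(1 / w(x)) * w(x), 0, L,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(w, 0, L, rel.tol = 1e-10)$value
  num / den
}

#' Quadrature oracle for the order parameter of a budded surface
#'
#' Plane of area Lx*Ly minus the cap footprint contributes P2 = 1; the
#' spherical cap contributes the surface integral of P2(cos theta) with
#' cos theta = sqrt(R^2 - r^2)/R and area element 2 pi r R / sqrt(R^2 -
#' r^2) dr over the footprint radius.
#'
#' @param radius bud radius R in nm.
#' @param cap_angle cap half-opening angle in radians.
#' @param box periodic box c(Lx, Ly) in nm.
#' @return The oracle S_C value.
#' @export
sc_bud_oracle <- function(radius, cap_angle, box) {
  rim <- radius * sin(cap_angle)
  plane_area <- box[1] * box[2] - pi * rim^2
  cap_area <- 2 * pi * radius^2 * (1 - cos(cap_angle))
  integrand <- function(r) {
    ct <- sqrt(radius^2 - r^2) / radius
    p2(ct) * 2 * pi * r * radius / sqrt(radius^2 - r^2)
  }
  cap_int <- stats::integrate(integrand, 0, rim, rel.tol = 1e-10)$value
  (plane_area * 1 + cap_int) / (plane_area + cap_area)
}

#' Sample a bilayer point cloud from a surface model
#'
#' Draws points uniformly in (x, y), lifts them onto the analytic surface
#' (upper leaflet; the lower leaflet is the same surface shifted down by
#' `leaflet_sep`), adds positional jitter if configured, and returns the
#' frame together with the oracle curvature order parameter of the
#' analytic normal field (dense quadrature of P2 of the normal's
#' z-cosine over the surface).
#'
#' @param model a [surface_model()].
#' @param leaflet_sep vertical separation between leaflet surfaces in nm
#'   (default 4).
#' @return List with `frame` ([lipid_frame()]) and `oracle_sc` (numeric).
#' @export
gen_surface_cloud <- function(model, leaflet_sep = 4) {
  stopifnot(inherits(model, "surface_model"))
  n <- model$n_lipids_per_leaflet
  hfun <- surface_height_fn(model)
  pts <- with_seed_or_not(model$seed, {
    x <- stats::runif(2 * n, 0, model$box[1])
    y <- stats::runif(2 * n, 0, model$box[2])
    z <- hfun(x, y)
    z[(n + 1):(2 * n)] <- z[(n + 1):(2 * n)] - leaflet_sep
    m <- cbind(x, y, z)
    if (model$jitter_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, model$jitter_sd), ncol = 3)
    }
    m
  })
  frame <- lipid_frame(pts, rep(c("upper", "lower"), each = n), model$box)
  list(frame = frame, oracle_sc = surface_sc_oracle(model))
}
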