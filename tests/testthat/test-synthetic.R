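test_that("isotherm generator evaluates declared forms exactly and stays monotone", {
  lin <- gen_isotherm(isotherm_model("linear", c(70, -1), c(20, 70)))
  expect_equal(as.numeric(area_at_pressure(lin, 20)), 50, tolerance = 1e-12)

  hyp <- gen_isotherm(isotherm_model("hyperbolic", 1000, c(20, 60), n = 401L))
  expect_equal(as.numeric(area_at_pressure(hyp, 25)), 40, tolerance = 1e-3)

  # plateau form: non-increasing pressure, flat on the low-slope segment
  pl <- gen_isotherm(isotherm_model("plateau", c(2, -2, 0, -3, 55, 45),
                                    c(30, 70), n = 401L))
  expect_true(all(diff(pl$pressure) >= -1e-12))  # pi rises on compression
  seg <- pl$pressure[pl$area > 46 & pl$area < 54]
  expect_lt(diff(range(seg)), 1e-9)

  # configuration errors
  expect_error(isotherm_model("linear", c(70, 1), c(20, 70)), "slope")
  expect_error(isotherm_model("hyperbolic", -5, c(20, 60)), "positive")
  expect_error(isotherm_model("linear", c(70, -1), c(70, 20)), "area_range")
  expect_error(gen_isotherm(isotherm_model("linear", c(10, -1), c(20, 70))),
               "negative")
})

test_that("identical seeds reproduce identical synthetic outputs", {
  m <- isotherm_model("linear", c(70, -1), c(20, 70), noise_sd = 0.5, seed = 42)
  expect_identical(gen_isotherm(m), gen_isotherm(m))

  sm <- single_bump_model(noise_sd = 2, seed = 11)
  expect_identical(gen_stress_profile(sm)$stress, gen_stress_profile(sm)$stress)

  cm <- surface_model("sinusoid", list(h0 = 0.5, wavelength = 5, offset = 1),
                      jitter_sd = 0.05, seed = 9, n_lipids_per_leaflet = 64L)
  expect_identical(gen_surface_cloud(cm)$frame$positions,
                   gen_surface_cloud(cm)$frame$positions)
})

test_that("mixture families obey the declared mixing rule", {
  p1 <- isotherm_model("linear", c(66, -1), c(20, 64))
  p2 <- isotherm_model("linear", c(92.5, -1.25), c(30, 72))

  # ideal mixing: mixture area is the exact mean of the pure areas
  fam0 <- gen_mixture_family(p1, p2, mixture_scenario(mole_fraction_first = 0.5))
  a1 <- as.numeric(area_at_pressure(fam0$pure_first, fam0$mixture$pressure))
  a2 <- as.numeric(area_at_pressure(fam0$pure_second, fam0$mixture$pressure))
  expect_equal(fam0$mixture$area, (a1 + a2) / 2, tolerance = 1e-12)

  # declared constant excess of -7.5 A^2 reproduces the measured 40 A^2
  # equimolar area from pure areas 54 and 41 A^2 at 25 mN/m
  fam <- gen_mixture_family(p1, p2,
    mixture_scenario(mole_fraction_first = 0.5, excess_coefficients = -7.5))
  expect_equal(as.numeric(area_at_pressure(fam$pure_first, 25)), 41, tolerance = 1e-9)
  expect_equal(as.numeric(area_at_pressure(fam$pure_second, 25)), 54, tolerance = 1e-9)
  expect_equal(as.numeric(area_at_pressure(fam$mixture, 25)), 40, tolerance = 1e-6)

  # boundary composition degenerates to the pure-first isotherm
  fam1 <- gen_mixture_family(p1, p2, mixture_scenario(mole_fraction_first = 1))
  a1g <- as.numeric(area_at_pressure(fam1$pure_first, fam1$mixture$pressure))
  expect_equal(fam1$mixture$area, a1g, tolerance = 1e-12)

  # non-overlapping pressure ranges refuse
  p3 <- isotherm_model("linear", c(200, -1), c(80, 120))  # pi in [80, 120]
  expect_error(gen_mixture_family(p1, p3, mixture_scenario()), "overlap")
})

test_that("stress generator ground truth matches dense quadrature and closed forms", {
  gs <- gen_stress_profile(single_bump_model(n_points = 4096L))
  prof <- compute_lpp(gs$stress)
  expect_equal(prof$lpp, gs$lpp_true, tolerance = 1e-12)

  # closed forms: 100 * 0.2 * sqrt(2*pi) * mu and * (mu^2 + sigma^2)
  expect_equal(gs$truth$bending_moment_bar_nm2, gauss_moment1(100, 1, 0.2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(gs$truth$gaussian_modulus_bar_nm3, -gauss_moment2(100, 1, 0.2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(gs$truth$bending_moment_pN, 5.013, tolerance = 1e-3,
               ignore_attr = TRUE)

  # oracle self-consistency: truth vs dense trapezoid of the generated profile
  expect_equal(ref_moment(prof$z, prof$lpp, 1),
               as.numeric(gs$truth$bending_moment_bar_nm2), tolerance = 1e-6)
  expect_equal(-ref_moment(prof$z, prof$lpp, 2),
               as.numeric(gs$truth$gaussian_modulus_bar_nm3), tolerance = 1e-6)

  # mirror-symmetric bump pair has zero first moment
  pair <- stress_field_model(
    data.frame(amplitude = c(50, 50), center = c(-1, 1), width = c(0.2, 0.2)),
    z_range = c(-3, 3))
  expect_equal(as.numeric(gen_stress_profile(pair)$truth$bending_moment_bar_nm2),
               0, tolerance = 1e-12)

  # margin rule: range must span centers by >= 5 widths
  expect_error(single_bump_model(z_range = c(-1.5, 1.5)), "margin")
})

test_that("surface clouds carry correct analytic oracles and respect the box", {
  pl <- gen_surface_cloud(surface_model("plane", list(offset = 3),
                                        n_lipids_per_leaflet = 50L, seed = 1))
  expect_equal(pl$oracle_sc, 1)
  up <- pl$frame$positions[pl$frame$leaflet == "upper", ]
  expect_true(all(up[, 3] == 3))          # jitter 0: exact height
  expect_true(all(up[, 1] >= 0 & up[, 1] < 10))

  tl <- gen_surface_cloud(surface_model("tilted_normal_field",
                                        list(tilt = pi / 2),
                                        n_lipids_per_leaflet = 16L, seed = 1))
  expect_equal(tl$oracle_sc, -0.5)        # P2(cos 90 deg) = -1/2

  sc <- sc_sinusoid_oracle(1, 10)
  expect_lt(sc, 1)
  cl <- gen_surface_cloud(surface_model("sinusoid",
                                        list(h0 = 1, wavelength = 10, offset = 0),
                                        n_lipids_per_leaflet = 16L, seed = 1))
  expect_equal(cl$oracle_sc, sc)

  # bud footprint must fit in the box
  expect_error(surface_model("spherical_bud",
                             list(radius = 8, cap_angle = pi / 2),
                             box = c(10, 10)),
               "footprint")
})

test_that("sinusoid oracle matches an independent flat-weight bound and bud oracle limits", {
  # amplitude -> 0 recovers the planar value
  expect_equal(sc_sinusoid_oracle(1e-8, 10), 1, tolerance = 1e-9)
  # bud with vanishing cap angle recovers the planar value
  expect_equal(sc_bud_oracle(3, 1e-6, c(10, 10)), 1, tolerance = 1e-6)
  # hemispherical bud S_C is strictly below any shallow sinusoid's
  expect_lt(sc_bud_oracle(4, pi / 2, c(10, 10)), sc_sinusoid_oracle(0.5, 10))
})
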