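test_that("planar clouds give exact heights, unit order parameter and exact thickness", {
  cl <- gen_surface_cloud(surface_model("plane", list(offset = 2),
                                        n_lipids_per_leaflet = 200L, seed = 4),
                          leaflet_sep = 4)
  gu <- fit_surface(cl$frame, "upper")
  gl <- fit_surface(cl$frame, "lower")
  expect_equal(as.vector(gu$heights), rep(2, 32 * 32), tolerance = 1e-12)
  expect_equal(curvature_order_parameter(gu), 1)
  expect_equal(as.numeric(membrane_thickness(gu, gl)), 4, tolerance = 1e-12)
  expect_equal(attr(membrane_thickness(gu, gl), "n_negative_nodes"), 0L)
  # translation invariance of the thickness
  shift <- cl$frame
  shift$positions[, 3] <- shift$positions[, 3] + 1
  gu2 <- fit_surface(shift, "upper"); gl2 <- fit_surface(shift, "lower")
  expect_equal(as.numeric(membrane_thickness(gu2, gl2)), 4, tolerance = 1e-12)
  # area per lipid: flat box, projected = box / N and surface agrees
  g8 <- surface_grid(matrix(0, 16, 16), box = c(8, 8))
  expect_equal(area_per_lipid(g8, 128), 50)             # 64 nm^2 / 128 = 50 A^2
  expect_equal(area_per_lipid(g8, 128, "surface"), 50, tolerance = 1e-9)
})

test_that("prescribed normal fields give the Legendre order parameter directly", {
  # uniform tilt via a linear ramp height field evaluated on explicit slopes
  g <- surface_grid(matrix(0, 16, 16), box = c(10, 10))
  g$theta[] <- pi / 2
  g$hx[] <- 0; g$hy[] <- 0       # weightless: pure angle average
  expect_equal(curvature_order_parameter(g), -0.5)
  g$theta[] <- pi / 4
  expect_equal(curvature_order_parameter(g), (3 * 0.5 - 1) / 2)
  oracle <- gen_surface_cloud(surface_model("tilted_normal_field",
                                            list(tilt = pi / 2),
                                            n_lipids_per_leaflet = 16L,
                                            seed = 2))$oracle_sc
  expect_equal(oracle, -0.5)
})

test_that("sinusoidal surfaces are recovered within tolerance of the analytic field", {
  model <- surface_model("sinusoid", list(h0 = 1, wavelength = 10, offset = 3),
                         box = c(10, 10), n_lipids_per_leaflet = 20000L, seed = 7)
  cl <- gen_surface_cloud(model)
  g <- fit_surface(cl$frame, "upper", nx = 64L, ny = 64L, bandwidth = 0.18)
  gx <- (seq_len(64) - 1) * 10 / 64
  analytic <- 3 + sin(2 * pi * gx / 10)   # h0 = 1, L = 10
  rms <- sqrt(mean((g$heights - matrix(analytic, 64, 64))^2))
  expect_lt(rms / stats::sd(analytic), 0.02)

  # order parameter matches the quadrature oracle within 1% at 64 x 64
  expect_equal(curvature_order_parameter(g), cl$oracle_sc, tolerance = 0.01)

  # surface-mode area exceeds projected by the analytic arc-length factor
  arc <- stats::integrate(function(x) sqrt(1 + (2 * pi / 10 * cos(2 * pi * x / 10))^2),
                          0, 10, rel.tol = 1e-10)$value / 10
  ratio <- area_per_lipid(g, 20000, "surface") / area_per_lipid(g, 20000)
  expect_equal(ratio, arc, tolerance = 0.01)
  expect_gte(ratio, 1)
})

test_that("surface fitting is periodic-equivariant under commensurate translations", {
  model <- surface_model("sinusoid", list(h0 = 0.8, wavelength = 5, offset = 1),
                         box = c(10, 10), n_lipids_per_leaflet = 600L, seed = 3)
  cl <- gen_surface_cloud(model)
  nx <- 20L
  g0 <- fit_surface(cl$frame, "upper", nx = nx, ny = nx)
  # translate all points by exactly 2 grid cells in x (with wrap)
  dx <- 2 * 10 / nx
  fr2 <- lipid_frame(cbind(cl$frame$positions[, 1] + dx,
                           cl$frame$positions[, 2],
                           cl$frame$positions[, 3]),
                     cl$frame$leaflet, cl$frame$box)
  g2 <- fit_surface(fr2, "upper", nx = nx, ny = nx)
  expect_equal(g2$heights, g0$heights[c(nx - 1, nx, 1:(nx - 2)), ],
               tolerance = 1e-9)
  expect_equal(curvature_order_parameter(g2), curvature_order_parameter(g0),
               tolerance = 1e-9)
  # 90-degree box-compatible rotation: (x, y) -> (y, Lx - x)
  fr3 <- lipid_frame(cbind(cl$frame$positions[, 2],
                           10 - cl$frame$positions[, 1],
                           cl$frame$positions[, 3]),
                     cl$frame$leaflet, cl$frame$box)
  g3 <- fit_surface(fr3, "upper", nx = nx, ny = nx)
  expect_equal(curvature_order_parameter(g3), curvature_order_parameter(g0),
               tolerance = 1e-6)
  expect_equal(area_per_lipid(g3, 600, "surface"),
               area_per_lipid(g0, 600, "surface"), tolerance = 1e-6)
})

test_that("order parameter decreases with sinusoid amplitude and converges with resolution", {
  # amplitude monotonicity of the oracle and of the fitted estimate
  amps <- c(0.25, 0.5, 1, 1.5, 2)
  oracle <- vapply(amps, sc_sinusoid_oracle, numeric(1), L = 10)
  expect_true(all(diff(oracle) < 0))
  fitted <- vapply(amps, function(h0) {
    cl <- gen_surface_cloud(surface_model("sinusoid",
                                          list(h0 = h0, wavelength = 10, offset = 0),
                                          n_lipids_per_leaflet = 2000L, seed = 21))
    curvature_order_parameter(fit_surface(cl$frame, "upper", 48L, 48L))
  }, numeric(1))
  expect_true(all(diff(fitted) < 0))
  expect_true(all(fitted <= 1))

  # resolution convergence toward the oracle on a noiseless dense cloud
  cl <- gen_surface_cloud(surface_model("sinusoid",
                                        list(h0 = 1, wavelength = 10, offset = 0),
                                        n_lipids_per_leaflet = 6000L, seed = 5))
  err <- vapply(c(16L, 32L, 64L), function(nx) {
    abs(curvature_order_parameter(fit_surface(cl$frame, "upper", nx, nx)) -
          cl$oracle_sc)
  }, numeric(1))
  expect_lt(err[3], err[1])

  # a budded surface curves more than the sinusoid of equal RMS height:
  # bud RMS height from independent radial quadrature over the box
  for (cfg in list(c(4, pi / 2.5), c(4, pi / 2), c(3, pi / 2))) {
    R <- cfg[1]; alpha <- cfg[2]
    rim <- R * sin(alpha)
    hfun <- function(r) sqrt(R^2 - r^2) - R * cos(alpha)
    m1 <- stats::integrate(function(r) hfun(r) * 2 * pi * r, 0, rim)$value / 100
    m2 <- stats::integrate(function(r) hfun(r)^2 * 2 * pi * r, 0, rim)$value / 100
    rms <- sqrt(m2 - m1^2)
    expect_lt(sc_bud_oracle(R, alpha, c(10, 10)),
              sc_sinusoid_oracle(sqrt(2) * rms, 10))
  }
})

test_that("trajectory summaries report window statistics of the per-frame series", {
  mk <- function(h0, seed) {
    gen_surface_cloud(surface_model("sinusoid",
                                    list(h0 = h0, wavelength = 10, offset = 2),
                                    n_lipids_per_leaflet = 800L,
                                    seed = seed))$frame
  }
  # identical repeated frames: zero IQR, mean equals the per-frame value
  f <- mk(0.5, 1)
  ts <- trajectory_summary(list(f, f, f), nx = 24L, ny = 24L)
  expect_equal(ts$stats["S_C", "iqr"], 0)
  expect_equal(ts$stats["S_C", "mean"], ts$per_frame$S_C[1])
  expect_equal(ts$stats["D_HH", "iqr"], 0)

  # decreasing amplitude drives S_C monotonically toward 1
  frames <- lapply(seq_along(c(2, 1.2, 0.6, 0.2)), function(i) {
    mk(c(2, 1.2, 0.6, 0.2)[i], seed = 30 + i)
  })
  ts2 <- trajectory_summary(frames, nx = 24L, ny = 24L)
  expect_true(all(diff(ts2$per_frame$S_C) > 0))

  # two-frame window statistics
  two <- trajectory_summary(frames[3:4], nx = 24L, ny = 24L)
  expect_equal(two$stats["S_C", "mean"], mean(two$per_frame$S_C))
  expect_equal(two$stats["S_C", "median"], stats::median(two$per_frame$S_C))

  expect_error(trajectory_summary(list()), "at least one")
  expect_error(trajectory_summary(frames, window_fraction = 0), "window_fraction")
})
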