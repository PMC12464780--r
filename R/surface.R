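#' Lipid reference-point frame
#'
#' One reference point per lipid (e.g. a headgroup bead chosen by the
#' caller) in a laterally periodic box: an N x 3 coordinate matrix in nm,
#' a per-point leaflet label, and the periodic box dimensions (Lx, Ly).
#' x and y are wrapped into [0, Lx) x [0, Ly).
#'
#' @param positions N x 3 numeric matrix of (x, y, z) in nm.
#' @param leaflet character/factor of length N with values `"upper"` or
#'   `"lower"`.
#' @param box numeric length-2 periodic box dimensions (Lx, Ly) in nm.
#' @param time optional frame time in ps.
#' @return An object of class `lipid_frame`.
#' @export
lipid_frame <- function(positions, leaflet, box, time = NA_real_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  leaflet <- as.character(leaflet)
  if (length(leaflet) != n) stop("leaflet labels must match the number of points")
  if (!all(leaflet %in% c("upper", "lower"))) {
    stop("leaflet labels must be 'upper' or 'lower'")
  }
  box <- as.numeric(box)
  if (length(box) != 2L || any(box <= 0)) stop("box must be positive (Lx, Ly)")
  positions[, 1] <- wrap_coord(positions[, 1], box[1])
  positions[, 2] <- wrap_coord(positions[, 2], box[2])
  counts <- table(factor(leaflet, levels = c("upper", "lower")))
  if (any(counts > 0 & counts < 4)) {
    stop("each non-empty leaflet needs at least 4 points")
  }
  colnames(positions) <- c("x", "y", "z")
  structure(list(positions = positions, leaflet = leaflet, box = box,
                 time = time),
            class = "lipid_frame")
}

#' @export
print.lipid_frame <- function(x, ...) {
  cat(sprintf("<lipid_frame> %d points (%d upper / %d lower), box %.2f x %.2f nm\n",
              nrow(x$positions), sum(x$leaflet == "upper"),
              sum(x$leaflet == "lower"), x$box[1], x$box[2]))
  invisible(x)
}

#' Construct a surface grid directly
#'
#' Builds a `surface_grid` from a height matrix on a node-centred periodic
#' grid, computing normals by central differences with periodic wrap.
#' Normals are oriented to have a non-negative z-component, so leaflet
#' orientation does not flip the tilt angle; theta is the angle between
#' each normal and the z-axis, in \[0, pi/2\].
#'
#' @param heights nx x ny matrix of heights h(x_i, y_j) in nm; node i sits
#'   at x_i = (i-1) Lx/nx (half-open periodic convention).
#' @param box periodic box (Lx, Ly) in nm.
#' @param bandwidth kernel bandwidth recorded as provenance (NA when the
#'   grid was not produced by [fit_surface()]).
#' @return An object of class `surface_grid` with fields `heights`,
#'   `normals` (nx x ny x 3), `theta`, `box`, `nx`, `ny`, `bandwidth`.
#' @export
surface_grid <- function(heights, box, bandwidth = NA_real_) {
  heights <- as.matrix(heights)
  nx <- nrow(heights)
  ny <- ncol(heights)
  if (nx < 4L || ny < 4L) stop("grid resolution must be at least 4 x 4")
  box <- as.numeric(box)
  dx <- box[1] / nx
  dy <- box[2] / ny
  ip <- c(2:nx, 1L); im <- c(nx, 1:(nx - 1L))
  jp <- c(2:ny, 1L); jm <- c(ny, 1:(ny - 1L))
  hx <- (heights[ip, , drop = FALSE] - heights[im, , drop = FALSE]) / (2 * dx)
  hy <- (heights[, jp, drop = FALSE] - heights[, jm, drop = FALSE]) / (2 * dy)
  nrm <- sqrt(hx^2 + hy^2 + 1)
  normals <- array(c(-hx / nrm, -hy / nrm, 1 / nrm), dim = c(nx, ny, 3))
  theta <- acos(pmin(1, pmax(-1, 1 / nrm)))
  structure(list(heights = heights, normals = normals, theta = theta,
                 hx = hx, hy = hy, box = box, nx = nx, ny = ny,
                 bandwidth = bandwidth, warnings = character()),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d x %d nodes, box %.2f x %.2f nm, mean theta %.3f rad, bandwidth %.3g nm\n",
              x$nx, x$ny, x$box[1], x$box[2], mean(x$theta), x$bandwidth))
  invisible(x)
}

#' Fit a periodic height field to one leaflet of a lipid frame
#'
#' Estimates the leaflet surface h(x, y) by Gaussian-kernel height
#' regression on a node-centred periodic grid: each node height is the
#' kernel-weighted average of the leaflet's point heights, with distances
#' taken under the minimum-image convention so the fitted field is
#' periodic by construction. Deterministic for fixed inputs.
#'
#' @param frame a [lipid_frame()].
#' @param leaflet `"upper"` or `"lower"`.
#' @param nx,ny grid resolution (default 32 x 32).
#' @param bandwidth Gaussian kernel bandwidth in nm; default 1.5 times the
#'   mean nearest-neighbour spacing estimate `sqrt(Lx*Ly/N)`. A bandwidth
#'   below that spacing estimate is accepted but recorded as a warning in
#'   the output.
#' @return A [surface_grid()].
#' @export
fit_surface <- function(frame, leaflet = c("upper", "lower"),
                        nx = 32L, ny = 32L, bandwidth = NULL) {
  stopifnot(inherits(frame, "lipid_frame"))
  leaflet <- match.arg(leaflet)
  sel <- frame$leaflet == leaflet
  if (!any(sel)) stop("leaflet '", leaflet, "' is empty")
  pts <- frame$positions[sel, , drop = FALSE]
  box <- frame$box
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 4L || ny < 4L) stop("grid resolution must be at least 4 x 4")
  spacing <- sqrt(box[1] * box[2] / nrow(pts))
  warn <- character()
  if (is.null(bandwidth)) bandwidth <- 1.5 * spacing
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (bandwidth < spacing) {
    warn <- sprintf("bandwidth %.3g nm below mean nearest-neighbour spacing %.3g nm; heights may be under-smoothed",
                    bandwidth, spacing)
  }
  gx <- (seq_len(nx) - 1) * box[1] / nx
  gy <- (seq_len(ny) - 1) * box[2] / ny
  # periodic squared distances, points x nodes, separable in x and y
  dx2 <- outer(pts[, 1], gx, function(p, g) min_image(p - g, box[1])^2)
  dy2 <- outer(pts[, 2], gy, function(p, g) min_image(p - g, box[2])^2)
  wx <- exp(-dx2 / (2 * bandwidth^2))
  wy <- exp(-dy2 / (2 * bandwidth^2))
  zwx <- pts[, 3] * wx
  heights <- crossprod(zwx, wy) / crossprod(wx, wy)  # nx x ny? see below
  # crossprod(wx, wy) is t(wx) %*% wy: (nodes_x x pts) %*% (pts x nodes_y)
  g <- surface_grid(heights, box, bandwidth = bandwidth)
  g$warnings <- warn
  g
}

#' Curvature order parameter of a fitted surface
#'
#' Area-weighted mean over the grid of the second Legendre polynomial of
#' the cosine of the normal tilt angle,
#' \deqn{S_C = \left\langle \frac{3\cos^2\theta - 1}{2} \right\rangle_A}
#' with per-node surface area elements
#' \eqn{dA = \sqrt{1 + h_x^2 + h_y^2}\, dx\, dy}. Equals 1 if and only if
#' the surface is planar (theta = 0 everywhere); deviations below 1
#' indicate increasing surface curvature.
#'
#' @param grid a [surface_grid()].
#' @return Dimensionless scalar, at most 1.
#' @export
curvature_order_parameter <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  w <- sqrt(1 + grid$hx^2 + grid$hy^2)
  sum(w * p2(cos(grid$theta))) / sum(w)
}

#' Area per lipid from a fitted surface
#'
#' Projected mode divides the periodic box area by the lipid count;
#' surface mode divides the triangulated area of the fitted height field
#' (two triangles per grid cell, periodic closure) by the lipid count.
#' The surface-mode area is never below the projected one.
#'
#' @param grid a [surface_grid()].
#' @param n_lipids number of lipids in the leaflet.
#' @param mode `"projected"` or `"surface"`.
#' @return Area per lipid in Angstrom^2.
#' @export
area_per_lipid <- function(grid, n_lipids, mode = c("projected", "surface")) {
  stopifnot(inherits(grid, "surface_grid"), n_lipids > 0)
  mode <- match.arg(mode)
  area_nm2 <- switch(mode,
                     projected = grid$box[1] * grid$box[2],
                     surface = triangulated_area(grid))
  area_nm2 / n_lipids * 100  # nm^2 -> A^2
}

triangulated_area <- function(grid) {
  h <- grid$heights
  nx <- grid$nx; ny <- grid$ny
  dx <- grid$box[1] / nx; dy <- grid$box[2] / ny
  ip <- c(2:nx, 1L); jp <- c(2:ny, 1L)
  h00 <- h
  h10 <- h[ip, , drop = FALSE]
  h01 <- h[, jp, drop = FALSE]
  h11 <- h[ip, jp, drop = FALSE]
  # triangle (00,10,11): cross((dx,0,h10-h00),(dx,dy,h11-h00))
  a1 <- 0.5 * sqrt((-dy * (h10 - h00))^2 +
                   (dx * (h11 - h00) - dx * (h10 - h00))^2 +
                   (dx * dy)^2)
  # triangle (00,11,01): cross((dx,dy,h11-h00),(0,dy,h01-h00))
  a2 <- 0.5 * sqrt((dy * (h11 - h00) - dy * (h01 - h00))^2 +
                   (-dx * (h01 - h00))^2 +
                   (dx * dy)^2)
  sum(a1 + a2)
}

#' Head-to-head membrane thickness from two leaflet surfaces
#'
#' Grid-mean of the node-wise height difference between the upper and
#' lower leaflet surfaces, in nm. Nodes where the difference is negative
#' (leaflet surfaces crossing) are counted in attribute
#' `n_negative_nodes`.
#'
#' @param upper,lower [surface_grid()]s on matching resolutions and box.
#' @return Mean thickness in nm with attribute `n_negative_nodes`.
#' @export
membrane_thickness <- function(upper, lower) {
  stopifnot(inherits(upper, "surface_grid"), inherits(lower, "surface_grid"))
  if (upper$nx != lower$nx || upper$ny != lower$ny ||
      any(abs(upper$box - lower$box) > 1e-9)) {
    stop("leaflet grids must share resolution and box dimensions")
  }
  d <- upper$heights - lower$heights
  structure(mean(d), n_negative_nodes = sum(d < 0))
}

#' Per-frame curvature summary of a trajectory
#'
#' Computes the curvature order parameter S_C, area per lipid A_L and
#' head-to-head thickness D_HH for every frame, then summarises a trailing
#' time window (default: all frames) with mean, median and interquartile
#' range — the statistics behind per-composition violin plots.
#' The reported per-frame S_C is the leaflet mean.
#'
#' @param frames list of [lipid_frame()]s in time order.
#' @param nx,ny,bandwidth surface-fitting parameters (see [fit_surface()]).
#' @param area_mode `"projected"` or `"surface"` for A_L.
#' @param window_fraction fraction of trailing frames to summarise, in
#'   (0, 1\]; default 1 (all frames).
#' @return A `curvature_summary`: list with `per_frame` data frame
#'   (`frame`, `time`, `S_C`, `A_L`, `D_HH`) and `stats` data frame of
#'   mean/median/IQR for each quantity over the window.
#' @export
trajectory_summary <- function(frames, nx = 32L, ny = 32L, bandwidth = NULL,
                               area_mode = "projected", window_fraction = 1) {
  if (length(frames) < 1L) stop("need at least one frame")
  if (window_fraction <= 0 || window_fraction > 1) {
    stop("window_fraction must lie in (0, 1]")
  }
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    gu <- fit_surface(fr, "upper", nx, ny, bandwidth)
    gl <- fit_surface(fr, "lower", nx, ny, bandwidth)
    n_up <- sum(fr$leaflet == "upper")
    n_lo <- sum(fr$leaflet == "lower")
    data.frame(
      frame = i, time = fr$time,
      S_C = (curvature_order_parameter(gu) + curvature_order_parameter(gl)) / 2,
      A_L = (area_per_lipid(gu, n_up, area_mode) +
             area_per_lipid(gl, n_lo, area_mode)) / 2,
      D_HH = as.numeric(membrane_thickness(gu, gl)))
  })
  per_frame <- do.call(rbind, rows)
  n <- nrow(per_frame)
  first <- n - max(1L, ceiling(window_fraction * n)) + 1L
  win <- per_frame[first:n, , drop = FALSE]
  summarise <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    c(mean = mean(v), median = stats::median(v), iqr = q[2] - q[1])
  }
  stats_df <- as.data.frame(rbind(S_C = summarise(win$S_C),
                                  A_L = summarise(win$A_L),
                                  D_HH = summarise(win$D_HH)))
  stats_df$quantity <- rownames(stats_df)
  structure(list(per_frame = per_frame, stats = stats_df,
                 window = c(first = first, last = n)),
            class = "curvature_summary")
}

#' @export
print.curvature_summary <- function(x, ...) {
  cat(sprintf("<curvature_summary> %d frames (window %d..%d)\n",
              nrow(x$per_frame), x$window["first"], x$window["last"]))
  print(x$stats[, c("quantity", "mean", "median", "iqr")], row.names = FALSE)
  invisible(x)
}
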