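#' Stress-tensor profile along the membrane normal
#'
#' Depth-resolved diagonal components of the pressure tensor from MD
#' post-processing: a strictly increasing, uniformly spaced z grid (nm)
#' with `Pxx`, `Pyy`, `Pzz` in bar at each node. Inputs are
#' pressure-tensor components as MD engines report them; no virial-sign
#' flip is applied (a stress-vs-pressure sign confusion negates both
#' elastic moments downstream).
#'
#' @param z grid along the membrane normal in nm; strictly increasing,
#'   uniform spacing within 1e-9 relative.
#' @param Pxx,Pyy,Pzz stress components in bar, same length as `z`.
#' @param frame_count number of trajectory frames averaged (provenance).
#' @return An object of class `stress_profile` (a data frame).
#' @export
stress_profile <- function(z, Pxx, Pyy, Pzz, frame_count = NA_integer_) {
  z <- as.numeric(z)
  n <- length(z)
  if (n < 16L) stop("stress profiles need at least 16 grid points")
  if (length(Pxx) != n || length(Pyy) != n || length(Pzz) != n) {
    stop("Pxx, Pyy, Pzz must match the z grid length")
  }
  if (is.unsorted(z, strictly = TRUE)) stop("z grid must be strictly increasing")
  dz <- diff(z)
  if (max(abs(dz - dz[1])) > 1e-9 * abs(dz[1])) {
    stop("non-uniform z grid: resample the profile onto a uniform grid first")
  }
  structure(data.frame(z = z, Pxx = as.numeric(Pxx), Pyy = as.numeric(Pyy),
                       Pzz = as.numeric(Pzz)),
            class = c("stress_profile", "data.frame"),
            frame_count = frame_count)
}

#' Lateral pressure profile from a stress profile
#'
#' Pointwise lateral-minus-normal stress,
#' \deqn{LPP(z) = \frac{P_{xx}(z) + P_{yy}(z)}{2} - P_{zz}(z)}
#' in bar. No smoothing is applied.
#'
#' @param stress a [stress_profile()].
#' @return An object of class `lpp_profile`: data frame with columns `z`
#'   (nm) and `lpp` (bar), `midplane_shift` attribute 0.
#' @export
compute_lpp <- function(stress) {
  stopifnot(inherits(stress, "stress_profile"))
  lpp <- (stress$Pxx + stress$Pyy) / 2 - stress$Pzz
  new_lpp_profile(stress$z, lpp, shift = 0)
}

new_lpp_profile <- function(z, lpp, shift = 0) {
  structure(data.frame(z = z, lpp = lpp),
            class = c("lpp_profile", "data.frame"),
            midplane_shift = shift)
}

#' @export
print.lpp_profile <- function(x, ...) {
  cat(sprintf("<lpp_profile> %d points, z in [%.3f, %.3f] nm, |LPP| max %.2f bar, midplane shift %.4g nm\n",
              nrow(x), min(x$z), max(x$z), max(abs(x$lpp)),
              attr(x, "midplane_shift")))
  invisible(x)
}

#' Centre a lateral pressure profile on the membrane midplane
#'
#' The elastic-constant integrals assume the membrane midplane lies at
#' z = 0. The default locator places the midplane at the midpoint between
#' the two outermost zero-crossings of LPP(z); if fewer than two crossings
#' exist it falls back to the geometric centre of the profile's support
#' (nodes where |LPP| exceeds 1% of its maximum). The applied shift is
#' recorded so original coordinates are recoverable.
#'
#' @param profile an `lpp_profile`.
#' @param mode `"zero_crossings"` (default), `"support_centre"`, or a
#'   numeric midplane position in the profile's current coordinates.
#' @return The centred `lpp_profile`; attribute `midplane_shift`
#'   accumulates the total shift applied relative to the original input.
#' @export
center_midplane <- function(profile, mode = "zero_crossings") {
  stopifnot(inherits(profile, "lpp_profile"))
  z <- profile$z
  v <- profile$lpp
  if (all(v == 0)) stop("centring failed: profile is identically zero")
  if (is.numeric(mode)) {
    mid <- as.numeric(mode)
  } else if (identical(mode, "zero_crossings")) {
    s <- sign(v)
    idx <- which(s[-1] * s[-length(s)] < 0)
    if (length(idx) >= 2L) {
      cross <- vapply(idx, function(i) {
        z[i] - v[i] * (z[i + 1] - z[i]) / (v[i + 1] - v[i])
      }, numeric(1))
      mid <- (min(cross) + max(cross)) / 2
    } else {
      mid <- support_centre(z, v)
    }
  } else if (identical(mode, "support_centre")) {
    mid <- support_centre(z, v)
  } else {
    stop("unknown centring mode: ", mode)
  }
  new_lpp_profile(z - mid, v, shift = attr(profile, "midplane_shift") - mid)
}

support_centre <- function(z, v, f = 0.01) {
  on <- which(abs(v) > f * max(abs(v)))
  if (length(on) == 0L) stop("centring failed: no interior structure in LPP")
  (z[min(on)] + z[max(on)]) / 2
}

#' Detect membrane integration bounds from an LPP profile
#'
#' Finds the limits d- and d+ used by the elastic-constant integrals.
#' The default support-threshold rule takes the outermost grid nodes where
#' |LPP| exceeds a fraction `f` of its maximum, padded by one grid step;
#' this keeps bulk-water noise out of the moments. Explicit user bounds
#' are returned verbatim. Full-box integration is available with
#' `rule = "full"`.
#'
#' @param profile a centred `lpp_profile`.
#' @param rule `"support"` (default), `"full"`, or a numeric length-2
#'   vector `c(d_minus, d_plus)` used verbatim.
#' @param f support threshold fraction of max |LPP| (default 0.01).
#' @return An object of class `membrane_bounds`: list with `d_minus`,
#'   `d_plus` (nm) and `detection_rule`.
#' @export
detect_bounds <- function(profile, rule = "support", f = 0.01) {
  stopifnot(inherits(profile, "lpp_profile"))
  z <- profile$z
  v <- profile$lpp
  if (is.numeric(rule)) {
    if (length(rule) != 2L || rule[1] >= rule[2]) {
      stop("explicit bounds must be c(d_minus, d_plus) with d_minus < d_plus")
    }
    return(new_bounds(rule[1], rule[2], "explicit user bounds", z))
  }
  if (identical(rule, "full")) {
    return(new_bounds(min(z), max(z), "full grid", z))
  }
  if (!identical(rule, "support")) stop("unknown bounds rule: ", rule)
  if (all(v == 0)) stop("degenerate profile: LPP is identically zero")
  h <- z[2] - z[1]
  on <- which(abs(v) > f * max(abs(v)))
  d_minus <- max(min(z), z[min(on)] - h)
  d_plus <- min(max(z), z[max(on)] + h)
  new_bounds(d_minus, d_plus,
             sprintf("support threshold f = %g of max |LPP|, one-step padding", f), z)
}

new_bounds <- function(d_minus, d_plus, rule, z) {
  if (d_minus < min(z) - 1e-12 || d_plus > max(z) + 1e-12) {
    stop("bounds fall outside the profile grid")
  }
  if (!(d_minus < 0 && d_plus > 0)) {
    stop(sprintf("bounds [%g, %g] must bracket the midplane z = 0; centre the profile first",
                 d_minus, d_plus))
  }
  structure(list(d_minus = d_minus, d_plus = d_plus, detection_rule = rule),
            class = "membrane_bounds")
}

#' @export
print.membrane_bounds <- function(x, ...) {
  cat(sprintf("<membrane_bounds> d- = %.4g nm, d+ = %.4g nm (%s)\n",
              x$d_minus, x$d_plus, x$detection_rule))
  invisible(x)
}
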