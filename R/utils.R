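# Shared numerical helpers.

# Second Legendre polynomial.
p2 <- function(x) (3 * x^2 - 1) / 2

# Evaluate polynomial with coefficients in increasing-degree order
# (c[1] + c[2]*x + ...). pracma::polyval expects decreasing order.
polyval_inc <- function(coef, x) pracma::polyval(rev(coef), x)

# Local polynomial derivative estimate dy/dx at every sample point.
# For each point, a degree-`order` polynomial is fit by least squares to the
# `window` nearest samples in x and differentiated analytically at that point.
# Equivalent to a Savitzky-Golay differentiation filter on uniform grids, but
# valid for non-uniform spacing and at the series ends (one-sided windows).
local_poly_deriv <- function(x, y, window = 11L, order = 3L) {
  n <- length(x)
  stopifnot(length(y) == n)
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) {
    stop("insufficient data: need at least ", window,
         " points for the derivative stencil, got ", n)
  }
  if (order >= window) stop("polynomial order must be below the window size")
  half <- (window - 1L) %/% 2L
  d <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half, n - window + 1L))
    idx <- lo:(lo + window - 1L)
    xc <- x[idx] - x[i]
    X <- outer(xc, 0:order, `^`)
    beta <- stats::lm.fit(X, y[idx])$coefficients
    d[i] <- beta[2L]   # first-derivative coefficient at xc = 0
  }
  d
}

# Wrap coordinates into [0, L).
wrap_coord <- function(x, L) {
  w <- x %% L
  w[w == L] <- 0
  w
}

# Minimum-image signed separation on a periodic interval of length L.
min_image <- function(dx, L) dx - L * round(dx / L)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed leaves the RNG alone.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
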